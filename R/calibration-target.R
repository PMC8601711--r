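# The thermal calibration target: an aluminium cross carrying thirty 11 mm
# tungsten bulbs on four arms. Three arms hold eight evenly spaced bulbs;
# the fourth holds six bulbs in three pairs, which breaks the 4-fold symmetry
# of the cross and lets the target's orientation be recovered from thermal
# footage alone.

#' Build the 30-bulb calibration target
#'
#' Bulb coordinates are expressed in the target frame: the cross lies in the
#' Z = 0 plane, arms along +X, +Y, -X and -Y. The -Y arm carries the six
#' bulbs in three pairs. Bulb spacing is not dictated by the hardware
#' description, so the arm length is configurable (default 1 m, even
#' spacing).
#'
#' @param arm_length_mm arm length from the cross centre to the outermost
#'   bulb position, in mm.
#' @param pair_half_gap_mm half the within-pair bulb separation on the
#'   paired arm, in mm.
#' @return object of class `calibration_target`: a data.frame with columns
#'   `bulb_id`, `arm` (`px`, `py`, `mx`, `my`), `X`, `Y`, `Z` (mm), plus
#'   attributes `arm_length_mm` and `bulb_diameter_mm` (11).
#' @export
calibration_target <- function(arm_length_mm = 1000, pair_half_gap_mm = 35) {
  even <- seq(0.125, 1, by = 0.125) * arm_length_mm          # 8 bulbs
  pair_centres <- c(0.25, 0.60, 0.95) * arm_length_mm        # 3 pairs of 2
  pairs <- as.vector(rbind(pair_centres - pair_half_gap_mm,
                           pair_centres + pair_half_gap_mm))
  df <- rbind(
    data.frame(arm = "px", X = even,  Y = 0,     pos = even),
    data.frame(arm = "py", X = 0,     Y = even,  pos = even),
    data.frame(arm = "mx", X = -even, Y = 0,     pos = even),
    data.frame(arm = "my", X = 0,     Y = -pairs, pos = pairs))
  df$Z <- 0
  df <- data.frame(bulb_id = seq_len(nrow(df)), df[c("arm", "X", "Y", "Z")],
                   pos_mm = df$pos)
  stopifnot(nrow(df) == 30, sum(df$arm == "my") == 6)
  structure(df, arm_length_mm = arm_length_mm, bulb_diameter_mm = 11,
            class = c("calibration_target", "data.frame"))
}

# ---- target identification from unlabelled blob coordinates ----------------

# fit the best line through >= min_inliers points; returns inlier index set
best_line <- function(pts, tol_px, exclude = integer(0)) {
  idx <- setdiff(seq_len(nrow(pts)), exclude)
  if (length(idx) < 2) return(NULL)
  best <- NULL; best_n <- 0
  cmb <- utils::combn(idx, 2)
  for (k in seq_len(ncol(cmb))) {
    a <- pts[cmb[1, k], ]; b <- pts[cmb[2, k], ]
    d <- b - a; len <- sqrt(sum(d^2))
    if (len < 1e-9) next
    n <- c(-d[2], d[1]) / len
    dist <- abs((pts[idx, 1] - a[1]) * n[1] + (pts[idx, 2] - a[2]) * n[2])
    inl <- idx[dist < tol_px]
    if (length(inl) > best_n) {
      best_n <- length(inl); best <- inl
    }
  }
  best
}

# least-squares line through points: returns point + unit direction
fit_line <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  list(point = ctr, dir = sv$v[, 1])
}

# 1D projective fit anchored at the cross centre: known positions s (mm
# along arm, measured from the centre) -> observed image offsets t (px from
# the centre); model t = a s / (c s + 1), which maps 0 -> 0. Anchoring at
# the centre is what makes a shifted evenly spaced subset distinguishable
# from the true one (an unanchored 1D homography would absorb the shift).
fit_1d_projective <- function(s, t) {
  # DLT: a s - c s t = t  ->  [s, -s t] theta = t
  A <- cbind(s, -s * t)
  th <- tryCatch(qr.solve(A, t), error = function(e) NULL)
  if (is.null(th)) return(Inf)
  pred <- th[1] * s / (th[2] * s + 1)
  sqrt(mean((pred - t)^2))
}

# assign detected points along one arm to bulb positions, tolerating missing
# bulbs: enumerate which subset of known positions is present (ordered), pick
# the subset whose 1D projective fit is best.
assign_arm_ids <- function(arm_offsets, known_pos) {
  n_det <- length(arm_offsets); n_all <- length(known_pos)
  if (n_det > n_all) return(NULL)
  ord <- order(arm_offsets)
  t_sorted <- arm_offsets[ord]
  subsets <- utils::combn(n_all, n_det)
  best <- NULL; best_rms <- Inf
  for (k in seq_len(ncol(subsets))) {
    s <- known_pos[subsets[, k]]
    rms <- if (n_det <= 2) 0 else fit_1d_projective(s, t_sorted)
    if (rms < best_rms) {
      best_rms <- rms; best <- subsets[, k]
    }
  }
  out <- integer(n_det)
  out[ord] <- best
  list(pos_index = out, rms = best_rms)
}

#' Identify calibration-target bulbs in one camera view
#'
#' Assigns bulb identities to unlabelled blob pixel coordinates from a single
#' pose. The cross projects to two image lines (arms are collinear in
#' opposite pairs); the three-pair arm is recognised by its gap pattern and
#' anchors the orientation, which is propagated to the remaining arms by the
#' cyclic order of arm directions around the cross centre (image v runs
#' downward, so the counter-clockwise target order appears clockwise).
#'
#' @param blobs numeric matrix with columns `u`, `v`: one row per detected
#'   blob (unlabelled), for a single pose and camera.
#' @param target a [calibration_target()].
#' @param tol_px collinearity tolerance in pixels.
#' @return a data.frame `bulb_id`, `u`, `v` on success; `NULL` (with a
#'   `reason` attribute via a warning) if the pose is rejected.
#' @export
identify_target <- function(blobs, target = calibration_target(),
                            tol_px = 2) {
  blobs <- as.matrix(blobs)[, 1:2, drop = FALSE]
  if (nrow(blobs) < 25) {
    warning("pose rejected: fewer than 25 of 30 bulbs detected")
    return(NULL)
  }
  l1_idx <- best_line(blobs, tol_px)
  l2_idx <- best_line(blobs, tol_px, exclude = l1_idx)
  if (is.null(l1_idx) || is.null(l2_idx) ||
      length(l1_idx) < 10 || length(l2_idx) < 8) {
    warning("pose rejected: could not isolate the two cross axes")
    return(NULL)
  }
  L1 <- fit_line(blobs[l1_idx, , drop = FALSE])
  L2 <- fit_line(blobs[l2_idx, , drop = FALSE])
  # centre = intersection of the two axes
  M <- cbind(L1$dir, -L2$dir)
  st <- tryCatch(solve(M[1:2, ], L2$point - L1$point),
                 error = function(e) NULL)
  if (is.null(st)) {
    warning("pose rejected: cross axes do not intersect")
    return(NULL)
  }
  ctr <- L1$point + st[1] * L1$dir

  # split each axis into its two arms by signed offset from the centre
  arms <- list()
  for (L in list(list(idx = l1_idx, dir = L1$dir),
                 list(idx = l2_idx, dir = L2$dir))) {
    off <- (blobs[L$idx, 1] - ctr[1]) * L$dir[1] +
           (blobs[L$idx, 2] - ctr[2]) * L$dir[2]
    arms <- c(arms,
              list(list(idx = L$idx[off > 0], dir = L$dir,
                        off = off[off > 0])),
              list(list(idx = L$idx[off < 0], dir = -L$dir,
                        off = -off[off < 0])))
  }
  if (any(vapply(arms, function(a) length(a$idx), 1L) < 4)) {
    warning("pose rejected: an arm has too few detected bulbs")
    return(NULL)
  }

  # the paired arm: 6ish points whose sorted gaps alternate small/large
  pair_score <- vapply(arms, function(a) {
    if (length(a$idx) < 5 || length(a$idx) > 6) return(Inf)
    g <- diff(sort(a$off))
    odd <- g[seq(1, length(g), by = 2)]
    even <- g[seq(2, length(g), by = 2)]
    if (!length(even)) return(Inf)
    max(odd) / min(even)   # < 1 means pair pattern
  }, 1)
  if (min(pair_score) > 0.5) {
    warning("pose rejected: six-bulb pair arm not identifiable")
    return(NULL)
  }
  my_arm <- which.min(pair_score)

  # cyclic order: for a front-facing target the counter-clockwise arm order
  # my -> px -> py -> mx is preserved in right-handed image coordinates
  # (u right, -v up).
  ang <- vapply(arms, function(a) atan2(-a$dir[2], a$dir[1]), 1)
  rel <- (ang - ang[my_arm]) %% (2 * pi)   # ccw offset from the pair arm
  ord <- order(rel)                         # my first, then ccw order
  arm_names <- character(4)
  arm_names[ord] <- c("my", "px", "py", "mx")

  out <- NULL
  for (a in seq_along(arms)) {
    nm <- arm_names[a]
    known <- target$pos_mm[target$arm == nm]
    ids <- target$bulb_id[target$arm == nm][order(known)]
    asg <- assign_arm_ids(arms[[a]]$off, sort(known))
    if (is.null(asg)) {
      warning(sprintf("pose rejected: ambiguous assignment on arm %s", nm))
      return(NULL)
    }
    out <- rbind(out, data.frame(bulb_id = ids[asg$pos_index],
                                 u = blobs[arms[[a]]$idx, 1],
                                 v = blobs[arms[[a]]$idx, 2]))
  }
  if (anyDuplicated(out$bulb_id)) {
    warning("pose rejected: duplicate bulb assignment")
    return(NULL)
  }
  out[order(out$bulb_id), , drop = FALSE]
}
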