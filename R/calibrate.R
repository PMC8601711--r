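# Stereo calibration from labelled target poses: per-camera planar
# (homography) linear initialisation, closed-form intrinsics, per-pose
# extrinsics, Levenberg-Marquardt bundle refinement, then the left-right
# relative pose. The world frame of the returned rig is anchored at the left
# camera with y the viewing direction and z height.

# normalised DLT homography: target plane (X, Y) -> pixels (u, v)
homography_dlt <- function(XY, uv) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- sqrt(2) / mean(d)
    T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1),
                3, 3, byrow = TRUE)
    list(T = T, p = cbind(s * (p[, 1] - ctr[1]), s * (p[, 2] - ctr[2])))
  }
  a <- norm_pts(XY); b <- norm_pts(uv)
  n <- nrow(XY)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(a$p[i, ], 1); u <- b$p[i, 1]; v <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, u * X)
    A[2 * i, ] <- c(0, 0, 0, -X, v * X)
  }
  h <- svd(A)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(b$T) %*% H %*% a$T
  H / H[3, 3]
}

# Zhang closed-form intrinsics (zero skew) from plane homographies.
# Returns intrinsics plus the condition number of the constraint system.
zhang_intrinsics <- function(Hs, image_size) {
  vij <- function(H, i, j) {
    # basis for B = [B11 0 B13; 0 B22 B23; B13 B23 B33]
    c(H[1, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(Hs, function(H) {
    rbind(vij(H, 1, 2), vij(H, 1, 1) - vij(H, 2, 2))
  }))
  sv <- svd(V)
  # the solution is the (one-dimensional) null space; a rank-deficient
  # constraint system (all-frontal poses) shows up as a second vanishing
  # singular value, so condition is measured against the second-smallest.
  cond <- sv$d[1] / sv$d[length(sv$d) - 1]
  b <- sv$v[, ncol(sv$v)]
  B11 <- b[1]; B22 <- b[2]; B13 <- b[3]; B23 <- b[4]; B33 <- b[5]
  if (B11 * B22 <= 0) stop("degenerate pose set: calibration normal equations are rank-deficient (add tilted poses)", call. = FALSE)
  cx <- -B13 / B11
  cy <- -B23 / B22
  lambda <- B33 - (B13^2 / B11 + B23^2 / B22)
  if (lambda / B11 <= 0 || lambda / B22 <= 0)
    stop("degenerate pose set: calibration normal equations are rank-deficient (add tilted poses)", call. = FALSE)
  fx <- sqrt(lambda / B11)
  fy <- sqrt(lambda / B22)
  list(intr = camera_intrinsics(fx = fx, fy = fy, cx = cx, cy = cy,
                                image_size = image_size),
       condition = cond)
}

# per-pose extrinsics (target frame -> camera frame) from H and K
extrinsics_from_homography <- function(H, intr) {
  K <- matrix(c(intr$fx, 0, intr$cx, 0, intr$fy, intr$cy, 0, 0, 1),
              3, 3, byrow = TRUE)
  Kinv <- solve(K)
  h1 <- Kinv %*% H[, 1]; h2 <- Kinv %*% H[, 2]; h3 <- Kinv %*% H[, 3]
  lam <- 1 / sqrt(sum(h1^2))
  if (h3[3] * lam < 0) lam <- -lam   # target must be in front of the camera
  r1 <- lam * h1; r2 <- lam * h2
  r3 <- pracma_cross(r1, r2)
  R <- nearest_rotation(cbind(r1, r2, r3))
  list(R = R, t = as.numeric(lam * h3))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# reprojection residuals for one camera over all poses
camera_residuals <- function(par, pose_pts, n_poses) {
  fx <- par[1]; fy <- par[2]; cx <- par[3]; cy <- par[4]
  out <- numeric(0)
  for (p in seq_len(n_poses)) {
    o <- 4 + (p - 1) * 6
    R <- rodrigues_to_matrix(par[o + 1:3])
    t <- par[o + 4:6]
    pts <- pose_pts[[p]]
    Xc <- pts$XYZ %*% t(R) + matrix(t, nrow(pts$XYZ), 3, byrow = TRUE)
    u <- fx * Xc[, 1] / Xc[, 3] + cx
    v <- fy * Xc[, 2] / Xc[, 3] + cy
    out <- c(out, u - pts$uv[, 1], v - pts$uv[, 2])
  }
  out
}

refine_camera <- function(intr0, exts0, pose_pts) {
  n_poses <- length(pose_pts)
  par0 <- c(intr0$fx, intr0$fy, intr0$cx, intr0$cy,
            unlist(lapply(exts0, function(e)
              c(matrix_to_rodrigues(e$R), e$t))))
  fit <- minpack.lm::nls.lm(
    par = par0, fn = camera_residuals, pose_pts = pose_pts,
    n_poses = n_poses,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  par <- fit$par
  exts <- lapply(seq_len(n_poses), function(p) {
    o <- 4 + (p - 1) * 6
    list(R = rodrigues_to_matrix(par[o + 1:3]), t = par[o + 4:6])
  })
  res <- camera_residuals(par, pose_pts, n_poses)
  list(fx = par[1], fy = par[2], cx = par[3], cy = par[4],
       exts = exts, rms = sqrt(mean(res^2)))
}

#' Calibrate a stereo rig from labelled target poses
#'
#' @param poses a data.frame with columns `pose_id`, `camera` (`"left"` or
#'   `"right"`), `bulb_id`, `u`, `v`: labelled bulb projections per pose
#'   (the output of [identify_target()] over a calibration sequence, or of
#'   [simulate_calibration_sequence()]).
#' @param target the [calibration_target()] the poses were filmed with.
#' @param image_size integer length-2 image size in pixels.
#' @param min_poses minimum number of usable poses (default 10).
#' @param condition_limit condition number of the intrinsics constraint
#'   system above which the pose set is declared degenerate.
#' @return a [stereo_rig()] with attributes `rms_px` (RMS reprojection error
#'   over both cameras), `condition` (per-camera condition numbers) and
#'   `n_poses`.
#' @export
calibrate_stereo <- function(poses, target = calibration_target(),
                             image_size = c(640L, 480L), min_poses = 10,
                             condition_limit = 1e8) {
  poses <- as.data.frame(poses)
  need <- c("pose_id", "camera", "bulb_id", "u", "v")
  miss <- setdiff(need, names(poses))
  if (length(miss))
    stop("calibration input is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  pose_ids <- sort(unique(poses$pose_id))
  # keep poses seen by both cameras
  both <- vapply(pose_ids, function(p)
    all(c("left", "right") %in% poses$camera[poses$pose_id == p]), TRUE)
  pose_ids <- pose_ids[both]
  if (length(pose_ids) < min_poses)
    stop(sprintf("calibration needs >= %d poses seen by both cameras (got %d)",
                 min_poses, length(pose_ids)), call. = FALSE)

  XYZ_all <- as.matrix(target[, c("X", "Y", "Z")])
  per_cam <- list()
  for (camn in c("left", "right")) {
    pose_pts <- lapply(pose_ids, function(p) {
      d <- poses[poses$pose_id == p & poses$camera == camn, ]
      d <- d[order(d$bulb_id), ]
      list(XYZ = XYZ_all[d$bulb_id, , drop = FALSE],
           uv = cbind(d$u, d$v))
    })
    Hs <- lapply(pose_pts, function(pp)
      homography_dlt(pp$XYZ[, 1:2, drop = FALSE], pp$uv))
    z <- zhang_intrinsics(Hs, image_size)
    if (z$condition > condition_limit)
      stop("degenerate pose set: calibration normal equations are rank-deficient (add tilted poses)", call. = FALSE)
    exts0 <- lapply(Hs, extrinsics_from_homography, intr = z$intr)
    per_cam[[camn]] <- c(refine_camera(z$intr, exts0, pose_pts),
                         list(condition = z$condition))
  }

  # relative pose right <- left, averaged over poses
  L <- per_cam$left; R <- per_cam$right
  rels <- lapply(seq_along(pose_ids), function(p) {
    Rrel <- R$exts[[p]]$R %*% t(L$exts[[p]]$R)
    trel <- R$exts[[p]]$t - Rrel %*% L$exts[[p]]$t
    list(R = Rrel, t = as.numeric(trel))
  })
  Rrel <- nearest_rotation(Reduce(`+`, lapply(rels, `[[`, "R")) / length(rels))
  trel <- Reduce(`+`, lapply(rels, `[[`, "t")) / length(rels)

  A <- world_to_cam_axes()
  left_cam <- camera(
    camera_intrinsics(L$fx, L$fy, L$cx, L$cy, image_size = image_size),
    camera_extrinsics(A, c(0, 0, 0)))
  right_cam <- camera(
    camera_intrinsics(R$fx, R$fy, R$cx, R$cy, image_size = image_size),
    camera_extrinsics(nearest_rotation(Rrel %*% A), as.numeric(trel)))
  baseline <- sqrt(sum((camera_centre(right_cam) - camera_centre(left_cam))^2))
  rig <- structure(list(left = left_cam, right = right_cam,
                        baseline_mm = baseline),
                   class = "stereo_rig")
  attr(rig, "rms_px") <- sqrt(mean(c(L$rms^2, R$rms^2)))
  attr(rig, "condition") <- c(left = L$condition, right = R$condition)
  attr(rig, "n_poses") <- length(pose_ids)
  rig
}

#' Simulate a calibration-target filming sequence
#'
#' Generates target poses spanning depth, tilt and in-plane orientation
#' (default 24 = 8 orientations x 3 tilt/depth configurations, mirroring the
#' field protocol) and projects every bulb into both cameras, with optional
#' pixel noise. Pose metadata is retained as ground truth.
#'
#' @param rig the true [stereo_rig()].
#' @param target a [calibration_target()].
#' @param n_poses number of poses (default 24).
#' @param pixel_noise isotropic Gaussian pixel noise s.d. (px).
#' @param depths_mm depths (world y, mm) cycled over configurations.
#' @param seed RNG seed.
#' @return list with `observations` (data.frame `pose_id`, `camera`,
#'   `bulb_id`, `u`, `v`) and `poses` (list of ground-truth pose transforms).
#' @export
simulate_calibration_sequence <- function(rig, target = calibration_target(),
                                          n_poses = 24, pixel_noise = 0,
                                          depths_mm = c(12000, 15000, 18000),
                                          seed = NULL) {
  local_seed(seed, {
    XY <- as.matrix(target[, c("X", "Y", "Z")])
    # target frame -> world: X -> x, Y -> z, normal -> -y (facing cameras)
    R0 <- matrix(c(1, 0, 0,
                   0, 0, -1,
                   0, 1, 0), 3, 3, byrow = TRUE)
    n_orient <- 8
    obs <- vector("list", n_poses)
    meta <- vector("list", n_poses)
    for (p in seq_len(n_poses)) {
      cfg <- ((p - 1) %/% n_orient) %% 3
      inplane <- 2 * pi * ((p - 1) %% n_orient) / n_orient
      tilt <- switch(cfg + 1,
                     rodrigues_to_matrix(c(0, 0, -0.45)),   # yaw left
                     rodrigues_to_matrix(c(0.40, 0, 0.2)),  # pitch + yaw
                     rodrigues_to_matrix(c(-0.25, 0, 0.35)))
      Rw <- tilt %*% R0 %*% rodrigues_to_matrix(c(0, 0, inplane))
      ctr <- c(2000 + 300 * cos(p), depths_mm[cfg + 1], 300 * sin(2 * p))
      Pw <- XY %*% t(Rw) + matrix(ctr, nrow(XY), 3, byrow = TRUE)
      for (camn in c("left", "right")) {
        uv <- project(Pw, rig[[camn]])
        if (pixel_noise > 0)
          uv <- uv + matrix(rnorm(length(uv), 0, pixel_noise), ncol = 2)
        w <- rig[[camn]]$intrinsics$image_size[1]
        h <- rig[[camn]]$intrinsics$image_size[2]
        vis <- uv[, 1] >= 0 & uv[, 1] <= w - 1 & uv[, 2] >= 0 & uv[, 2] <= h - 1
        obs[[p]] <- rbind(obs[[p]],
                          data.frame(pose_id = p, camera = camn,
                                     bulb_id = target$bulb_id[vis],
                                     u = uv[vis, 1], v = uv[vis, 2]))
      }
      meta[[p]] <- list(R = Rw, centre = ctr)
    }
    list(observations = do.call(rbind, obs), poses = meta)
  })
}
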