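# Tracking: cross-camera pairing of detections via triangulation residual,
# greedy frame-by-frame trajectory linking with global per-frame assignment,
# and the published QC rules (shared points, speed consistency, outlier
# smoothing). A brute-force enumerating linker is provided as a test oracle
# for small scenes.

#' Trajectory linking parameters
#'
#' Defaults are the published parameter set: maximum speed 15 m/s, maximum
#' frame gap 15, maximum step 1000 mm, minimum trajectory length 6
#' localisations, frame interval 0.032 s.
#'
#' @param vmax maximum plausible speed, m/s.
#' @param max_frame_gap maximum number of frames between linked
#'   localisations.
#' @param max_step maximum 3D distance between linked localisations, mm.
#' @param min_length minimum localisations per trajectory.
#' @param dt frame interval, s (0.032 as reported; 1/32 = 0.03125 s is also
#'   supported via this argument).
#' @return object of class `linking_params`.
#' @export
linking_params <- function(vmax = 15, max_frame_gap = 15, max_step = 1000,
                           min_length = 6, dt = 0.032) {
  stopifnot(vmax > 0, max_frame_gap > 0, max_step > 0, min_length >= 2,
            dt > 0)
  structure(list(vmax = vmax, max_frame_gap = max_frame_gap,
                 max_step = max_step, min_length = min_length, dt = dt),
            class = "linking_params")
}

#' Pair detections across cameras into 3D localisations
#'
#' Per frame, every left-right detection pair is triangulated and scored by
#' its mean reprojection residual; a global one-to-one minimum-cost
#' assignment keeps the consistent pairs, pairs above `max_residual` are
#' dropped, and unmatched detections are discarded.
#'
#' @param detections_left,detections_right data.frames from
#'   [detect_stack()] (columns `frame`, `u`, `v`).
#' @param rig the calibrated [stereo_rig()].
#' @param max_residual maximum mean reprojection residual (px, default 2).
#' @return data.frame of 3D localisations: `frame`, `x`, `y`, `z` (mm),
#'   `residual` (px), `det_left`, `det_right` (row indices into the inputs).
#' @export
pair_stereo <- function(detections_left, detections_right, rig,
                        max_residual = 2) {
  empty <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      z = numeric(), residual = numeric(),
                      det_left = integer(), det_right = integer())
  if (!nrow(detections_left) || !nrow(detections_right)) return(empty)
  out <- empty
  for (f in intersect(unique(detections_left$frame),
                      unique(detections_right$frame))) {
    il <- which(detections_left$frame == f)
    ir <- which(detections_right$frame == f)
    cost <- matrix(NA_real_, length(il), length(ir))
    pts <- vector("list", length(il) * length(ir))
    for (a in seq_along(il)) for (b in seq_along(ir)) {
      tr <- tryCatch(
        triangulate(c(detections_left$u[il[a]], detections_left$v[il[a]]),
                    c(detections_right$u[ir[b]], detections_right$v[ir[b]]),
                    rig),
        error = function(e) NULL)
      if (is.null(tr) || !is.finite(tr$residual) ||
          tr$residual > max_residual) next
      cost[a, b] <- tr$residual
      pts[[(a - 1) * length(ir) + b]] <- tr
    }
    m <- solve_assignment(cost)
    for (a in which(!is.na(m))) {
      tr <- pts[[(a - 1) * length(ir) + m[a]]]
      out <- rbind(out, data.frame(
        frame = f, x = tr$point[1], y = tr$point[2], z = tr$point[3],
        residual = tr$residual, det_left = il[a], det_right = ir[m[a]]))
    }
  }
  out[order(out$frame), , drop = FALSE]
}

# is linking loc j (frame fj) after loc i (frame fi) legal?
link_legal <- function(dx_mm, gap_frames, params) {
  gap_frames >= 1 && gap_frames <= params$max_frame_gap &&
    dx_mm <= params$max_step &&
    dx_mm / (gap_frames * params$dt * 1000) <= params$vmax
}

#' Link 3D localisations into trajectories
#'
#' Greedy in frame order with a global per-frame minimum-cost assignment
#' between active tracks and the frame's localisations (cost = 3D gap
#' distance; equal costs broken by smaller frame gap, then smaller
#' residual). An extension is legal iff the frame gap, step length and
#' implied speed are all within `params`. Tracks shorter than `min_length`
#' are discarded.
#'
#' @param localisations data.frame from [pair_stereo()] (needs `frame`,
#'   `x`, `y`, `z`; `residual` optional), sorted by frame.
#' @param params a [linking_params()].
#' @return list of trajectories, each a data.frame of its localisations with
#'   attribute `id`; every output satisfies the linking invariants.
#' @export
build_trajectories <- function(localisations, params = linking_params()) {
  if (!nrow(localisations)) return(list())
  locs <- localisations[order(localisations$frame), , drop = FALSE]
  if (is.null(locs$residual)) locs$residual <- 0
  tracks <- list()   # each: list(rows = integer rows into locs, last = row)
  closed <- list()
  eps <- 1e-9
  for (f in sort(unique(locs$frame))) {
    rows <- which(locs$frame == f)
    if (length(tracks)) {
      # retire tracks beyond the maximum gap
      last_f <- vapply(tracks, function(tr) locs$frame[tr$last], 1)
      expired <- f - last_f > params$max_frame_gap
      closed <- c(closed, tracks[expired])
      tracks <- tracks[!expired]
    }
    if (length(tracks) && length(rows)) {
      cost <- matrix(NA_real_, length(tracks), length(rows))
      for (a in seq_along(tracks)) {
        la <- tracks[[a]]$last
        gap <- f - locs$frame[la]
        d <- sqrt((locs$x[rows] - locs$x[la])^2 +
                    (locs$y[rows] - locs$y[la])^2 +
                    (locs$z[rows] - locs$z[la])^2)
        ok <- vapply(d, link_legal, TRUE, gap_frames = gap, params = params)
        # primary cost distance; tie-breaks: smaller gap, smaller residual
        cost[a, ok] <- d[ok] + eps * gap + eps^2 * locs$residual[rows[ok]]
      }
      m <- solve_assignment(cost)
      for (a in which(!is.na(m))) {
        r <- rows[m[a]]
        tracks[[a]]$rows <- c(tracks[[a]]$rows, r)
        tracks[[a]]$last <- r
      }
      rows <- setdiff(rows, rows[m[!is.na(m)]])
    }
    for (r in rows) tracks[[length(tracks) + 1]] <- list(rows = r, last = r)
  }
  closed <- c(closed, tracks)
  keep <- Filter(function(tr) length(tr$rows) >= params$min_length, closed)
  out <- lapply(seq_along(keep), function(i) {
    tr <- locs[keep[[i]]$rows, , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "id") <- i
    attr(tr, "params") <- params
    tr
  })
  for (tr in out) assert_trajectory(tr, params)
  out
}

# invariant check on every emitted trajectory
assert_trajectory <- function(tr, params) {
  stopifnot(nrow(tr) >= params$min_length,
            all(diff(tr$frame) >= 1),
            all(diff(tr$frame) <= params$max_frame_gap))
  d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
  stopifnot(all(d <= params$max_step + 1e-9),
            all(d / (diff(tr$frame) * params$dt * 1000) <=
                  params$vmax + 1e-9))
  invisible(TRUE)
}

#' Brute-force enumerating linker (test oracle)
#'
#' Enumerates every partition of the localisations into trajectories that
#' satisfies the linking constraints (each localisation either legally
#' extends an open track or opens a new one) and returns the partition
#' maximising the number of localisations in kept (length >= `min_length`)
#' trajectories, breaking ties by total link distance. The search is an
#' exact branch-and-bound: a branch is abandoned only when provably unable
#' to beat the incumbent (a group that can no longer reach `min_length`
#' before the scene ends forfeits its points). Independent of the greedy
#' per-frame assignment in [build_trajectories()]; intended for small
#' scenes (a few bats), guarded by a node budget.
#'
#' @param localisations data.frame as for [build_trajectories()].
#' @param params a [linking_params()].
#' @param max_nodes search-node budget (error if exceeded).
#' @return list of trajectories in the same format as
#'   [build_trajectories()].
#' @export
link_bruteforce <- function(localisations, params = linking_params(),
                            max_nodes = 2e5) {
  if (!nrow(localisations)) return(list())
  locs <- localisations[order(localisations$frame), , drop = FALSE]
  n <- nrow(locs)
  minl <- params$min_length
  frames <- locs$frame
  nodes <- 0L
  best_v <- -1; best_cost <- Inf; best_assign <- NULL

  dist_to <- function(a, b) {
    sqrt((locs$x[a] - locs$x[b])^2 + (locs$y[a] - locs$y[b])^2 +
           (locs$z[a] - locs$z[b])^2)
  }
  # future frames strictly after f and reachable within the frame gap from
  # a chain already ending at f (scene-local: any later frame is reachable
  # by hopping one localisation per frame as long as gaps stay legal)
  n_future_frames <- function(i, f) {
    length(unique(frames[seq.int(i, n)][frames[seq.int(i, n)] > f &
                                          frames[seq.int(i, n)] <=
                                            f + params$max_frame_gap *
                                              (minl + 1)]))
  }

  assign <- integer(n)
  tails <- integer(0)   # row index of each group tail
  sizes <- integer(0)

  recurse <- function(i, cost_acc) {
    nodes <<- nodes + 1L
    if (nodes > max_nodes)
      stop("brute-force linker exceeded its search budget", call. = FALSE)
    if (i > n) {
      v <- sum(sizes[sizes >= minl])
      if (v > best_v || (v == best_v && cost_acc < best_cost - 1e-12)) {
        best_v <<- v; best_cost <<- cost_acc; best_assign <<- assign
      }
      return(invisible(NULL))
    }
    # upper bound: points already in still-viable groups plus everything
    # not yet assigned
    viable <- sizes >= minl |
      (sizes + vapply(tails, function(t) n_future_frames(i, frames[t]), 1L)
       >= minl)
    ub <- sum(sizes[viable]) + (n - i + 1)
    if (ub < best_v || (ub == best_v && cost_acc >= best_cost - 1e-12))
      return(invisible(NULL))

    # extensions, nearest first, then a new track
    cand <- which(frames[tails] < frames[i])
    if (length(cand)) {
      d <- vapply(tails[cand], dist_to, 1, b = i)
      ok <- vapply(seq_along(cand), function(k)
        link_legal(d[k], frames[i] - frames[tails[cand[k]]], params), TRUE)
      cand <- cand[ok]; d <- d[ok]
      for (k in order(d)) {
        g <- cand[k]
        old_tail <- tails[g]
        tails[g] <<- i; sizes[g] <<- sizes[g] + 1L; assign[i] <<- g
        recurse(i + 1, cost_acc + d[k])
        tails[g] <<- old_tail; sizes[g] <<- sizes[g] - 1L
      }
    }
    tails[length(tails) + 1] <<- i
    sizes[length(sizes) + 1] <<- 1L
    assign[i] <<- length(tails)
    recurse(i + 1, cost_acc)
    tails <<- tails[-length(tails)]
    sizes <<- sizes[-length(sizes)]
    assign[i] <<- 0L
    invisible(NULL)
  }
  recurse(1L, 0)

  kept <- Filter(function(rows) length(rows) >= minl,
                 split(seq_len(n), best_assign))
  lapply(seq_along(kept), function(i) {
    tr <- locs[kept[[i]], , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "id") <- i
    tr
  })
}

#' Remove trajectories sharing too many localisations
#'
#' Any trajectory sharing more than three localisation points with another
#' is removed (both members of the offending pair); shared-point counts are
#' recorded in the `shared_points` attribute of every returned trajectory.
#'
#' @param trajectories list of trajectories (from [build_trajectories()]).
#' @param max_shared maximum tolerated shared localisations (default 3).
#' @return the retained trajectories.
#' @export
qc_shared_points <- function(trajectories, max_shared = 3) {
  n <- length(trajectories)
  if (n <= 1) {
    for (i in seq_len(n)) attr(trajectories[[i]], "shared_points") <- 0L
    return(trajectories)
  }
  keys <- lapply(trajectories, function(tr)
    paste(tr$frame, signif(tr$x, 10), signif(tr$y, 10), signif(tr$z, 10)))
  shared <- integer(n)
  drop <- logical(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- length(intersect(keys[[i]], keys[[j]]))
    shared[i] <- max(shared[i], s)
    shared[j] <- max(shared[j], s)
    if (s > max_shared) drop[i] <- drop[j] <- TRUE
  }
  out <- trajectories[!drop]
  kept_shared <- shared[!drop]
  for (i in seq_along(out)) attr(out[[i]], "shared_points") <- kept_shared[i]
  out
}

#' Speed-consistency check
#'
#' Fails a trajectory iff any two subsequent instantaneous speeds differ by
#' more than `max_jump` (3 m/s as published).
#'
#' @param trajectory one trajectory data.frame (>= 3 localisations).
#' @param max_jump maximum speed difference between subsequent segments,
#'   m/s.
#' @param dt frame interval, s.
#' @return list with `pass` (logical) and `offending` (indices of the later
#'   segment of each offending pair).
#' @export
qc_speed_consistency <- function(trajectory, max_jump = 3, dt = 0.032) {
  if (nrow(trajectory) < 3)
    stop("speed-consistency check needs >= 3 localisations", call. = FALSE)
  v <- instantaneous_speeds(trajectory, dt)
  jumps <- abs(diff(v))
  off <- which(jumps > max_jump) + 1L
  list(pass = length(off) == 0, offending = off)
}

#' Remove isolated erroneous localisations, or reject the trajectory
#'
#' A localisation is deemed erroneous iff both of its adjacent segments
#' imply a speed jump above `max_jump` or a step above `max_step`, and
#' removing it restores consistency. If more than `max_fraction` of the
#' localisations are erroneous the whole trajectory is rejected (returned as
#' `NULL`) rather than over-edited; if nothing is wrong it is returned
#' unchanged.
#'
#' @param trajectory one trajectory data.frame.
#' @param params a [linking_params()] (supplies `max_step` and `dt`).
#' @param max_jump speed-jump limit, m/s.
#' @param max_fraction maximum fraction of localisations that may be removed
#'   (default 0.1).
#' @return the (possibly edited) trajectory with attribute `n_removed`, or
#'   `NULL` if rejected.
#' @export
smooth_trajectory <- function(trajectory, params = linking_params(),
                              max_jump = 3, max_fraction = 0.1) {
  violations <- function(tr) {
    d <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
    v <- d / (diff(tr$frame) * params$dt * 1000)
    sum(d > params$max_step) +
      (if (length(v) >= 2) sum(abs(diff(v)) > max_jump) else 0)
  }
  tr <- trajectory
  n0 <- nrow(tr)
  removed <- 0L
  while (nrow(tr) >= 3 && violations(tr) > 0) {
    cur <- violations(tr)
    cand_scores <- vapply(2:(nrow(tr) - 1), function(i)
      violations(tr[-i, , drop = FALSE]), 1)
    if (min(cand_scores) >= cur) break   # no single removal helps
    i <- which.min(cand_scores) + 1L
    tr <- tr[-i, , drop = FALSE]
    removed <- removed + 1L
    if (removed > max_fraction * n0) return(NULL)   # reject whole trajectory
  }
  if (violations(tr) > 0) {
    # unresolved distortion: return unchanged but flagged
    attr(trajectory, "n_removed") <- 0L
    attr(trajectory, "smooth_failed") <- TRUE
    return(trajectory)
  }
  attr(tr, "n_removed") <- removed
  attr(tr, "smooth_failed") <- FALSE
  tr
}
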