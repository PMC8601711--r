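# Detection: background subtraction over a frame stack, connected-component
# blob extraction with intensity-weighted sub-pixel centroids, and the
# empirical pixel-threshold selection step (the threshold that maximises the
# number of QC-passing trajectories while penalising discarded
# localisations).

#' Background-subtract a frame stack
#'
#' @param stack list of numeric frame matrices.
#' @param mode `"adjacent_frame"` (absolute difference between consecutive
#'   frames, as used on the field footage: a moving target leaves a blob at
#'   both its old and new position) or `"rolling_median"` (subtract the
#'   per-pixel temporal median background; the robust default for synthetic
#'   scenes).
#' @param window median window in frames for `"rolling_median"`; `NULL`
#'   (default) uses the whole stack as a static background model.
#' @return list with `frames` (non-negative difference matrices) and
#'   `frame_index` (0-based index each difference frame refers to).
#' @export
background_subtract <- function(stack,
                                mode = c("rolling_median", "adjacent_frame"),
                                window = NULL) {
  mode <- match.arg(mode)
  n <- length(stack)
  if (n < 2) stop("background subtraction needs >= 2 frames", call. = FALSE)
  if (mode == "adjacent_frame") {
    frames <- lapply(2:n, function(i) abs(stack[[i]] - stack[[i - 1]]))
    return(list(frames = frames, frame_index = seq.int(1L, n - 1L)))
  }
  dims <- dim(stack[[1]])
  m <- vapply(stack, as.numeric, numeric(prod(dims)))
  if (is.null(window) || window >= n) {
    bg <- row_medians(m)
    frames <- lapply(seq_len(n), function(i)
      matrix(pmax(m[, i] - bg, 0), dims[1], dims[2]))
  } else {
    half <- window %/% 2
    frames <- lapply(seq_len(n), function(i) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      bg <- row_medians(m[, lo:hi, drop = FALSE])
      matrix(pmax(m[, i] - bg, 0), dims[1], dims[2])
    })
  }
  list(frames = frames, frame_index = seq.int(0L, n - 1L))
}

#' Detect blobs in one difference frame
#'
#' Connected components (8-connectivity) above the pixel threshold, filtered
#' by minimum blob area, with intensity-weighted centroids at sub-pixel
#' precision. Pixel coordinates are 0-based with `u` along columns and `v`
#' along rows.
#'
#' @param frame numeric difference-frame matrix.
#' @param pixel_threshold intensity threshold (> 0).
#' @param min_blob_area minimum component area in pixels (default 2, to
#'   reject single-pixel noise).
#' @param frame_index 0-based frame index recorded in the output.
#' @param camera camera label recorded in the output.
#' @return data.frame `camera`, `frame`, `u`, `v`, `area`, `peak` (possibly
#'   zero rows).
#' @export
threshold_detect <- function(frame, pixel_threshold, min_blob_area = 2,
                             frame_index = 0L, camera = "left") {
  stopifnot_scalar(pixel_threshold, "pixel_threshold")
  mask <- frame > pixel_threshold
  empty <- data.frame(camera = character(), frame = integer(),
                      u = numeric(), v = numeric(), area = integer(),
                      peak = numeric())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(t(mask))   # EBImage images are x-major
  lab <- t(EBImage::imageData(lab))
  ids <- sort(unique(lab[lab > 0]))
  out <- empty
  for (id in ids) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_blob_area) next
    wgt <- frame[px]
    out <- rbind(out, data.frame(
      camera = camera, frame = as.integer(frame_index),
      u = sum((px[, 2] - 1) * wgt) / sum(wgt),
      v = sum((px[, 1] - 1) * wgt) / sum(wgt),
      area = nrow(px), peak = max(wgt)))
  }
  out
}

#' Detect blobs across a whole stack
#'
#' @param stack list of frame matrices (raw; background subtraction is
#'   applied first).
#' @param pixel_threshold intensity threshold.
#' @param camera camera label.
#' @param mode,window passed to [background_subtract()].
#' @param min_blob_area minimum blob area (px).
#' @return data.frame of detections over all frames.
#' @export
detect_stack <- function(stack, pixel_threshold, camera = "left",
                         mode = "rolling_median", window = NULL,
                         min_blob_area = 2) {
  bs <- background_subtract(stack, mode = mode, window = window)
  out <- mapply(function(fr, idx)
    threshold_detect(fr, pixel_threshold, min_blob_area, idx, camera),
    bs$frames, bs$frame_index, SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Select the pixel threshold empirically
#'
#' Runs the full detect -> pair -> link -> QC chain for each candidate
#' threshold and scores each candidate as the number of QC-passing
#' trajectories minus `lambda` times the number of discarded localisations
#' (localisations not retained in any QC-passing trajectory). Returns the
#' arg-max; ties go to the higher threshold (fewer spurious detections).
#'
#' @param stack_left,stack_right raw frame stacks.
#' @param rig the calibrated [stereo_rig()].
#' @param candidate_thresholds numeric vector (>= 2 candidates unless a
#'   single one is supplied, which is returned trivially).
#' @param linking a [linking_params()].
#' @param lambda penalty weight on discarded localisations (default 0.1; the
#'   "minimum amount of noise" criterion is not quantified in the field
#'   protocol, so this weight is an explicit modelling choice).
#' @param mode,window background-subtraction settings.
#' @param max_residual stereo pairing residual gate (px).
#' @return list with `threshold` (chosen) and `diagnostics` (per-candidate
#'   data.frame: threshold, n_detections, n_localisations, n_trajectories,
#'   n_discarded, score).
#' @export
select_threshold <- function(stack_left, stack_right, rig,
                             candidate_thresholds, linking = linking_params(),
                             lambda = 0.1, mode = "rolling_median",
                             window = NULL, max_residual = 2) {
  ths <- sort(candidate_thresholds)
  if (length(ths) == 1)
    return(list(threshold = ths, diagnostics = NULL))
  diag <- NULL
  for (th in ths) {
    dl <- detect_stack(stack_left, th, "left", mode, window)
    dr <- detect_stack(stack_right, th, "right", mode, window)
    locs <- pair_stereo(dl, dr, rig, max_residual = max_residual)
    trajs <- build_trajectories(locs, linking)
    trajs <- qc_shared_points(trajs)
    trajs <- Filter(function(tr) {
      nrow(tr) < 3 || qc_speed_consistency(tr, dt = linking$dt)$pass
    }, trajs)
    n_used <- sum(vapply(trajs, nrow, 1L))
    diag <- rbind(diag, data.frame(
      threshold = th, n_detections = nrow(dl) + nrow(dr),
      n_localisations = nrow(locs), n_trajectories = length(trajs),
      n_discarded = nrow(locs) - n_used,
      score = length(trajs) - lambda * (nrow(locs) - n_used)))
  }
  if (all(diag$n_trajectories == 0))
    stop("no candidate threshold yielded any trajectory; widen the candidate grid",
         call. = FALSE)
  best <- diag$threshold[diag$score == max(diag$score)]
  list(threshold = max(best), diagnostics = diag)
}
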