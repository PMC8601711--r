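# Thermal-like frame rendering: Gaussian blobs for in-view bats over
# Gaussian background noise, with Poisson clutter blobs standing in for
# insects. Frames are numeric matrices in [0, 1] (written as 16-bit
# grayscale multi-page TIFF).

# add one Gaussian blob at sub-pixel centre (u, v), 0-based pixel centres
add_blob <- function(frame, u, v, sigma, amplitude) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(4 * sigma)
  cols <- max(1, floor(u) - r + 1):min(w, ceiling(u) + r + 1)
  rows <- max(1, floor(v) - r + 1):min(h, ceiling(v) + r + 1)
  if (!length(cols) || !length(rows)) return(frame)
  du <- (cols - 1) - u
  dv <- (rows - 1) - v
  g <- exp(-outer(dv^2, du^2, `+`) / (2 * sigma^2)) * amplitude
  frame[rows, cols] <- frame[rows, cols] + g
  frame
}

#' Render two-camera frame stacks from ground-truth paths
#'
#' Per camera and frame: constant base level plus Gaussian background noise,
#' one Gaussian blob per in-view projected bat position, and Poisson-rate
#' clutter blobs. Paths outside a camera's field of view are simply absent
#' from that camera. The projection uses the full camera model of the rig.
#'
#' @param paths list of `ground_truth_path` objects (frame indices share one
#'   clock).
#' @param rig a [stereo_rig()].
#' @param n_frames number of frames to render (default: max frame over paths
#'   + 1).
#' @param noise list: `background_sd` (Gaussian noise s.d., image units),
#'   `blob_sigma` (px), `blob_amplitude`, `clutter_rate` (expected clutter
#'   blobs per frame per camera), `clutter_amplitude`, `base_level`.
#' @param seed RNG seed.
#' @return list with elements `left` and `right`, each a list of `n_frames`
#'   numeric matrices (rows = image v, cols = image u), and `truth`, a
#'   data.frame of projected blob centres (`camera`, `frame`, `path`,
#'   `u`, `v`).
#' @export
render_frames <- function(paths, rig, n_frames = NULL,
                          noise = list(), seed = NULL) {
  nz <- utils::modifyList(
    list(background_sd = 0.02, blob_sigma = 1.6, blob_amplitude = 0.6,
         clutter_rate = 0, clutter_amplitude = 0.3, base_level = 0.1),
    noise)
  if (is.null(n_frames))
    n_frames <- max(vapply(paths, function(p) max(p$frame), 0)) + 1
  w <- rig$left$intrinsics$image_size[1]
  h <- rig$left$intrinsics$image_size[2]
  local_seed(seed, {
    stacks <- list()
    truth <- NULL
    for (camn in c("left", "right")) {
      cam <- rig[[camn]]
      stack <- vector("list", n_frames)
      for (f in seq_len(n_frames) - 1L) {
        fr <- matrix(nz$base_level, h, w)
        if (nz$background_sd > 0)
          fr <- fr + matrix(rnorm(h * w, 0, nz$background_sd), h, w)
        for (pi in seq_along(paths)) {
          p <- paths[[pi]]
          row <- which(p$frame == f)
          if (!length(row)) next
          uv <- tryCatch(project(as.numeric(p[row, c("x", "y", "z")]), cam),
                         error = function(e) NULL)
          if (is.null(uv)) next
          if (uv[1] < 0 || uv[1] > w - 1 || uv[2] < 0 || uv[2] > h - 1) next
          fr <- add_blob(fr, uv[1], uv[2], nz$blob_sigma, nz$blob_amplitude)
          truth <- rbind(truth, data.frame(camera = camn, frame = f,
                                           path = pi, u = uv[1], v = uv[2]))
        }
        n_clut <- if (nz$clutter_rate > 0) rpois(1, nz$clutter_rate) else 0L
        if (n_clut > 0) {
          cu <- runif(n_clut, 0, w - 1)
          cv <- runif(n_clut, 0, h - 1)
          for (k in seq_len(n_clut))
            fr <- add_blob(fr, cu[k], cv[k], nz$blob_sigma * 0.7,
                           nz$clutter_amplitude)
        }
        stack[[f + 1L]] <- pmin(pmax(fr, 0), 1)
      }
      stacks[[camn]] <- stack
    }
    c(stacks, list(truth = truth))
  })
}

#' Write a frame stack as multi-page 16-bit grayscale TIFF
#'
#' @param stack list of numeric matrices in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  tiff::writeTIFF(stack, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF frame stack
#'
#' @param path TIFF file path.
#' @return list of numeric matrices in `[0, 1]`.
#' @export
read_frame_stack <- function(path) {
  out <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(out)) out <- list(out)
  lapply(out, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
}
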