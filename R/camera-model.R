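# Pinhole camera model, stereo rig construction, projection and
# triangulation.
#
# World frame convention (matching how flight metrics are reported): x is
# lateral (along the camera baseline), y is range from the camera plane
# (the viewing direction), z is height. The camera frame is the usual
# computer-vision one (x right, y down, z forward), so a camera looking
# straight down-range has the fixed world-to-camera rotation that maps
# (x, y, z)_world -> (x, -z, y)_camera.

#' Camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels (0-based pixel coordinates).
#' @param k1,k2 radial distortion coefficients (default 0; the thermal lenses
#'   are modelled distortion-free unless calibration says otherwise).
#' @param image_size integer length-2, width and height in pixels.
#' @return object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy = fx, cx = (image_size[1] - 1) / 2,
                              cy = (image_size[2] - 1) / 2,
                              k1 = 0, k2 = 0, image_size = c(640L, 480L)) {
  stopifnot_scalar(fx, "fx"); stopifnot_scalar(fy, "fy")
  if (cx < 0 || cx > image_size[1] - 1 || cy < 0 || cy > image_size[2] - 1)
    stop("principal point must lie inside the image", call. = FALSE)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, k1 = k1, k2 = k2,
                 image_size = as.integer(image_size)),
            class = "camera_intrinsics")
}

#' Camera extrinsics (world-to-camera rigid transform)
#'
#' `X_cam = R %*% X_world + t`, translation in mm.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t numeric length-3 translation (mm).
#' @return object of class `camera_extrinsics`.
#' @export
camera_extrinsics <- function(R, t) {
  R <- as.matrix(R)
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be orthonormal with determinant +1", call. = FALSE)
  structure(list(R = R, t = as.numeric(t)), class = "camera_extrinsics")
}

#' A calibrated camera (intrinsics + extrinsics)
#' @param intrinsics a [camera_intrinsics()] object.
#' @param extrinsics a [camera_extrinsics()] object.
#' @return object of class `camera`.
#' @export
camera <- function(intrinsics, extrinsics) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(extrinsics, "camera_extrinsics"))
  structure(list(intrinsics = intrinsics, extrinsics = extrinsics),
            class = "camera")
}

# world->camera axis permutation for a camera looking along +y world
world_to_cam_axes <- function() {
  matrix(c(1, 0, 0,
           0, 0, -1,
           0, 1, 0), nrow = 3, byrow = TRUE)
}

#' Construct a parallel-axis stereo rig
#'
#' Default geometry mirrors the field set-up: two cameras at the same height,
#' 4 m apart along x, optical axes parallel and horizontal, looking down-range
#' (+y). The world frame is anchored at the left camera's optical centre.
#' Focal length defaults to a 33-degree horizontal field of view on a 640 px
#' sensor.
#'
#' @param baseline_mm camera separation along x in mm.
#' @param fov_deg horizontal field of view in degrees (sets the focal length).
#' @param image_size integer length-2 image size in pixels.
#' @param k1,k2 radial distortion coefficients applied to both cameras.
#' @return object of class `stereo_rig` with elements `left`, `right`,
#'   `baseline_mm`.
#' @export
#' @examples
#' rig <- stereo_rig()
#' project(c(2000, 15000, 500), rig$left)
stereo_rig <- function(baseline_mm = 4000, fov_deg = 33,
                       image_size = c(640L, 480L), k1 = 0, k2 = 0) {
  stopifnot_scalar(baseline_mm, "baseline_mm")
  f <- image_size[1] / (2 * tan(fov_deg / 2 * pi / 180))
  intr <- camera_intrinsics(fx = f, fy = f, image_size = image_size,
                            k1 = k1, k2 = k2)
  A <- world_to_cam_axes()
  left <- camera(intr, camera_extrinsics(A, c(0, 0, 0)))
  # right camera centre at (baseline, 0, 0) world: t = -R %*% C
  right <- camera(intr, camera_extrinsics(A, -A %*% c(baseline_mm, 0, 0)))
  structure(list(left = left, right = right, baseline_mm = baseline_mm),
            class = "stereo_rig")
}

#' Camera optical centre in world coordinates
#' @param cam a [camera()] object.
#' @return numeric length-3 (mm).
#' @export
camera_centre <- function(cam) {
  e <- cam$extrinsics
  as.numeric(-t(e$R) %*% e$t)
}

#' Project world points into a camera
#'
#' Perspective division first, then radial distortion on the normalised image
#' coordinates, then the pixel mapping; sub-pixel precision throughout.
#'
#' @param points numeric length-3 vector or n x 3 matrix of world points (mm).
#' @param cam a [camera()] object.
#' @return n x 2 matrix of pixel coordinates `(u, v)`.
#' @export
project <- function(points, cam) {
  P <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  e <- cam$extrinsics; k <- cam$intrinsics
  Xc <- P %*% t(e$R) + matrix(e$t, nrow(P), 3, byrow = TRUE)
  if (any(Xc[, 3] <= 0))
    stop("point behind camera: non-positive depth", call. = FALSE)
  xn <- Xc[, 1] / Xc[, 3]
  yn <- Xc[, 2] / Xc[, 3]
  r2 <- xn^2 + yn^2
  dist <- 1 + k$k1 * r2 + k$k2 * r2^2
  cbind(u = k$fx * xn * dist + k$cx,
        v = k$fy * yn * dist + k$cy)
}

# undistort normalised coordinates by fixed-point iteration
undistort_normalised <- function(xd, yd, k1, k2, iters = 20) {
  x <- xd; y <- yd
  if (k1 == 0 && k2 == 0) return(cbind(x, y))
  for (i in seq_len(iters)) {
    r2 <- x^2 + y^2
    d <- 1 + k1 * r2 + k2 * r2^2
    x <- xd / d; y <- yd / d
  }
  cbind(x, y)
}

# pixel -> unit ray direction in world coordinates, plus camera centre
pixel_ray <- function(px, cam) {
  k <- cam$intrinsics; e <- cam$extrinsics
  xn <- (px[1] - k$cx) / k$fx
  yn <- (px[2] - k$cy) / k$fy
  un <- undistort_normalised(xn, yn, k$k1, k$k2)
  d_cam <- c(un[1], un[2], 1)
  d_world <- as.numeric(t(e$R) %*% d_cam)
  list(origin = camera_centre(cam), dir = d_world / sqrt(sum(d_world^2)))
}

#' Triangulate a stereo pixel pair
#'
#' Midpoint of the shortest segment between the two back-projected rays,
#' with the mean reprojection error over both cameras reported as the
#' residual.
#'
#' @param px_left,px_right numeric length-2 pixel coordinates `(u, v)`.
#' @param rig a [stereo_rig()] (or any list with `left`/`right` cameras).
#' @param min_ray_angle_deg minimum angle between rays in degrees below which
#'   depth is declared unresolvable (default 0.05).
#' @return list with `point` (length-3 world mm) and `residual` (px).
#' @export
triangulate <- function(px_left, px_right, rig, min_ray_angle_deg = 0.05) {
  rl <- pixel_ray(px_left, rig$left)
  rr <- pixel_ray(px_right, rig$right)
  b <- rr$origin - rl$origin
  d1 <- rl$dir; d2 <- rr$dir
  cross_ang <- acos(min(1, abs(sum(d1 * d2)))) * 180 / pi
  if (cross_ang < min_ray_angle_deg)
    stop("near-parallel rays: depth unresolvable for this pixel pair",
         call. = FALSE)
  # closest points: solve [d1.d1 -d1.d2; d1.d2 -d2.d2] [s; t] = [d1.b; d2.b]
  a11 <- sum(d1 * d1); a12 <- sum(d1 * d2); a22 <- sum(d2 * d2)
  b1 <- sum(d1 * b); b2 <- sum(d2 * b)
  den <- a11 * a22 - a12^2
  s <- (b1 * a22 - a12 * b2) / den
  t <- (a12 * b1 - a11 * b2) / den
  p1 <- rl$origin + s * d1
  p2 <- rr$origin + t * d2
  point <- (p1 + p2) / 2
  res <- tryCatch({
    pl <- project(point, rig$left); pr <- project(point, rig$right)
    (sqrt(sum((pl - px_left)^2)) + sqrt(sum((pr - px_right)^2))) / 2
  }, error = function(e) Inf)
  list(point = as.numeric(point), residual = res)
}
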