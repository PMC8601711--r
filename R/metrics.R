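# Per-trajectory flight variables: instantaneous and mean speed, total
# travelled length, net displacement, tortuosity value, mean range (y),
# distance from the deterrent speakers and mean height (z). World
# coordinates are mm; metrics are reported in metres and m/s.

#' Instantaneous speeds along a trajectory
#'
#' `speed_i = ||P_{i+1} - P_i|| / (gap_i * dt)` in m/s, where `gap_i` is the
#' frame gap of segment i.
#'
#' @param traj trajectory data.frame with `frame`, `x`, `y`, `z` (mm).
#' @param dt frame interval in seconds (default 0.032).
#' @return numeric vector, one speed per segment.
#' @export
instantaneous_speeds <- function(traj, dt = 0.032) {
  if (nrow(traj) < 2)
    stop("instantaneous speeds need >= 2 localisations", call. = FALSE)
  d_mm <- sqrt(diff(traj$x)^2 + diff(traj$y)^2 + diff(traj$z)^2)
  gaps <- diff(traj$frame)
  (d_mm / 1000) / (gaps * dt)
}

#' Mean trajectory flight speed
#'
#' Arithmetic mean of the instantaneous speeds, m/s.
#'
#' @inheritParams instantaneous_speeds
#' @export
mean_speed <- function(traj, dt = 0.032) {
  mean(instantaneous_speeds(traj, dt))
}

#' Total travelled length and net displacement
#'
#' Total length is the sum of all straight-line distance segments between
#' successive localisations (segments spanning frame gaps contribute their
#' straight-line length); net displacement is the distance from the first to
#' the last localisation. Both in metres.
#'
#' @param traj trajectory data.frame.
#' @return named numeric `c(total, net)` in m.
#' @export
total_length_and_net <- function(traj) {
  d_mm <- sqrt(diff(traj$x)^2 + diff(traj$y)^2 + diff(traj$z)^2)
  net_mm <- sqrt((traj$x[nrow(traj)] - traj$x[1])^2 +
                   (traj$y[nrow(traj)] - traj$y[1])^2 +
                   (traj$z[nrow(traj)] - traj$z[1])^2)
  c(total = sum(d_mm) / 1000, net = net_mm / 1000)
}

#' Tortuosity value
#'
#' `(total travelled distance / net displacement) / 10`: 0.1 for a straight
#' path, larger for convoluted flight, nominally bounded in (0, 1] for
#' ratios up to 10. Undefined (NA, with a message) when net displacement is
#' zero.
#'
#' @param traj trajectory data.frame.
#' @return numeric scalar, or `NA` when undefined.
#' @export
tortuosity_value <- function(traj) {
  tn <- total_length_and_net(traj)
  if (tn["net"] == 0) {
    message("tortuosity undefined for zero net displacement; trajectory excluded from tortuosity analyses")
    return(NA_real_)
  }
  unname((tn["total"] / tn["net"]) / 10)
}

#' Mean range, distance from the deterrent, and mean height
#'
#' Mean range is the mean of the y coordinate (m, from the camera plane);
#' distance from the deterrent adds the speaker offset behind the cameras
#' (default 15 m); mean height is the mean z (m, relative to the cameras).
#' Both the raw mean y and the offset distance are returned so either
#' reporting convention can be reproduced.
#'
#' @param traj trajectory data.frame (mm world coordinates).
#' @param deterrent_offset speaker distance behind the camera plane, m.
#' @return named numeric `c(mean_y, distance_from_deterrent, mean_height)`
#'   in m.
#' @export
distance_and_height <- function(traj, deterrent_offset = 15) {
  my <- mean(traj$y) / 1000
  c(mean_y = my, distance_from_deterrent = my + deterrent_offset,
    mean_height = mean(traj$z) / 1000)
}

#' Summarise a set of trajectories into a metrics table
#'
#' @param trajectories list of trajectory data.frames.
#' @param dt frame interval, s.
#' @param deterrent_offset speaker offset, m.
#' @param labels optional data.frame with one row per trajectory of design
#'   labels (e.g. `site`, `night`, `block`, `treatment`) bound onto the
#'   output.
#' @return data.frame, one row per trajectory: `trajectory_id`,
#'   `mean_speed`, `total_length`, `net_displacement`, `tortuosity_value`,
#'   `mean_y`, `distance_from_deterrent`, `mean_height`,
#'   `n_localisations`, `n_segments`.
#' @export
trajectory_metrics <- function(trajectories, dt = 0.032,
                               deterrent_offset = 15, labels = NULL) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    tn <- total_length_and_net(tr)
    dh <- distance_and_height(tr, deterrent_offset)
    data.frame(trajectory_id = attr(tr, "id") %||% i,
               mean_speed = mean_speed(tr, dt),
               total_length = unname(tn["total"]),
               net_displacement = unname(tn["net"]),
               tortuosity_value = suppressMessages(tortuosity_value(tr)),
               mean_y = unname(dh["mean_y"]),
               distance_from_deterrent = unname(dh["distance_from_deterrent"]),
               mean_height = unname(dh["mean_height"]),
               n_localisations = nrow(tr),
               n_segments = nrow(tr) - 1L)
  })
  out <- do.call(rbind, rows)
  if (!is.null(labels)) out <- cbind(out, labels)
  out
}
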