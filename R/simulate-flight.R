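# Ground-truth flight simulation: a 3D correlated random walk with
# commuting/foraging kinematic regimes, and a deterrent-response mechanism
# (regime switch plus heading bias away from the source) that encodes the
# three observed behavioural effects: faster, straighter flight at greater
# distance from the speakers.

#' Flight kinematic regime
#'
#' Defaults follow the observed per-trajectory kinematics: commuting-like
#' flight at 4.86 m/s with nearly straight headings, foraging-like flight at
#' 4.54 m/s with loose, twisty headings. Turning-rate data are not available
#' for these bats, so the turn concentrations are model assumptions (see the
#' methods vignette).
#'
#' @param name `"commuting"` or `"foraging"`.
#' @param mean_speed mean flight speed, m/s.
#' @param speed_sd between-step speed s.d., m/s.
#' @param turn_concentration concentration of the wrapped-normal turning
#'   angle (dimensionless; higher = straighter; the turning-angle s.d. is
#'   `1/sqrt(turn_concentration)` radians).
#' @param vertical_sd s.d. of the vertical velocity component, m/s.
#' @param step_rate steps per second (frame rate; default 1/0.032).
#' @return object of class `flight_regime`.
#' @export
flight_regime <- function(name = c("commuting", "foraging"),
                          mean_speed = NULL, speed_sd = NULL,
                          turn_concentration = NULL, vertical_sd = NULL,
                          step_rate = 1 / 0.032) {
  name <- match.arg(name)
  def <- switch(name,
    commuting = list(mean_speed = 4.86, speed_sd = 0.92,
                     turn_concentration = 60, vertical_sd = 0.25),
    foraging = list(mean_speed = 4.54, speed_sd = 0.99,
                    turn_concentration = 6, vertical_sd = 0.6))
  out <- list(name = name,
              mean_speed = mean_speed %||% def$mean_speed,
              speed_sd = speed_sd %||% def$speed_sd,
              turn_concentration = turn_concentration %||% def$turn_concentration,
              vertical_sd = vertical_sd %||% def$vertical_sd,
              step_rate = step_rate)
  stopifnot_scalar(out$mean_speed, "mean_speed")
  if (!is.numeric(out$turn_concentration) || out$turn_concentration <= 0)
    stop("'turn_concentration' must be > 0 (Inf = perfectly straight)",
         call. = FALSE)
  structure(out, class = "flight_regime")
}

# one correlated-random-walk step; state: pos (mm), heading (rad), dt (s)
crw_step <- function(pos, heading, regime, dt, bias_fun = NULL) {
  # per-step speed ~ Gamma with mean mean_speed, sd speed_sd (degenerate if 0)
  sp <- if (regime$speed_sd <= 0) regime$mean_speed else {
    shape <- (regime$mean_speed / regime$speed_sd)^2
    rgamma(1, shape = shape, rate = shape / regime$mean_speed)
  }
  turn_sd <- 1 / sqrt(regime$turn_concentration)
  heading <- heading + if (is.finite(turn_sd) && turn_sd > 0)
    rnorm(1, 0, turn_sd) else 0
  if (!is.null(bias_fun)) heading <- bias_fun(pos, heading)
  dz <- rnorm(1, 0, regime$vertical_sd) * dt * 1000
  step_mm <- sp * dt * 1000
  new_pos <- pos + c(cos(heading) * step_mm, sin(heading) * step_mm, dz)
  list(pos = new_pos, heading = heading)
}

#' Simulate a ground-truth 3D flight path
#'
#' A 3D correlated random walk: per-frame horizontal step length is Gamma
#' distributed with mean `mean_speed * dt`; the horizontal heading evolves by
#' wrapped-normal turning angles with the regime's concentration; vertical
#' increments are Gaussian. Positions are exact ground truth in world mm.
#'
#' @param regime a [flight_regime()].
#' @param n_frames number of frames (>= 6).
#' @param volume bounding box, list with `x`, `y`, `z` each a length-2 range
#'   in mm; the walk starts at a random point well inside and is truncated at
#'   the boundary (with a warning) if it escapes.
#' @param dt frame interval in seconds (default 0.032).
#' @param start optional length-3 start position (mm).
#' @param heading0 optional initial heading (rad, in the x-y plane).
#' @param seed RNG seed.
#' @return object of class `ground_truth_path`: data.frame with columns
#'   `frame` (0-based), `x`, `y`, `z` (mm), `regime`, plus attributes
#'   `path_id`, `dt`, `responded`.
#' @export
simulate_trajectory <- function(regime, n_frames, volume =
                                  list(x = c(500, 3500), y = c(9000, 20000),
                                       z = c(-1500, 1500)),
                                dt = 0.032, start = NULL, heading0 = NULL,
                                seed = NULL) {
  stopifnot(inherits(regime, "flight_regime"))
  if (n_frames < 6) stop("'n_frames' must be >= 6", call. = FALSE)
  local_seed(seed, {
    mid <- function(r) r[1] + (0.3 + 0.4 * runif(1)) * diff(r)
    pos <- start %||% c(mid(volume$x), mid(volume$y), mid(volume$z))
    heading <- heading0 %||% runif(1, 0, 2 * pi)
    out <- matrix(NA_real_, n_frames, 3)
    out[1, ] <- pos
    truncated <- FALSE
    for (i in seq_len(n_frames - 1)) {
      st <- crw_step(pos, heading, regime, dt)
      p <- st$pos
      clamped <- pmin(pmax(p, c(volume$x[1], volume$y[1], volume$z[1])),
                      c(volume$x[2], volume$y[2], volume$z[2]))
      if (any(clamped != p)) {
        truncated <- TRUE
        out <- out[seq_len(i), , drop = FALSE]
        break
      }
      pos <- p; heading <- st$heading
      out[i + 1, ] <- pos
    }
    if (truncated)
      warning("path truncated at the volume boundary (", nrow(out),
              " of ", n_frames, " frames kept)")
    structure(
      data.frame(frame = seq_len(nrow(out)) - 1L,
                 x = out[, 1], y = out[, 2], z = out[, 3],
                 regime = regime$name),
      path_id = NA_integer_, dt = dt, responded = FALSE,
      class = c("ground_truth_path", "data.frame"))
  })
}

#' Apply a deterrent response to a ground-truth path
#'
#' At each frame where the local sound pressure level meets the response
#' threshold, the bat switches (once, with probability `switch_prob`) to the
#' commuting regime and its heading is biased away from the source; the path
#' is re-simulated from the switch frame onward. This is the minimal
#' mechanism producing the three observed deterrent effects: higher speed,
#' lower tortuosity, greater distance from the speakers.
#'
#' @param path a [simulate_trajectory()] output.
#' @param field a [sound_field_params()] defining SPL over the scene.
#' @param response list with `spl_threshold` (dB), `switch_prob` (0-1) and
#'   `away_bias` (0-1, per-step pull of the heading toward the away-from-
#'   source direction).
#' @param commuting the regime switched into (default [flight_regime()]
#'   `"commuting"`).
#' @param seed RNG seed.
#' @return a `ground_truth_path`; attribute `responded` records whether the
#'   switch happened, and the `regime` column flags post-switch frames.
#' @export
apply_deterrent_response <- function(path, field,
                                     response = list(spl_threshold = 40,
                                                     switch_prob = 1,
                                                     away_bias = 0.3),
                                     commuting = flight_regime("commuting"),
                                     seed = NULL) {
  stopifnot(inherits(path, "ground_truth_path"))
  if (response$switch_prob <= 0) return(path)
  dt <- attr(path, "dt")
  local_seed(seed, {
    spl <- spl_at_position(field, as.matrix(path[, c("x", "y", "z")]))
    hot <- which(spl >= response$spl_threshold)
    if (!length(hot)) return(path)
    trigger <- NA_integer_
    for (i in hot) {
      if (runif(1) < response$switch_prob) { trigger <- i; break }
    }
    if (is.na(trigger)) return(path)

    src <- field$position
    if (!is.null(dim(src))) src <- src[1, ]
    bias_fun <- function(pos, heading) {
      away <- atan2(pos[2] - src[2], pos[1] - src[1])
      d <- ((away - heading + pi) %% (2 * pi)) - pi
      heading + response$away_bias * d
    }
    pos <- as.numeric(path[trigger, c("x", "y", "z")])
    heading <- if (trigger > 1) {
      atan2(path$y[trigger] - path$y[trigger - 1],
            path$x[trigger] - path$x[trigger - 1])
    } else runif(1, 0, 2 * pi)
    n <- nrow(path)
    out <- path
    for (i in seq(trigger, n - 1)) {
      st <- crw_step(pos, heading, commuting, dt, bias_fun)
      pos <- st$pos; heading <- st$heading
      out[i + 1, c("x", "y", "z")] <- as.list(pos)
      out$regime[i + 1] <- commuting$name
    }
    attr(out, "responded") <- TRUE
    out
  })
}
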