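# Deterrent sound-field model: spherical spreading plus ISO 9613-1
# pure-tone atmospheric absorption.

#' Sound-field parameters for a deterrent speaker
#'
#' Bundles the source level, emission frequency, atmospheric state and source
#' position used to predict sound pressure level (SPL) over the scene. The
#' defaults describe an ultrasonic bat deterrent emitting at 98 dB SPL
#' (re 20 uPa) at 1 m with its frequency of maximum energy at 50 kHz, in a
#' cool humid riparian night atmosphere (14 degrees C, 90% relative humidity,
#' 101.325 kPa).
#'
#' @param source_level dB SPL at the 1 m reference distance.
#' @param frequency emission frequency in kHz.
#' @param temperature air temperature in degrees C.
#' @param relative_humidity relative humidity in percent (0-100).
#' @param pressure static pressure in kPa.
#' @param position numeric length-3 source position in the world frame (mm).
#' @return an object of class `sound_field_params`.
#' @export
#' @examples
#' sf <- sound_field_params()
#' spl_at_distance(sf, 15)  # ~52 dB
sound_field_params <- function(source_level = 98, frequency = 50,
                               temperature = 14, relative_humidity = 90,
                               pressure = 101.325,
                               position = c(2000, -15000, 1000)) {
  stopifnot_scalar(frequency, "frequency")
  stopifnot_scalar(pressure, "pressure")
  if (relative_humidity < 0 || relative_humidity > 100)
    stop("'relative_humidity' must be within [0, 100]", call. = FALSE)
  structure(list(source_level = source_level, frequency = frequency,
                 temperature = temperature,
                 relative_humidity = relative_humidity,
                 pressure = pressure, position = as.numeric(position)),
            class = "sound_field_params")
}

#' Atmospheric absorption coefficient (ISO 9613-1)
#'
#' Pure-tone atmospheric absorption from classical (translational/rotational)
#' losses plus the vibrational relaxation of oxygen and nitrogen, following
#' the ISO 9613-1 closed-form expressions.
#'
#' @param frequency frequency in kHz.
#' @param temperature air temperature in degrees C. Valid range -20 to 50.
#' @param relative_humidity relative humidity in percent (0-100).
#' @param pressure static pressure in kPa (valid up to 200 kPa).
#' @return absorption coefficient in dB per metre.
#' @export
#' @examples
#' atmospheric_absorption(50, 14, 90, 101.325)  # ~1.59 dB/m
atmospheric_absorption <- function(frequency, temperature = 14,
                                   relative_humidity = 90,
                                   pressure = 101.325) {
  if (any(frequency < 0))
    stop("'frequency' must be >= 0 kHz", call. = FALSE)
  if (temperature < -20 || temperature > 50)
    stop("'temperature' outside the supported range [-20, 50] C", call. = FALSE)
  if (relative_humidity < 0 || relative_humidity > 100)
    stop("'relative_humidity' must be within [0, 100] %", call. = FALSE)
  if (pressure <= 0 || pressure > 200)
    stop("'pressure' must be in (0, 200] kPa", call. = FALSE)

  f <- frequency * 1000            # Hz
  T <- temperature + 273.15        # K
  T0 <- 293.15                     # reference temperature, K
  T01 <- 273.16                    # triple point, K
  pr <- 101.325                    # reference pressure, kPa

  # molar concentration of water vapour (%)
  psat_pr <- 10^(-6.8346 * (T01 / T)^1.261 + 4.6151)
  h <- relative_humidity * psat_pr * (pr / pressure)

  # relaxation frequencies of oxygen and nitrogen (Hz)
  frO <- (pressure / pr) * (24 + 4.04e4 * h * (0.02 + h) / (0.391 + h))
  frN <- (pressure / pr) * (T / T0)^(-0.5) *
    (9 + 280 * h * exp(-4.170 * ((T / T0)^(-1 / 3) - 1)))

  8.686 * f^2 * (
    1.84e-11 * (pr / pressure) * (T / T0)^0.5 +
      (T / T0)^(-2.5) * (
        0.01275 * exp(-2239.1 / T) / (frO + f^2 / frO) +
          0.1068 * exp(-3352 / T) / (frN + f^2 / frN)))
}

#' Sound pressure level at a distance from the deterrent
#'
#' `L(d) = L_1m - 20 log10(d / 1 m) - alpha (d - 1 m)`: spherical spreading
#' from the 1 m reference plus atmospheric absorption accumulated beyond the
#' reference distance, so the model is exact at 1 m by construction.
#'
#' @param params a [sound_field_params()] object.
#' @param distance distance(s) from the source in metres; must be >= 1.
#' @return SPL in dB (vectorised over `distance`).
#' @export
spl_at_distance <- function(params, distance) {
  stopifnot(inherits(params, "sound_field_params"))
  if (any(distance < 1))
    stop("'distance' must be >= 1 m (model defined from the reference distance outward)",
         call. = FALSE)
  alpha <- atmospheric_absorption(params$frequency, params$temperature,
                                  params$relative_humidity, params$pressure)
  params$source_level - 20 * log10(distance) - alpha * (distance - 1)
}

#' SPL at arbitrary world positions
#'
#' Distance is taken to the nearest source; multiple sources are treated by
#' the nearest-source approximation (no incoherent summation). Positions
#' closer than the 1 m reference are clamped to 1 m.
#'
#' @param params a [sound_field_params()] object (its `position` field may be
#'   a matrix with one row per source, in mm).
#' @param positions numeric matrix, one row per world position (mm).
#' @return numeric vector of SPL values in dB.
#' @export
spl_at_position <- function(params, positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  src <- params$position
  if (is.null(dim(src))) src <- matrix(src, nrow = 1)
  d <- sapply(seq_len(nrow(src)), function(s) {
    sqrt(rowSums((positions - matrix(src[s, ], nrow(positions), 3,
                                     byrow = TRUE))^2)) / 1000
  })
  d <- if (is.null(dim(d))) matrix(d, ncol = nrow(src)) else d
  dmin <- pmax(apply(d, 1, min), 1)
  spl_at_distance(params, dmin)
}

#' SPL coverage map over a scene volume
#'
#' @param params a [sound_field_params()] object.
#' @param x,y,z numeric vectors of grid coordinates (mm, world frame).
#' @return a data.frame with columns `x`, `y`, `z`, `spl_db` (one row per
#'   voxel, x varying fastest).
#' @export
coverage_map <- function(params, x, y, z) {
  grid <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  grid$spl_db <- spl_at_position(params, as.matrix(grid[, c("x", "y", "z")]))
  grid
}

#' SPL-versus-distance table
#'
#' @param params a [sound_field_params()] object.
#' @param distances distances in metres (default 1-45 m).
#' @return data.frame with `distance_m` and `spl_db`.
#' @export
spl_table <- function(params = sound_field_params(),
                      distances = c(1, seq(5, 45, by = 5))) {
  data.frame(distance_m = distances,
             spl_db = spl_at_distance(params, distances))
}
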