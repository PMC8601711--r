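# Ground-truth flight simulation, deterrent response, count and
# call-parameter generators.

test_that("generators are pure functions of seed and parameters", {
  reg <- flight_regime("foraging")
  p1 <- simulate_trajectory(reg, 30, seed = 9)
  p2 <- simulate_trajectory(reg, 30, seed = 9)
  expect_identical(as.data.frame(p1), as.data.frame(p2))

  c1 <- simulate_counts(seed = 9)
  c2 <- simulate_counts(seed = 9)
  expect_identical(c1, c2)

  k1 <- simulate_call_params(n_passes_per_arm = 20, seed = 9)
  k2 <- simulate_call_params(n_passes_per_arm = 20, seed = 9)
  expect_identical(k1, k2)
})

test_that("an infinitely concentrated constant-speed walk is straight", {
  reg <- flight_regime("commuting", speed_sd = 0, turn_concentration = Inf,
                       vertical_sd = 0)
  p <- simulate_trajectory(reg, 20, seed = 1)
  expect_equal(tortuosity_value(p), 0.1, tolerance = 1e-12)
  expect_equal(mean_speed(p), 4.86, tolerance = 1e-9)
})

test_that("foraging paths are more tortuous than commuting paths", {
  tort <- function(name, seed) {
    p <- suppressWarnings(simulate_trajectory(
      flight_regime(name), 40, seed = seed,
      volume = list(x = c(-1e5, 1e5), y = c(-1e5, 1e5), z = c(-1e5, 1e5))))
    tortuosity_value(p)
  }
  n <- 120
  tf <- vapply(seq_len(n), function(s) tort("foraging", 1000 + s), 1)
  tc <- vapply(seq_len(n), function(s) tort("commuting", 2000 + s), 1)
  expect_gt(mean(tf), mean(tc))
  # commuting speeds stochastically dominate foraging in the mean
  ms <- function(name, seed) mean_speed(suppressWarnings(simulate_trajectory(
    flight_regime(name), 40, seed = seed,
    volume = list(x = c(-1e5, 1e5), y = c(-1e5, 1e5), z = c(-1e5, 1e5)))))
  expect_gt(mean(vapply(seq_len(n), function(s) ms("commuting", 3000 + s), 1)),
            mean(vapply(seq_len(n), function(s) ms("foraging", 4000 + s), 1)))
})

test_that("a too-small volume truncates with a warning, never silently", {
  reg <- flight_regime("commuting")
  expect_warning(
    p <- simulate_trajectory(reg, 60, seed = 2,
                             volume = list(x = c(1900, 2100),
                                           y = c(9000, 9600),
                                           z = c(-200, 200))),
    "truncated")
  expect_lt(nrow(p), 60)
})

test_that("deterrent response is identity when disabled or out of reach", {
  sf <- sound_field_params()
  p <- simulate_trajectory(flight_regime("foraging"), 30, seed = 5)
  same <- apply_deterrent_response(
    p, sf, response = list(spl_threshold = 40, switch_prob = 0,
                           away_bias = 0.5), seed = 1)
  expect_identical(as.data.frame(same), as.data.frame(p))
  high <- apply_deterrent_response(
    p, sf, response = list(spl_threshold = 200, switch_prob = 1,
                           away_bias = 0.5), seed = 1)
  expect_identical(as.data.frame(high), as.data.frame(p))
  expect_false(attr(high, "responded"))
})

test_that("responsive bats end further from the source than unresponsive ones", {
  sf <- sound_field_params(position = c(2000, -15000, 1000))
  n <- 60
  dist_to_src <- function(p) {
    last <- as.numeric(p[nrow(p), c("x", "y", "z")])
    sqrt(sum((last - sf$position)^2)) / 1000
  }
  vol <- list(x = c(-1e5, 1e5), y = c(-1e5, 1e5), z = c(-1e5, 1e5))
  d_resp <- d_null <- numeric(n)
  for (s in seq_len(n)) {
    p <- suppressWarnings(simulate_trajectory(flight_regime("foraging"), 50,
                                              seed = 100 + s, volume = vol,
                                              start = c(2000, 12000, 0)))
    r <- apply_deterrent_response(
      p, sf, response = list(spl_threshold = 10, switch_prob = 1,
                             away_bias = 0.8), seed = 200 + s)
    expect_true(attr(r, "responded"))
    d_resp[s] <- dist_to_src(r)
    d_null[s] <- dist_to_src(p)
  }
  expect_gt(mean(d_resp), mean(d_null))
})

test_that("rendered blob centroids sit on the projected positions", {
  rig <- small_rig()
  p <- straight_path(8, start = c(1000, 12000, 0), direction = c(1, 0.3, 0))
  sc <- render_frames(list(p), rig,
                      noise = list(background_sd = 0, clutter_rate = 0),
                      seed = 1)
  expect_equal(nrow(sc$truth), 2 * 8)   # both cameras, all frames visible
  # with zero noise each frame holds exactly one blob at the projection
  det <- detect_stack(sc$left, 0.05, "left")
  expect_equal(nrow(det), 8)
  m <- merge(det, sc$truth[sc$truth$camera == "left", ], by = "frame")
  expect_lt(max(abs(m$u.x - m$u.y)), 0.05)
  expect_lt(max(abs(m$v.x - m$v.y)), 0.05)
})

test_that("same seed renders bit-identical stacks", {
  rig <- small_rig()
  p <- test_paths(1, 8, seed = 77)
  a <- render_frames(p, rig, noise = list(clutter_rate = 2), seed = 9)
  b <- render_frames(p, rig, noise = list(clutter_rate = 2), seed = 9)
  expect_identical(a$left, b$left)
  expect_identical(a$right, b$right)
})

test_that("counts follow the design and the requested effect size", {
  cc <- simulate_counts(seed = 31)
  # alternating blocks, control first, 12 per night
  one <- cc[cc$series == "pygmaeus_pass" & cc$night == 1, ]
  expect_equal(one$treatment, rep(c("control", "deterrent"), 6))
  expect_equal(nrow(one), 12)
  # Poisson limit: mean within 2% of baseline over many blocks
  p0 <- count_sim_params(baseline_rate = c(a_pass = 50),
                         deterrent_rate_ratio = c(a_pass = 1),
                         dispersion = Inf, sd_site = 0, sd_night = 0,
                         sd_block = 0, n_sites = 5, n_nights_per_site = 10,
                         n_blocks_per_night = 40)
  cp <- simulate_counts(p0, seed = 32)
  expect_equal(mean(cp$count), 50, tolerance = 0.02)
  # rate ratio 0.70 -> treated/control mean ratio ~0.70
  p1 <- count_sim_params(baseline_rate = c(a_pass = 50),
                         deterrent_rate_ratio = c(a_pass = 0.70),
                         dispersion = Inf, sd_site = 0, sd_night = 0,
                         sd_block = 0, n_sites = 5, n_nights_per_site = 10,
                         n_blocks_per_night = 40)
  c1 <- simulate_counts(p1, seed = 33)
  ratio <- mean(c1$count[c1$treatment == "deterrent"]) /
    mean(c1$count[c1$treatment == "control"])
  expect_equal(ratio, 0.70, tolerance = 0.03)
})

test_that("call records satisfy bandwidth = start - end and the shifts", {
  cp <- simulate_call_params(n_passes_per_arm = 400, seed = 41)
  expect_equal(cp$bandwidth, cp$start_frequency - cp$end_frequency)
  dbw <- mean(cp$bandwidth[cp$treatment == "deterrent"]) -
    mean(cp$bandwidth[cp$treatment == "control"])
  expect_equal(dbw, -5.79, tolerance = 0.8)
  # no-shift generator gives equal arms within Monte-Carlo error
  p0 <- call_param_sim_params(shift_bandwidth = 0, shift_start = 0)
  c0 <- simulate_call_params(p0, n_passes_per_arm = 400, seed = 42)
  d0 <- mean(c0$bandwidth[c0$treatment == "deterrent"]) -
    mean(c0$bandwidth[c0$treatment == "control"])
  expect_lt(abs(d0), 0.8)
})
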