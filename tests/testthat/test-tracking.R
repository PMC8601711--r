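# Stereo pairing, trajectory linking against the brute-force oracle, and
# the QC rules.

test_that("one noiseless bat yields one localisation per frame at truth", {
  rig <- stereo_rig()
  p <- test_paths(1, 12, seed = 61)[[1]]
  P <- as.matrix(p[, c("x", "y", "z")])
  dl <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    uv <- project(P[i, ], rig$left)
    data.frame(camera = "left", frame = p$frame[i], u = uv[1], v = uv[2])
  }))
  dr <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    uv <- project(P[i, ], rig$right)
    data.frame(camera = "right", frame = p$frame[i], u = uv[1], v = uv[2])
  }))
  locs <- pair_stereo(dl, dr, rig)
  expect_equal(nrow(locs), nrow(p))
  expect_equal(locs$x, p$x, tolerance = 1e-6)
  expect_equal(locs$z, p$z, tolerance = 1e-6)
  expect_true(all(locs$residual < 1e-9))
})

test_that("two bats a metre apart at range stay distinct with no swaps", {
  rig <- stereo_rig()
  n <- 100
  pa <- straight_path(n, speed = 4, start = c(1500, 15000, 200))
  pb <- straight_path(n, speed = 4, start = c(2500, 15000, -200))
  mk <- function(p, cam, label) {
    uv <- project(as.matrix(p[, c("x", "y", "z")]), rig[[cam]])
    data.frame(camera = cam, frame = p$frame, u = uv[, 1], v = uv[, 2],
               truth = label)
  }
  dl <- rbind(mk(pa, "left", "a"), mk(pb, "left", "b"))
  dr <- rbind(mk(pa, "right", "a"), mk(pb, "right", "b"))
  locs <- pair_stereo(dl, dr, rig)
  expect_equal(nrow(locs), 2 * n)
  # identity audit: every localisation pairs same-bat detections
  expect_equal(dl$truth[locs$det_left], dr$truth[locs$det_right])
})

test_that("a detection in one camera only yields no localisation", {
  rig <- stereo_rig()
  dl <- data.frame(camera = "left", frame = 0, u = 320, v = 240)
  dr <- dl[0, ]
  expect_equal(nrow(pair_stereo(dl, dr, rig)), 0)
})

test_that("linking honours the published parameter set", {
  lp <- linking_params()
  mkloc <- function(frames, step_mm) {
    data.frame(frame = frames, x = 2000 + step_mm * seq_along(frames),
               y = 15000, z = 0, residual = 0)
  }
  # 7 consecutive localisations 100 mm apart -> one trajectory of 7
  t7 <- build_trajectories(mkloc(0:6, 100), lp)
  expect_equal(length(t7), 1)
  expect_equal(nrow(t7[[1]]), 7)
  # 5 localisations only -> below the minimum length
  expect_equal(length(build_trajectories(mkloc(0:4, 100), lp)), 0)
  # a 1200 mm step is never linked
  far <- data.frame(frame = 0:7, x = c(rep(2000, 4), rep(3200, 4)),
                    y = 15000, z = 0, residual = 0)
  expect_equal(length(build_trajectories(far, lp)), 0)
  # a 16-frame gap splits the candidates
  gap <- mkloc(c(0:6, 23:29), 10)
  tg <- build_trajectories(gap, lp)
  expect_equal(sort(vapply(tg, nrow, 1L)), c(7L, 7L))
  # the speed gate binds even within max_step: 600 mm in one frame = 18.75 m/s
  fast <- mkloc(0:6, 600)
  expect_equal(length(build_trajectories(fast, lp)), 0)
})

test_that("recovered partitions equal ground truth and the brute-force oracle", {
  lp <- linking_params()
  for (cfg in list(list(n_bats = 2, n_frames = 8, seed = 71),
                   list(n_bats = 3, n_frames = 6, seed = 72))) {
    paths <- test_paths(cfg$n_bats, cfg$n_frames, seed = cfg$seed)
    locs <- gt_localisations(paths)
    got <- build_trajectories(locs[order(locs$frame), ], lp)
    oracle <- link_bruteforce(locs, lp)
    truth <- lapply(paths, function(p)
      data.frame(frame = p$frame, x = p$x, y = p$y, z = p$z))
    expect_equal(partition_of(got), partition_of(truth))
    expect_equal(partition_of(oracle), partition_of(truth))
  }
})

test_that("every emitted trajectory satisfies the linking invariants", {
  lp <- linking_params()
  withr::with_seed(73, {
    for (rep in 1:5) {
      # jittered two-bat scene with dropped frames
      paths <- test_paths(2, 15, seed = 700 + rep)
      locs <- gt_localisations(paths)
      locs <- locs[runif(nrow(locs)) > 0.15, ]     # random dropouts
      locs$x <- locs$x + rnorm(nrow(locs), 0, 10)  # 1 cm noise
      trajs <- build_trajectories(locs[order(locs$frame), ], lp)
      for (tr in trajs) {
        expect_true(stereobat:::assert_trajectory(tr, lp))
      }
    }
  })
})

test_that("shared-point QC applies the more-than-three rule exactly", {
  base <- data.frame(frame = 0:9, x = seq(0, 900, by = 100), y = 15000,
                     z = 0, residual = 0)
  other3 <- base; other3$x <- other3$x + c(rep(0, 3), rep(5000, 7))
  other4 <- base; other4$x <- other4$x + c(rep(0, 4), rep(5000, 6))
  keep3 <- qc_shared_points(list(base, other3))
  expect_equal(length(keep3), 2)       # 3 shared points: both retained
  expect_equal(attr(keep3[[1]], "shared_points"), 3L)
  expect_equal(length(qc_shared_points(list(base, other4))), 0)  # 4 shared
  expect_equal(length(qc_shared_points(list(base))), 1)
})

test_that("speed-consistency flags >3 m/s jumps, boundary passes", {
  mk <- function(speeds) {
    # consecutive frames, dt 0.032: step = speed * 32 mm
    x <- cumsum(c(0, speeds * 32))
    data.frame(frame = seq_along(x) - 1, x = x, y = 15000, z = 0)
  }
  expect_true(qc_speed_consistency(mk(c(4, 4, 4, 4)))$pass)
  r <- qc_speed_consistency(mk(c(4, 4, 7.5, 7.5)))
  expect_false(r$pass)
  expect_true(qc_speed_consistency(mk(c(4, 4, 6.9, 6.9)))$pass)
  expect_error(qc_speed_consistency(mk(5)), ">= 3")
})

test_that("smoothing removes an isolated outlier but rejects heavy distortion", {
  clean <- straight_path(20, speed = 5)
  clean <- data.frame(frame = clean$frame, x = clean$x, y = clean$y,
                      z = clean$z)
  out <- smooth_trajectory(clean)
  expect_equal(attr(out, "n_removed"), 0L)
  expect_equal(out$y, clean$y)

  one <- clean; one$x[10] <- one$x[10] + 800   # single displaced point
  sm <- smooth_trajectory(one)
  expect_equal(attr(sm, "n_removed"), 1L)
  expect_equal(sm$x, clean$x[-10])

  three <- clean
  three$x[c(5, 10, 15)] <- three$x[c(5, 10, 15)] + 800  # 15% erroneous
  expect_null(smooth_trajectory(three))
})
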