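# Calibration target construction, blob-to-bulb identification, and stereo
# calibration recovery from simulated target sequences.

test_that("the target has 30 bulbs with one three-pair arm", {
  tg <- calibration_target()
  expect_equal(nrow(tg), 30)
  expect_equal(sum(tg$arm == "my"), 6)
  expect_equal(attr(tg, "bulb_diameter_mm"), 11)
  # the paired arm is the only arm of six
  expect_equal(as.numeric(table(tg$arm)[c("px", "py", "mx")]), c(8, 8, 8))
})

test_that("a simulated default sequence has 24 poses", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, seed = 3)
  expect_equal(length(unique(sim$observations$pose_id)), 24)
})

test_that("noiseless poses are identified 30/30, in any orientation", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, seed = 11)
  obs <- sim$observations
  withr::with_seed(4, {
    for (p in c(1, 5, 9, 17)) {    # spans all three tilt configurations
      d <- obs[obs$pose_id == p & obs$camera == "left", ]
      shuf <- d[sample(nrow(d)), ]
      got <- identify_target(cbind(shuf$u, shuf$v))
      expect_false(is.null(got))
      m <- merge(got, d, by = "bulb_id")
      expect_equal(m$u.x, m$u.y, tolerance = 1e-9)
      expect_equal(m$v.x, m$v.y, tolerance = 1e-9)
    }
  })
})

test_that("identification survives missing bulbs but rejects < 25", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, seed = 12)
  d <- sim$observations[sim$observations$pose_id == 2 &
                          sim$observations$camera == "right", ]
  withr::with_seed(5, {
    keep <- sort(sample(30, 27))
    got <- identify_target(cbind(d$u[keep], d$v[keep]))
    expect_false(is.null(got))
    expect_equal(got$bulb_id, d$bulb_id[keep][order(d$bulb_id[keep])])
    expect_warning(out20 <- identify_target(cbind(d$u[1:20], d$v[1:20])),
                   "fewer than 25")
    expect_null(out20)
  })
})

test_that("noiseless calibration recovers the rig almost exactly", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, n_poses = 24, seed = 21)
  cal <- calibrate_stereo(sim$observations)
  f_true <- rig$left$intrinsics$fx
  expect_lt(abs(cal$left$intrinsics$fx - f_true) / f_true, 1e-3)
  expect_lt(abs(cal$right$intrinsics$fy - f_true) / f_true, 1e-3)
  expect_lt(attr(cal, "rms_px"), 0.01)
  expect_equal(cal$baseline_mm, rig$baseline_mm, tolerance = 1)
  # the recovered rotations remain orthonormal
  for (cm in list(cal$left, cal$right)) {
    R <- cm$extrinsics$R
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
  }
})

test_that("pixel noise degrades reprojection gracefully", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, n_poses = 24, pixel_noise = 0.5,
                                       seed = 22)
  cal <- calibrate_stereo(sim$observations)
  expect_lte(attr(cal, "rms_px"), 1)
})

test_that("too few or degenerate poses are refused", {
  rig <- stereo_rig()
  sim <- simulate_calibration_sequence(rig, n_poses = 24, seed = 23)
  few <- sim$observations[sim$observations$pose_id <= 5, ]
  expect_error(calibrate_stereo(few), ">= 10 poses")

  # frontal-parallel poses only: intrinsics unidentifiable
  tg <- calibration_target()
  XY <- as.matrix(tg[, c("X", "Y", "Z")])
  R0 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  obs <- do.call(rbind, lapply(1:12, function(p) {
    ctr <- c(2000, 12000 + 500 * p, 0)
    Pw <- XY %*% t(R0) + matrix(ctr, nrow(XY), 3, byrow = TRUE)
    do.call(rbind, lapply(c("left", "right"), function(cn) {
      uv <- project(Pw, rig[[cn]])
      data.frame(pose_id = p, camera = cn, bulb_id = tg$bulb_id,
                 u = uv[, 1], v = uv[, 2])
    }))
  }))
  expect_error(calibrate_stereo(obs), "degenerate pose set")
})
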