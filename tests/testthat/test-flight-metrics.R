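# Per-trajectory flight variables.

test_that("instantaneous speeds follow distance over gap-scaled time", {
  tr <- data.frame(frame = c(0, 1, 3), x = c(0, 160, 480),
                   y = 0, z = 0)
  v <- instantaneous_speeds(tr, dt = 0.032)
  expect_equal(v, c(5, 5))          # 0.16 m in 1 frame; 0.32 m in 2 frames
  expect_equal(instantaneous_speeds(data.frame(frame = 0:1, x = 0,
                                               y = c(0, 0), z = 0)), 0)
  expect_error(instantaneous_speeds(tr[1, ]), ">= 2")
})

test_that("mean speed is the mean of instantaneous speeds", {
  tr <- data.frame(frame = 0:3, x = cumsum(c(0, 4, 5, 6)) * 32,
                   y = 0, z = 0)
  expect_equal(mean_speed(tr), 5)
  p <- straight_path(10, speed = 4.86)
  expect_equal(mean_speed(p), 4.86, tolerance = 1e-12)
})

test_that("total length and net displacement obey the geometry", {
  line <- data.frame(frame = 0:10, x = seq(0, 1000, by = 100), y = 0, z = 0)
  expect_equal(total_length_and_net(line), c(total = 1, net = 1))
  outback <- data.frame(frame = 0:10,
                        x = c(seq(0, 500, by = 100), seq(400, 0, by = -100)),
                        y = 0, z = 0)
  expect_equal(total_length_and_net(outback), c(total = 1, net = 0))
  ell <- data.frame(frame = 0:2, x = c(0, 300, 300), y = c(0, 0, 400), z = 0)
  expect_equal(total_length_and_net(ell), c(total = 0.7, net = 0.5))
})

test_that("tortuosity is (total/net)/10 with the straight-line floor", {
  line <- data.frame(frame = 0:5, x = seq(0, 500, by = 100), y = 0, z = 0)
  expect_identical(tortuosity_value(line), 0.1)
  twice <- data.frame(frame = 0:2, x = c(0, 2000, 2000),
                      y = c(0, 0, -2000), z = 0)
  # total 4 m, net 2*sqrt(2) m ... construct exactly total 4, net 2:
  zig <- data.frame(frame = 0:2, x = c(0, 2000, 0), y = c(0, 1000, 2000),
                    z = 0)
  tn <- total_length_and_net(zig)
  expect_equal(tortuosity_value(zig), (tn[["total"]] / tn[["net"]]) / 10)
  outback <- data.frame(frame = 0:2, x = c(0, 500, 0), y = 0, z = 0)
  expect_message(tv <- tortuosity_value(outback), "excluded")
  expect_true(is.na(tv))
})

test_that("distance from the deterrent adds the speaker offset to mean y", {
  tr <- data.frame(frame = 0:3, x = 0, y = 10000, z = c(0, 500, 1000, 1500))
  dh <- distance_and_height(tr)
  expect_equal(unname(dh), c(10, 25, 0.75))
  # start of the stereo FOV sits ~20 m from the speakers
  fov <- data.frame(frame = 0:1, x = 0, y = 5470, z = 0)
  expect_equal(distance_and_height(fov)[["distance_from_deterrent"]], 20.47)
  expect_equal(distance_and_height(tr, deterrent_offset = 0)[["distance_from_deterrent"]],
               10)
})

test_that("total length dominates net displacement and floors tortuosity", {
  withr::with_seed(91, {
    for (i in 1:20) {
      p <- suppressWarnings(simulate_trajectory(
        flight_regime("foraging"), 25, seed = 900 + i,
        volume = list(x = c(-1e5, 1e5), y = c(-1e5, 1e5), z = c(-1e5, 1e5))))
      tn <- total_length_and_net(p)
      expect_gte(tn[["total"]], tn[["net"]])
      tv <- tortuosity_value(p)
      if (!is.na(tv)) expect_gte(tv, 0.1 - 1e-12)
    }
  })
})

test_that("metrics shift correctly under rigid translation", {
  p <- test_paths(1, 15, seed = 95)[[1]]
  shifted <- p
  shifted$x <- p$x + 500; shifted$y <- p$y + 2000; shifted$z <- p$z - 300
  m0 <- trajectory_metrics(list(p))
  m1 <- trajectory_metrics(list(shifted))
  expect_equal(m1$mean_speed, m0$mean_speed)
  expect_equal(m1$total_length, m0$total_length)
  expect_equal(m1$tortuosity_value, m0$tortuosity_value)
  expect_equal(m1$mean_y, m0$mean_y + 2)
  expect_equal(m1$distance_from_deterrent, m0$distance_from_deterrent + 2)
  expect_equal(m1$mean_height, m0$mean_height - 0.3)
})
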