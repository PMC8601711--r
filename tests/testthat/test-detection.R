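# Background subtraction, blob detection and threshold selection.

blank <- function(h = 60, w = 80, level = 0) matrix(level, h, w)

blob_frame <- function(u, v, sigma = 1.5, amp = 1, h = 60, w = 80) {
  fr <- blank(h, w)
  stereobat:::add_blob(fr, u, v, sigma, amp)
}

test_that("a static scene differences to zero in both modes", {
  stack <- replicate(5, blank(level = 0.3), simplify = FALSE)
  adj <- background_subtract(stack, "adjacent_frame")
  expect_true(all(vapply(adj$frames, max, 1) == 0))
  med <- background_subtract(stack, "rolling_median")
  expect_true(all(vapply(med$frames, max, 1) == 0))
  expect_error(background_subtract(stack[1], "adjacent_frame"), ">= 2")
})

test_that("adjacent differencing leaves old and new blob positions", {
  # displacement larger than the blob width
  stack <- list(blob_frame(20, 30), blob_frame(50, 30))
  adj <- background_subtract(stack, "adjacent_frame")
  det <- threshold_detect(adj$frames[[1]], 0.1)
  expect_equal(nrow(det), 2)
  expect_equal(sort(det$u), c(20, 50), tolerance = 0.1)
})

test_that("median background isolates a transient blob", {
  stack <- c(replicate(6, blank(level = 0.2), simplify = FALSE),
             list(blank(level = 0.2) + blob_frame(40, 25)))
  med <- background_subtract(stack, "rolling_median")
  det <- threshold_detect(med$frames[[7]], 0.1)
  expect_equal(nrow(det), 1)
  expect_equal(c(det$u, det$v), c(40, 25), tolerance = 0.05)
})

test_that("thresholding filters by intensity and area with sub-pixel centroids", {
  fr <- blob_frame(33.4, 21.7, amp = 1)
  expect_equal(nrow(threshold_detect(fr, 2)), 0)         # above max intensity
  det <- threshold_detect(fr, 0.1)                       # amplitude 10x threshold
  expect_equal(nrow(det), 1)
  expect_equal(c(det$u, det$v), c(33.4, 21.7), tolerance = 0.1)
  # two separated blobs -> two detections
  fr2 <- stereobat:::add_blob(fr, 60, 40, 1.5, 1)
  expect_equal(nrow(threshold_detect(fr2, 0.1)), 2)
  # single-pixel noise rejected by the area filter
  fr3 <- blank(); fr3[10, 10] <- 1
  expect_equal(nrow(threshold_detect(fr3, 0.1, min_blob_area = 2)), 0)
})

test_that("raising the threshold never increases detections", {
  withr::with_seed(8, {
    fr <- blob_frame(20, 20) + blob_frame(55, 45, amp = 0.4) +
      matrix(abs(rnorm(60 * 80, 0, 0.05)), 60, 80)
    counts <- vapply(c(0.05, 0.1, 0.2, 0.35, 0.6, 1.1),
                     function(th) nrow(threshold_detect(fr, th)), 1L)
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("threshold selection suppresses clutter and keeps true tracks", {
  rig <- small_rig()
  paths <- test_paths(2, 14, seed = 55)
  sc <- render_frames(paths, rig,
                      noise = list(background_sd = 0, blob_amplitude = 0.6,
                                   clutter_rate = 3, clutter_amplitude = 0.25),
                      seed = 56)
  sel <- select_threshold(sc$left, sc$right, rig,
                          candidate_thresholds = c(0.1, 0.4))
  expect_equal(sel$threshold, 0.4)   # above clutter, below bat amplitude
  d <- sel$diagnostics
  expect_equal(d$n_trajectories[d$threshold == 0.4], 2)
  # single candidate returned trivially
  expect_equal(select_threshold(sc$left, sc$right, rig, 0.4)$threshold, 0.4)
})

test_that("equal scores resolve to the higher threshold", {
  rig <- small_rig()
  paths <- test_paths(1, 10, seed = 57)
  sc <- render_frames(paths, rig,
                      noise = list(background_sd = 0, clutter_rate = 0),
                      seed = 58)
  # both thresholds sit below the blob amplitude: identical outcomes
  sel <- select_threshold(sc$left, sc$right, rig, c(0.1, 0.2))
  expect_equal(sel$threshold, 0.2)
})
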