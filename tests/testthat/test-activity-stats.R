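# Pass counting, block aggregation, composition arithmetic, AICc/LRT, and
# the mixed-model fits on simulated data.

test_that("pass counting applies the one-second gap rule", {
  expect_equal(count_passes(c(0, 0.2, 0.5, 2.0)), 2)
  expect_equal(count_passes(c(0, 0.9, 1.8, 2.7)), 1)   # all gaps <= 1 s
  expect_equal(count_passes(numeric(0)), 0L)
  expect_equal(count_passes(c(0, 1.0, 2.0)), 1)        # boundary: gap == 1 s
  expect_error(count_passes(c(2, 1)), "sorted")
})

test_that("block aggregation drops the first minute and sums the rest", {
  files <- expand.grid(site = 1, night = 1, block = 1:2, file_index = 1:30)
  files$count <- 1
  agg <- aggregate_blocks(files)
  expect_equal(agg$count, c(24, 24))
  # events only in the first six files contribute nothing
  f2 <- files; f2$count <- ifelse(f2$file_index <= 6, 5, 0)
  expect_equal(aggregate_blocks(f2)$count, c(0, 0))
  # malformed block is named
  expect_error(aggregate_blocks(files[files$file_index <= 29 |
                                        files$block == 2, ]),
               "without exactly 30 files")
})

test_that("composition arithmetic reproduces printed-count examples", {
  counts <- data.frame(
    species_group = c("pygmaeus", "myotis", "pipistrellus", "other"),
    count = c(4304, 727, 323, 86))
  tab <- composition_table(counts, n_nights = 9)
  expect_equal(tab$percent[tab$species_group == "pygmaeus"], 79.12)
  expect_equal(attr(tab, "grand_total"), 5440)
  expect_equal(sum(tab$total) / 9, 604.44, tolerance = 0.001)
  expect_equal(sum(tab$percent), 100, tolerance = 0.01)
  single <- composition_table(data.frame(species_group = "a", count = 10),
                              n_nights = 2)
  expect_equal(single$percent, 100)
})

test_that("percent reduction handles both directions and the model form", {
  blocks <- data.frame(treatment = rep(c("control", "deterrent"), each = 2),
                       count = c(60, 40, 35, 35))
  pr <- percent_reduction(blocks, beta_treatment = log(0.7))
  expect_equal(unname(pr["raw_percent"]), 30)
  expect_equal(unname(pr["model_percent"]), 30, tolerance = 1e-9)
  inc <- data.frame(treatment = c("control", "deterrent"), count = c(50, 60))
  expect_equal(unname(percent_reduction(inc)["raw_percent"]), -20)
  expect_equal(unname(percent_reduction(
    data.frame(treatment = c("control", "deterrent"),
               count = c(50, 50)))["raw_percent"]), 0)
})

test_that("AICc arithmetic and the >2 selection rule", {
  expect_equal(aicc(-50, 2, 10), 104 + 12 / 7)
  expect_error(aicc(-50, 9, 10), "n > k")
  # fabricate two fits via lm on the same data
  withr::with_seed(13, {
    d <- data.frame(x = rnorm(40), g = rnorm(40))
    d$y <- 1 + 0.1 * d$x + rnorm(40)
    simple <- stats::lm(y ~ 1, d)
    rich <- stats::lm(y ~ x + g, d)
    sel <- model_select(list(null = simple, full = rich))
    # a weak predictor cannot beat the >2 AICc hurdle
    expect_equal(sel$chosen, "null")
  })
})

test_that("the likelihood-ratio test matches the chi-squared tail", {
  withr::with_seed(14, {
    d <- data.frame(x = rnorm(100))
    d$y <- 2 + 0.8 * d$x + rnorm(100)
    full <- stats::lm(y ~ x, d)
    red <- stats::lm(y ~ 1, d)
    out <- lrt(full, red)
    expect_equal(unname(out["df"]), 1)
    expect_equal(unname(out["p"]),
                 pchisq(unname(out["chisq"]), 1, lower.tail = FALSE))
    expect_error(lrt(red, full), "nested")
    expect_error(lrt(full, stats::lm(y ~ 1, d[1:50, ])), "same data")
  })
})

test_that("count model recovers a known rate ratio and refuses sparse groups", {
  cb <- simulate_counts(count_sim_params(
    baseline_rate = c(a_pass = 46.5),
    deterrent_rate_ratio = c(a_pass = 0.70)), seed = 101)
  m <- suppress_fit_noise(fit_count_model(cb))
  expect_true(m$family %in% c("poisson", "negative binomial"))
  # single replicate: a plausible-range check (mean recovery over many
  # replicates is asserted in the acceptance suite)
  expect_gt(m$rate_ratio, 0.5)
  expect_lt(m$rate_ratio, 0.9)
  expect_lt(m$p, 0.05)
  expect_equal(sum(m$random$percent), 100, tolerance = 1e-6)
  # sparse group: fewer than 20 events per night in most nights
  sparse <- simulate_counts(count_sim_params(
    baseline_rate = c(a_pass = 0.5),
    deterrent_rate_ratio = c(a_pass = 0.7)), seed = 102)
  expect_error(fit_count_model(sparse), "refused")
})

test_that("call-parameter model recovers the bandwidth shift with adjustment", {
  cp <- simulate_call_params(n_passes_per_arm = 150, seed = 103)
  m <- suppress_fit_noise(fit_call_param_model(cp, "bandwidth"))
  est <- m$fixed$estimate[m$fixed$term == "treatmentdeterrent"]
  expect_equal(est, -5.79, tolerance = 0.8)
  expect_equal(m$p_adjusted, min(1, m$p * 6))
  # Bonferroni arithmetic and property
  expect_equal(min(1, 0.01 * 6), 0.06)
  expect_gte(m$p_adjusted, m$p)
})

test_that("trajectory models run across all five responses", {
  withr::with_seed(104, {
    n <- 300
    d <- data.frame(site = sample(1:3, n, TRUE),
                    block = sample(1:12, n, TRUE))
    d$night <- (d$site - 1) * 3 + sample(1:3, n, TRUE)
    d$treatment <- ifelse(d$block %% 2 == 1, "control", "deterrent")
    tr_eff <- d$treatment == "deterrent"
    d$mean_speed <- rnorm(n, 4.54 + 0.32 * tr_eff, 0.95)
    d$distance_from_deterrent <- rnorm(n, 14 + 1.6 * tr_eff, 4)
    d$mean_height <- rnorm(n, 0.5, 1.5)
    d$total_length <- rlnorm(n, 0.8, 0.5)
    d$tortuosity_value <- pmin(0.97, pmax(0.03,
      rbeta(n, 5, 35) + 0.015 * !tr_eff))
    fits <- suppress_fit_noise(fit_trajectory_models(d))
    expect_named(fits, c("speed", "distance", "height", "length",
                         "tortuosity"))
    # with the treatment x distance interaction the treatment effect is
    # evaluated at the mean distance
    fx <- fits$speed$fixed
    est <- fx$estimate[fx$term == "treatmentdeterrent"] +
      fx$estimate[fx$term == "treatmentdeterrent:distance"] *
        mean(d$distance_from_deterrent)
    expect_equal(est, 0.32, tolerance = 0.5)
    expect_equal(fits$tortuosity$family, "beta")
    expect_false(is.null(fits$height$boxcox_lambda))
    # degenerate tortuosity: all straight lines
    d2 <- d; d2$tortuosity_value <- 0.1
    expect_error(suppress_fit_noise(
      fit_trajectory_models(d2, responses = "tortuosity")), "degenerate")
  })
})

test_that("null count simulations keep the treatment LRT near nominal size", {
  # small calibration run; the acceptance suite uses many more replicates
  p_null <- count_sim_params(baseline_rate = c(a_pass = 46.5),
                             deterrent_rate_ratio = c(a_pass = 1),
                             dispersion = Inf, sd_site = 0, sd_night = 0,
                             sd_block = 0)
  ps <- vapply(1:60, function(r) {
    cb <- simulate_counts(p_null, seed = 5000 + r)
    suppress_fit_noise(fit_count_model(cb))$p
  }, 1)
  # 60 replicates: reject if wildly off nominal
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(mean(ps < 0.5), 0.2)
})
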