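test_that("booster envelope is zero at the booster instant, rises to 1, matches direct evaluation", {
  expect_identical(booster_envelope(0, 0.2), 0)
  expect_identical(booster_envelope(-15, 0.7), 0)
  expect_equal(booster_envelope(1e6, 0.2), 1, tolerance = 1e-12)
  # direct evaluation of 2(1/(1+e^-5.2) - 1/2)
  expect_equal(booster_envelope(26, 0.2), 2 * (1 / (1 + exp(-5.2)) - 0.5),
               tolerance = 1e-12)
  expect_equal(round(booster_envelope(26, 0.2), 5), 0.98903)
  t <- seq(0.5, 300, by = 0.5)
  v <- booster_envelope(t, 0.31)
  # strictly increasing until floating-point saturation at 1
  expect_true(all(diff(v) > 0 | v[-length(v)] > 1 - 1e-12))
  expect_true(all(v >= 0 & v < 1 + 1e-15))
  expect_error(booster_envelope(NA, 0.2), "non-finite")
  expect_error(booster_envelope(10, -1), "timing_rate")
})

test_that("booster saturation halves at titer 0, decays with titer, rejects negatives", {
  expect_equal(booster_saturation(0, 0.3), 0.5)
  expect_equal(booster_saturation(0, 5), 0.5)
  expect_equal(booster_saturation(1e4, 0.3), 0, tolerance = 1e-12)
  # independent evaluation 1/(1+e^3)
  expect_equal(booster_saturation(10, 0.3), 1 / (1 + exp(3)), tolerance = 1e-12)
  expect_equal(round(booster_saturation(10, 0.3), 5), 0.04743)
  T0 <- seq(0, 18, by = 0.5)
  expect_true(all(diff(booster_saturation(T0, 0.34)) < 0))
  expect_true(all(booster_saturation(T0, 0.34) <= 0.5))
  expect_error(booster_saturation(-1, 0.3), ">= 0")
})

test_that("booster gain composes envelope and saturation; asymptote at titer 0 equals B", {
  expect_identical(booster_gain(5, 0, 7, 0.2, 0.33), 0)
  expect_equal(booster_gain(0, 1e7, 4.5, 0.2, 0.33), 4.5, tolerance = 1e-10)
  # compose the two component oracles
  expect_equal(booster_gain(8, 26, 7, 0.2, 0.33),
               2 * 7 * (2 * (1 / (1 + exp(-0.2 * 26)) - 0.5)) *
                 (1 / (1 + exp(0.33 * 8))),
               tolerance = 1e-12)
  # monotone decreasing in starting titer, single contribution below B
  g <- booster_gain(seq(0, 16, 0.5), 40, 7, 0.2, 0.33)
  expect_true(all(diff(g) < 0))
  expect_true(all(g <= 7))
})

test_that("percent conversions reproduce the reported scale translations and invert", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(-0.55), 100 * (2^-0.55 - 1), tolerance = 1e-12)
  expect_equal(round(percent_change(-0.55)), -32)
  expect_equal(round(percent_change(4.26)), 1816)
  p <- c(-60, -32, 0, 15, 1816)
  expect_equal(percent_change(log2_change(p)), p, tolerance = 1e-10)
  d <- c(-2, -0.55, 0, 0.38, 4.26)
  expect_equal(log2_change(percent_change(d)), d, tolerance = 1e-10)
  expect_equal(daily_to_annual(annual_to_daily(-0.55)), -0.55)
})

test_that("peak day matches a dense grid search and handles degenerate declines", {
  expect_identical(peak_day(2, 0.15, 0), Inf)
  expect_identical(peak_day(2, 0.15, 0.001), Inf)
  # decline so strong the response never rises
  expect_identical(peak_day(1, 0.1, -0.2), 0)
  grid_peak <- function(B, H, D) {
    t <- seq(0, 400, by = 0.01)
    t[which.max(2 * B * (plogis(H * t) - 0.5) + D * t)]
  }
  cases <- list(c(1.5, 0.15, -0.0015), c(8, 0.31, -0.55 / 365),
                c(2, 0.05, -0.002), c(0.5, 0.4, -0.001))
  for (cs in cases)
    expect_equal(peak_day(cs[1], cs[2], cs[3]), grid_peak(cs[1], cs[2], cs[3]),
                 tolerance = 0.1)
})

test_that("trajectory prediction is linear without boosters and clamps at zero", {
  pop <- test_pop()
  donor <- donor_parameters(annual_to_daily(-0.55), 0.3)
  tr <- predict_trajectory(numeric(0), 11, donor, pop, c(0, 365))
  expect_equal(tr$titer, c(11, 10.45))
  expect_equal(tr$titer_unclamped, c(11, 10.45))
  tr0 <- predict_trajectory(numeric(0), 0.2, donor, pop, 365)
  expect_identical(tr0$titer, 0)
  expect_lt(tr0$titer_unclamped, 0)
  expect_error(predict_trajectory(c(30, 10), 5, donor, pop, 50), "sorted")
})

test_that("trajectory predictor agrees with brute-force re-summation on random instances", {
  set.seed(101)
  for (i in 1:100) {
    pop <- population_parameters(
      max_effect = runif(1, 0.5, 9), timing_rate = runif(1, 0.05, 0.6),
      mean_decline = -0.002, sd_decline = 1e-4,
      mean_saturation = 0.3, sd_saturation = 0.05,
      residual_sd = 0.5)
    donor <- donor_parameters(runif(1, -0.004, 0.0005), runif(1, 0.05, 0.8))
    m <- sample(0:6, 1)
    x <- sort(sample(1:900, m))
    baseline <- runif(1, 0, 13)
    days <- sort(sample(0:1000, 12))
    tr <- predict_trajectory(x, baseline, donor, pop, days)
    expect_equal(tr$titer, bf_trajectory(x, baseline, donor, pop, days),
                 tolerance = 1e-10)
  }
})

test_that("clamping is idempotent and removing a booster never raises the trajectory", {
  pop <- test_pop()
  donor <- donor_parameters(-0.003, 0.25)
  x <- c(50, 200, 420)
  days <- 0:600
  tr <- predict_trajectory(x, 2, donor, pop, days)
  expect_true(all(tr$titer >= 0))
  expect_identical(pmax(0, tr$titer), tr$titer)
  for (drop in seq_along(x)) {
    tr2 <- predict_trajectory(x[-drop], 2, donor, pop, days)
    expect_true(all(tr2$titer <= tr$titer + 1e-12))
  }
})

test_that("parameter containers validate their invariants", {
  expect_error(population_parameters(-1, 0.2, -0.001, 1e-4, 0.3, 0.05,
                                     residual_sd = 0.5))
  expect_error(population_parameters(2, 0.2, -0.001, 1e-4, 0.3, 0.05,
                                     cov_decline_saturation = 1,
                                     residual_sd = 0.5),
               "positive semi-definite")
  expect_error(donor_parameters(NA, 0.3))
  expect_error(donor_record("a", c(0, 20, 10), c(1, 2, 3)), "increasing")
  expect_error(donor_record("a", c(0, 20), c(-1, 2)), ">= 0")
  expect_warning(donor_record("a", c(0, 20, 27), c(1, 2, 3)), "14 days")
  expect_warning(donor_record("a", c(0, 20), c(21, 2)), "plausible")
})
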