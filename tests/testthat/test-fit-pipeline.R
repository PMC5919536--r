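# Filters are checked against explicit hand enumerations; fitting stages
# against self-consistency on noise-free data and parameter recovery on
# simulated cohorts whose design satisfies the model assumptions.

test_that("booster-free filter matches hand enumeration on toy schedules", {
  # boosters at 0 and 400, donations every 28 days to day 784
  days <- seq(0, 784, by = 28)
  titers <- round(12 - 0.002 * days)
  rec <- toy_record(days, titers, c(0, 400))
  got <- filter_unboostered(list(rec))
  want <- enumerate_unboostered(days, titers, c(0, 400))
  expect_equal(got$t, want$t)
  expect_equal(got$dtiter, want$dtiter)
  # first compliant measurements: day 112 (after booster 0), day 504 (after 400)
  expect_setequal(unique(got$origin_day), c(112, 504))

  # never boostered: everything usable, origin = first donation
  rec2 <- toy_record(days, titers, numeric(0))
  got2 <- filter_unboostered(list(rec2))
  expect_equal(nrow(got2), length(days) - 1)
  expect_equal(got2$t, days[-1])
  expect_true(all(got2$origin_day == 0))

  # a booster 50 days before the final donation excludes that donation (and
  # the boostered donation itself belongs to the new, excluded era)
  rec3 <- toy_record(c(0, 150, 300, 450, 500), c(10, 10, 9, 9, 12), 450)
  got3 <- filter_unboostered(list(rec3))
  expect_false(500 %in% (got3$t + got3$origin_day))
  expect_equal(got3$t, c(150, 300))
})

test_that("decline fit is exact for a noise-free donor and flags degenerate designs", {
  d <- data.frame(donor_id = "a", t = c(100, 200, 400),
                  dtiter = -0.002 * c(100, 200, 400))
  f <- fit_decline(d)
  expect_equal(f$estimates$mean_decline, -0.002, tolerance = 1e-12)
  expect_equal(f$donor_effects$decline_rate, -0.002, tolerance = 1e-12)
  expect_error(fit_decline(data.frame(donor_id = c("a", "b"), t = c(10, 10),
                                      dtiter = c(1, 2))),
               "distinct time points")
})

test_that("decline fit recovers the generating parameters on a non-informative design", {
  # never-boostered donors, baselines high enough that no trajectory reaches
  # the zero clamp: the random-slope ML estimator sees exactly its model
  cfg <- cohort_config(n_donors = 250, new_donor_boosters = 0,
                       booster_trigger_titer = 0, booster_drop_from_max = 99,
                       established_fraction = 1, established_mean = 13,
                       established_sd = 1, career_meanlog = log(3),
                       career_sdlog = 0.4, max_follow_up = 1825)
  co <- suppressWarnings(simulate_cohort(cfg, seed = 6))
  expect_gt(min(unlist(lapply(co$records, attr, "true_titers"))), 0)
  s1 <- fit_decline(filter_unboostered(co))
  true_mu <- mean(co$parameters$decline_rate) * 365
  expect_lt(abs(s1$estimates$mean_decline_annual - true_mu), 0.07)
  # the residual acts on titer differences: two measurement errors (plus
  # rounding) per observation, partially absorbed by the random slope, so
  # sigma_hat lies between sigma_tot and sqrt(2)*sigma_tot
  sig_tot <- sqrt(0.62^2 + 1 / 12)
  expect_gt(s1$estimates$residual_sd, sig_tot * 0.95)
  expect_lt(s1$estimates$residual_sd, sqrt(2) * sig_tot)
})

test_that("ignoring the donor grouping biases the pooled decline towards zero", {
  co <- cached_cohort(n = 300, seed = 9)
  s1 <- fit_decline(filter_unboostered(co))
  # titer-triggered boostering censors fast decliners: the naive pooled
  # slope is much closer to zero than the random-effects estimate
  expect_gt(s1$details$pooled_slope, s1$estimates$mean_decline)
})

test_that("post-booster extraction matches hand enumeration and its exclusion rules", {
  # boosters at day 0 and 150: the first window is open at 150; the second
  # booster (150 d after the first, above the 100-d exclusion) qualifies too
  rec <- toy_record(c(0, 40, 80, 120, 150, 190), c(9, 10, 11, 11, 10, 11),
                    c(0, 150))
  got <- extract_post_booster(list(rec))
  expect_equal(got$t[got$booster_day == 0], c(40, 80, 120))
  expect_equal(got$dtiter[got$booster_day == 0], c(1, 2, 2))
  expect_equal(got$t[got$booster_day == 150], 40)
  expect_equal(got$dtiter[got$booster_day == 150], 1)

  # boosters at day 0 and 60: the second window is excluded entirely
  rec2 <- toy_record(c(0, 30, 60, 90, 120), c(9, 10, 9, 10, 10), c(0, 60))
  got2 <- extract_post_booster(list(rec2))
  expect_true(all(got2$booster_day == 0))
  expect_equal(got2$t, 30)  # window of booster 0 open at the day-60 booster

  # three boosters, all qualifying: every window is capped by the 200-day
  # horizon, and the first also by the next booster at 300
  days <- seq(0, 1000, by = 40)
  tit <- round(10 + sin(days / 100))
  rec3 <- toy_record(days, tit, c(0, 320, 880))
  got3 <- extract_post_booster(list(rec3))
  expect_equal(got3$t[got3$booster_day == 0], c(40, 80, 120, 160, 200))
  expect_equal(got3$t[got3$booster_day == 320], c(40, 80, 120, 160, 200))
  expect_equal(got3$t[got3$booster_day == 880], c(40, 80, 120))
})

test_that("timing fit recovers exactly from noise-free model data and degrades gracefully", {
  D <- -0.0015
  t <- rep(c(5, 9, 14, 21, 30, 45, 70, 100, 150, 200), each = 3)
  y <- 2 * 2 * (plogis(0.15 * t) - 0.5) + D * t
  f <- fit_timing(data.frame(donor_id = "x", t = t, dtiter = y), D)
  expect_equal(f$estimates$max_effect, 2, tolerance = 1e-6)
  expect_equal(f$estimates$timing_rate, 0.15, tolerance = 1e-6)
  expect_true(f$converged)
  # all lags >= 28 days: H nearly unidentified, fit must not crash
  t2 <- rep(seq(28, 200, by = 14), each = 2)
  set.seed(4)
  y2 <- 2 * 0.4 * (plogis(0.31 * t2) - 0.5) + D * t2 + rnorm(length(t2), 0, 0.6)
  f2 <- fit_timing(data.frame(donor_id = "x", t = t2, dtiter = y2), D)
  expect_true(is.finite(f2$estimates$timing_rate))
  expect_true(is.finite(f2$estimates$peak_day))
})

test_that("peak-change extraction follows the 26-50 day window without excluding later boosters", {
  # donations at 0, 30, 60; boosters at 0 and 30: booster 0 keeps its day-30
  # peak observation even though a further booster intervened
  rec <- toy_record(c(0, 30, 60), c(3, 7, 9), c(0, 30))
  got <- extract_peak_changes(list(rec))
  expect_equal(nrow(got), 1)  # booster 30 is excluded (< 50 d after booster 0)
  expect_equal(got$T0, 3)
  expect_equal(got$dtiter, 4)
  expect_equal(got$t, 30)

  # first measurement in the window is taken, not a later one
  rec2 <- toy_record(c(0, 28, 40, 55), c(10, 11, 12, 11), 0)
  got2 <- extract_peak_changes(list(rec2))
  expect_equal(got2$t, 28)
  expect_equal(got2$dtiter, 1)

  # no measurement inside the window: the booster contributes nothing
  rec3 <- toy_record(c(0, 20, 60), c(10, 11, 11), 0)
  expect_equal(nrow(extract_peak_changes(list(rec3))), 0)
})

test_that("magnitude fit recovers exactly from noise-free data with a decreasing gain curve", {
  D <- -0.0015
  T0 <- rep(c(0, 2, 4, 6, 8, 10, 12, 14), each = 2)
  t <- rep(c(28, 40), times = 8)
  y <- 2 * 7.5 * (1 - plogis(0.33 * T0)) + t * D
  f <- fit_magnitude(data.frame(donor_id = "x", T0 = T0, t = t, dtiter = y), D)
  expect_equal(f$estimates$max_effect, 7.5, tolerance = 1e-6)
  expect_equal(f$estimates$saturation_speed, 0.33, tolerance = 1e-6)
  gain <- 2 * f$estimates$max_effect *
    booster_saturation(0:16, f$estimates$saturation_speed)
  expect_true(all(diff(gain) < 0))
})

test_that("integral fit reproduces the generating fixed effects on a noise-free cohort", {
  pop <- default_population()
  popq <- pop; popq$residual_sd <- 1e-6
  cfg <- cohort_config(n_donors = 40, pop = popq, round_titers = FALSE)
  co <- suppressWarnings(simulate_cohort(cfg, seed = 5))
  tD <- co$parameters$decline_rate; tL <- co$parameters$saturation_speed
  f <- fit_integral(co$records, pop$timing_rate,
                    start = list(max_effect = 6, mean_decline = mean(tD) * 1.2,
                                 sd_decline = sd(tD),
                                 mean_saturation = mean(tL) * 0.8,
                                 sd_saturation = sd(tL), residual_sd = 0.05))
  expect_true(f$converged)
  expect_equal(f$estimates$max_effect, pop$max_effect, tolerance = 1e-4)
  expect_equal(f$estimates$mean_decline_annual, mean(tD) * 365, tolerance = 1e-4)
  expect_equal(f$estimates$mean_saturation, mean(tL), tolerance = 1e-3)
  # empirical-Bayes decline rates equal the generating ones
  expect_lt(max(abs(f$donor_effects$decline_rate - tD)) * 365, 1e-3)
  # residuals of the fully predictive model vanish
  pr <- per_donor_residuals(co$records, f)
  expect_lt(max(pr$mae), 1e-4)
})

test_that("with no boosters the integral fit degenerates to the decline fit", {
  cfg <- cohort_config(n_donors = 60, new_donor_boosters = 0,
                       booster_trigger_titer = 0, booster_drop_from_max = 99,
                       established_fraction = 1, established_mean = 13,
                       established_sd = 1, career_meanlog = log(3),
                       career_sdlog = 0.4, max_follow_up = 1825)
  co <- suppressWarnings(simulate_cohort(cfg, seed = 7))
  s1 <- fit_decline(filter_unboostered(co))
  f <- fit_integral(co$records, 0.3,
                    start = list(max_effect = 2,
                                 mean_decline = s1$estimates$mean_decline,
                                 sd_decline = s1$estimates$sd_decline,
                                 mean_saturation = 0.3, sd_saturation = 0.05,
                                 residual_sd = s1$estimates$residual_sd))
  # the Laplace approximation is exact for the linear submodel, so the two
  # routes maximise the same likelihood
  expect_equal(f$estimates$mean_decline, s1$estimates$mean_decline,
               tolerance = 1e-4)
  expect_equal(f$estimates$sd_decline, s1$estimates$sd_decline,
               tolerance = 1e-3)
  expect_equal(f$estimates$residual_sd, s1$estimates$residual_sd,
               tolerance = 1e-4)
})

test_that("integral fit on a default cohort converges within the 30-loop budget with a shrinking trace", {
  co <- cached_cohort(n = 150, seed = 10)
  f <- cached_fit()
  expect_true(f$integral$converged)
  expect_lte(f$integral$iterations, 30)
  tr <- f$integral$trace
  expect_true(nrow(tr) >= 2)
  # relative parameter change over the last loop is below the 7-digit tolerance
  last <- tr[nrow(tr), 2:8]; prev <- tr[nrow(tr) - 1, 2:8]
  expect_lt(max(abs(last - prev) / pmax(abs(prev), 1e-8)), 1e-7)
  # cohort-mean per-donor MAE close to the folded-normal mean of the
  # measurement error
  pr <- per_donor_residuals(co$records, f$integral)
  expect_lt(abs(mean(pr$mae) - 0.62 * sqrt(2 / pi)), 0.08)
  expect_true(!is.unsorted(rev(pr$mae)))  # reported in decreasing MAE order
})

test_that("MAP donor estimation obeys its prior and likelihood limits", {
  co <- cached_cohort(n = 150, seed = 10)
  ref <- cached_fit()$integral

  # zero-width prior returns the population means
  refz <- ref
  refz$estimates$sd_decline <- 1e-9
  refz$estimates$sd_saturation <- 1e-9
  mp <- map_fit_donor(co$records[[3]], refz)
  expect_equal(mp$decline_rate, ref$estimates$mean_decline, tolerance = 1e-9)
  expect_equal(mp$saturation_speed, ref$estimates$mean_saturation,
               tolerance = 1e-9)

  # flat prior + long noise-free record recovers the generating parameters
  pop <- default_population()
  popq <- pop; popq$residual_sd <- 1e-6
  dn <- donor_parameters(annual_to_daily(-0.6), 0.4)
  recn <- suppressWarnings(simulate_donor(
    dn, popq, cohort_config(pop = popq, round_titers = FALSE), seed = 3,
    profile = list(follow_up = 5000, mean_gap = 30, n_initial = 4,
                   baseline = 4, established = FALSE)))
  reff <- ref
  reff$estimates$max_effect <- pop$max_effect
  reff$estimates$timing_rate <- pop$timing_rate
  reff$estimates$mean_decline <- annual_to_daily(-0.3)
  reff$estimates$mean_saturation <- 0.2
  reff$estimates$sd_decline <- annual_to_daily(5)
  reff$estimates$sd_saturation <- 5
  reff$estimates$residual_sd <- 1e-4
  mpf <- map_fit_donor(recn, reff)
  expect_equal(mpf$decline_rate, dn$decline_rate, tolerance = 1e-3)
  expect_equal(mpf$saturation_speed, dn$saturation_speed, tolerance = 1e-3)

  # fewer than two measurements: prior mean with a flag
  short <- donor_record("s", obs_days = 0, measured_titers = 8)
  mps <- map_fit_donor(short, ref)
  expect_identical(attr(mps, "flag"), "prior_mean")
  expect_equal(mps$decline_rate, ref$estimates$mean_decline)
})

test_that("split validation is deterministic, disjoint, and degenerates to the main fit", {
  co <- cached_cohort(n = 60, seed = 12)
  v <- split_validate(co$records, n_fit = 45, seed = 2)
  v2 <- split_validate(co$records, n_fit = 45, seed = 2)
  expect_identical(v$idx_fit, v2$idx_fit)
  expect_length(intersect(v$idx_fit, v$idx_heldout), 0)
  expect_length(v$idx_heldout, 15)
  expect_equal(v$insample_mae, v2$insample_mae)
  expect_true(all(c("decline_rate", "saturation_speed", "mae") %in%
                    names(v$heldout)))

  # n_fit covering every donor reproduces the full fit with no held-out set
  vall <- split_validate(co$records, n_fit = 60, seed = 2)
  f <- fit_titer_model(co$records)
  expect_equal(vall$fit$integral$estimates, f$integral$estimates,
               tolerance = 1e-8)
  expect_true(is.na(vall$heldout_mae))
})

test_that("day-less records are refused by every stage that needs timing", {
  rec <- donor_record("x", obs_days = NULL, measured_titers = c(5, 6, 7))
  expect_error(filter_unboostered(list(rec)), "day")
  expect_error(extract_post_booster(list(rec)), "day")
  expect_error(extract_peak_changes(list(rec)), "day")
  expect_error(fit_integral(list(rec, rec), 0.3), "day")
})
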