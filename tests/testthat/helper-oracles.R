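# Independent oracles and small fixtures shared across the suite.

# Small, fast population for unit tests (round numbers, not the calibrated
# defaults).
test_pop <- function(residual_sd = 0.3)
  population_parameters(max_effect = 2, timing_rate = 0.15,
                        mean_decline = -0.0015, sd_decline = 4e-4,
                        mean_saturation = 0.3, sd_saturation = 0.05,
                        residual_sd = residual_sd)

# Brute-force trajectory oracle: re-sums every booster term independently at
# every evaluation day, with its own recursion for the starting titers.
bf_trajectory <- function(booster_days, baseline, donor, pop, eval_days) {
  B <- pop$max_effect; H <- pop$timing_rate
  D <- donor$decline_rate; L <- donor$saturation_speed
  env <- function(dt) if (dt <= 0) 0 else 2 * (1 / (1 + exp(-H * dt)) - 0.5)
  sat <- function(T0) 1 - 1 / (1 + exp(-L * T0))
  T0 <- numeric(length(booster_days))
  for (j in seq_along(booster_days)) {
    v <- baseline + D * booster_days[j]
    if (j > 1) for (l in 1:(j - 1))
      v <- v + 2 * B * env(booster_days[j] - booster_days[l]) * sat(T0[l])
    T0[j] <- max(0, v)
  }
  out <- numeric(length(eval_days))
  for (k in seq_along(eval_days)) {
    v <- baseline + D * eval_days[k]
    for (j in seq_along(booster_days))
      v <- v + 2 * B * env(eval_days[k] - booster_days[j]) * sat(T0[j])
    out[k] <- max(0, v)
  }
  out
}

# Hand-enumeration oracle for the booster-free filter: returns the expected
# (t, dtiter) rows for one record, by explicit looping.
enumerate_unboostered <- function(days, titers, boosters, min_since = 100) {
  last_b <- vapply(days, function(d) {
    prev <- boosters[boosters <= d]
    if (!length(prev)) NA_real_ else max(prev)
  }, 0)
  since <- ifelse(is.na(last_b), Inf, days - last_b)
  era <- vapply(days, function(d) sum(boosters <= d), 0)
  ok <- since >= min_since
  out <- NULL
  for (e in unique(era)) {
    idx <- which(era == e & ok)
    if (length(idx) < 2) next
    o <- idx[1]
    out <- rbind(out, data.frame(t = days[idx[-1]] - days[o],
                                 dtiter = titers[idx[-1]] - titers[o]))
  }
  out
}

# a deterministic toy record used by several filter tests
toy_record <- function(days, titers, boosters, id = "toy")
  suppressWarnings(donor_record(id, obs_days = days, measured_titers = titers,
                                booster_days = boosters))

# small simulated cohort cached per session to keep the suite fast
cached_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 150, seed = 42, ...) {
    key <- paste(n, seed, length(list(...)))
    if (is.null(cache[[key]]))
      cache[[key]] <- suppressWarnings(
        simulate_cohort(cohort_config(n_donors = n, ...), seed = seed))
    cache[[key]]
  }
})

# full staged fit of the 150-donor reference cohort, computed once
cached_fit <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$fit))
      cache$fit <- suppressWarnings(fit_titer_model(cached_cohort(n = 150, seed = 10)))
    cache$fit
  }
})
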