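# Staged estimation pipeline:
#   Step 1   random-effects log-linear decline on booster-free segments
#   Step 2A  nonlinear least squares for the booster time envelope (B, H)
#   Step 2B  nonlinear least squares for the magnitude saturation (B, L)
#   Step 3   integral nonlinear mixed-effects fit with iterated latent
#            starting titers (Laplace marginal likelihood, Rcpp backend)
# plus residual diagnostics, MAP estimation for out-of-sample donors and
# split-sample validation.

as_records <- function(x) {
  if (inherits(x, "rhd_cohort")) return(x$records)
  if (inherits(x, "rhd_record")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "rhd_record"))) return(x)
  stop("expected an rhd_cohort, an rhd_record, or a list of rhd_record objects")
}

require_days <- function(records, what) {
  if (!all(vapply(records, has_days, TRUE)))
    stop(what, " requires day-resolved records; the anonymised dialect has no ",
         "'day' column. Supply data in the extended dialect.")
}

#' Result container for one fitting stage
#'
#' @param stage Stage label.
#' @param estimates Named list of fixed-effect / hyperparameter estimates.
#' @param donor_effects Data frame of per-donor estimates, or `NULL`.
#' @param loglik Log-likelihood (or negative residual score).
#' @param iterations Iterations used by the stage.
#' @param converged Logical convergence flag.
#' @param trace Optional per-iteration parameter trace (matrix).
#' @param details Stage-specific extras.
#' @return An object of class `"rhd_stage_fit"`.
#' @keywords internal
stage_fit <- function(stage, estimates, donor_effects = NULL, loglik = NA_real_,
                      iterations = NA_integer_, converged = NA, trace = NULL,
                      details = list()) {
  structure(list(stage = stage, estimates = estimates,
                 donor_effects = donor_effects, loglik = loglik,
                 iterations = iterations, converged = converged,
                 trace = trace, details = details),
            class = "rhd_stage_fit")
}

#' @export
print.rhd_stage_fit <- function(x, ...) {
  cat(sprintf("Stage fit: %s (%s, %s iterations)\n", x$stage,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              x$iterations))
  est <- x$estimates
  for (nm in names(est))
    if (is.numeric(est[[nm]]) && length(est[[nm]]) == 1L)
      cat(sprintf("  %-22s %.6g\n", nm, est[[nm]]))
  if (!is.null(x$donor_effects))
    cat(sprintf("  per-donor estimates for %d donors\n", nrow(x$donor_effects)))
  invisible(x)
}

# measured titer at the last donation at or before `day` (NA if none)
titer_at_or_before <- function(record, day) {
  idx <- which(record$obs_days <= day)
  if (!length(idx)) return(NA_real_)
  record$measured_titers[max(idx)]
}

#' Booster-free titer differences
#'
#' Extracts the observations used for the natural-decline fit: only
#' donations at least `min_days_since_booster` days after any last booster
#' event.  Follow-up restarts with each booster: within every inter-booster
#' segment the first compliant measurement is set as time 0 and later
#' compliant measurements enter as differences from it.
#'
#' @param records An `rhd_cohort` or list of day-resolved [donor_record()]s.
#' @param min_days_since_booster Exclusion window after a booster (100 days).
#' @return Data frame with columns `donor_id`, `t` (days since segment
#'   origin), `dtiter` (log2 change from the origin measurement),
#'   `origin_day`, `origin_titer`, `days_since_booster`.
#' @export
filter_unboostered <- function(records, min_days_since_booster = 100) {
  records <- as_records(records)
  require_days(records, "filter_unboostered")
  out <- lapply(records, function(r) {
    d <- r$obs_days; x <- r$booster_days
    era <- if (length(x)) findInterval(d, x) else rep(0L, length(d))
    since <- ifelse(era == 0L, Inf, d - x[pmax(era, 1L)])
    ok <- since >= min_days_since_booster
    res <- NULL
    for (e in unique(era)) {
      idx <- which(era == e & ok)
      if (length(idx) < 2) next
      o <- idx[1]
      res <- rbind(res, data.frame(
        donor_id = r$donor_id,
        t = d[idx[-1]] - d[o],
        dtiter = r$measured_titers[idx[-1]] - r$measured_titers[o],
        origin_day = d[o],
        origin_titer = r$measured_titers[o],
        days_since_booster = since[idx[-1]]))
    }
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(donor_id = character(), t = numeric(), dtiter = numeric(),
                      origin_day = numeric(), origin_titer = numeric(),
                      days_since_booster = numeric())
  out
}

#' Step 1: random-effects log-linear decline fit
#'
#' Maximum-likelihood fit of the random-slope model without intercept,
#' \eqn{C_i(t) = D_i t + \epsilon}, \eqn{D_i \sim N(\mu_D, \sigma_D^2)},
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}, to booster-free titer
#' differences (differences are anchored at 0 by construction).  Per-donor
#' decline rates are the empirical-Bayes modes.  With a single donor the
#' model degenerates to ordinary least squares through the origin.
#'
#' @param diffs Output of [filter_unboostered()].
#' @return An `rhd_stage_fit` with estimates `mean_decline`, `sd_decline`,
#'   `residual_sd` (per-day and annual variants) and per-donor
#'   `donor_effects`; `details$pooled_slope` carries the naive non-grouped
#'   OLS slope for bias diagnostics.
#' @export
fit_decline <- function(diffs) {
  stopifnot(is.data.frame(diffs), nrow(diffs) >= 2)
  if (length(unique(diffs$t)) < 2)
    stop("degenerate design: decline fit needs at least two distinct time points")
  pooled <- unname(coef(lm(dtiter ~ 0 + t, data = diffs)))

  if (length(unique(diffs$donor_id)) < 2) {
    m <- lm(dtiter ~ 0 + t, data = diffs)
    muD <- unname(coef(m)[1])
    sig <- suppressWarnings(summary(m)$sigma)  # may warn on a perfect fit
    de <- data.frame(donor_id = unique(diffs$donor_id), decline_rate = muD)
    return(stage_fit("decline",
                     list(mean_decline = muD,
                          mean_decline_annual = daily_to_annual(muD),
                          sd_decline = NA_real_, sd_decline_annual = NA_real_,
                          residual_sd = sig),
                     donor_effects = de, loglik = as.numeric(logLik(m)),
                     iterations = 1L, converged = TRUE,
                     details = list(pooled_slope = pooled,
                                    n_obs = nrow(diffs), n_donors = 1L)))
  }

  # fit on the annual time scale so slope and residual are of comparable size
  diffs$t_yr <- diffs$t / DAYS_PER_YEAR
  m <- lme4::lmer(dtiter ~ 0 + t_yr + (0 + t_yr | donor_id), data = diffs,
                  REML = FALSE,
                  control = lme4::lmerControl(check.conv.singular = "ignore"))
  muD <- annual_to_daily(unname(lme4::fixef(m)[["t_yr"]]))
  sdD <- annual_to_daily(attr(lme4::VarCorr(m)$donor_id, "stddev")[["t_yr"]])
  sig <- stats::sigma(m)
  re <- lme4::ranef(m)$donor_id
  de <- data.frame(donor_id = rownames(re),
                   decline_rate = muD + annual_to_daily(re[["t_yr"]]))
  conv <- length(m@optinfo$conv$lme4$messages) == 0
  stage_fit("decline",
            list(mean_decline = muD, mean_decline_annual = daily_to_annual(muD),
                 sd_decline = sdD, sd_decline_annual = daily_to_annual(sdD),
                 residual_sd = sig),
            donor_effects = de, loglik = as.numeric(logLik(m)),
            iterations = m@optinfo$feval, converged = conv,
            details = list(pooled_slope = pooled, n_obs = nrow(diffs),
                           n_donors = length(unique(diffs$donor_id))))
}

#' Post-booster titer differences for the timing fit
#'
#' For every booster at least `prior_exclusion` days after the previous one,
#' collects titer changes relative to the measurement at boostering, up to
#' `horizon` days after the booster or until the next booster event.
#'
#' @param records Day-resolved records.
#' @param horizon Follow-up window after a booster (200 days).
#' @param prior_exclusion Minimum spacing from the previous booster (100 days).
#' @return Data frame with `donor_id`, `booster_day`, `t` (days since
#'   booster), `dtiter`, `origin_titer`.
#' @export
extract_post_booster <- function(records, horizon = 200, prior_exclusion = 100) {
  records <- as_records(records)
  require_days(records, "extract_post_booster")
  out <- lapply(records, function(r) {
    x <- r$booster_days
    if (!length(x)) return(NULL)
    res <- NULL
    for (j in seq_along(x)) {
      if (j > 1 && x[j] - x[j - 1] < prior_exclusion) next
      t0 <- titer_at_or_before(r, x[j])
      if (is.na(t0)) next
      # window is open on the right at the next booster event: together with
      # the prior-spacing exclusion this keeps the lag profile free of the
      # initial-series composition (low starting titers appearing only at
      # short lags), which would otherwise masquerade as a fast envelope
      idx <- which(r$obs_days > x[j] &
                     r$obs_days <= x[j] + horizon &
                     r$obs_days < if (j < length(x)) x[j + 1] else Inf)
      if (!length(idx)) next
      res <- rbind(res, data.frame(
        donor_id = r$donor_id, booster_day = x[j],
        t = r$obs_days[idx] - x[j],
        dtiter = r$measured_titers[idx] - t0,
        origin_titer = t0))
    }
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(donor_id = character(), booster_day = numeric(),
                      t = numeric(), dtiter = numeric(), origin_titer = numeric())
  out
}

#' Step 2A: booster timing fit
#'
#' Nonlinear least squares for
#' \eqn{C(t) = 2B(1/(1+e^{-Ht}) - 1/2) + D t} on post-booster differences,
#' with the population decline rate \eqn{D} fixed from Step 1.  Reports the
#' implied peak day.
#'
#' @param post_diffs Output of [extract_post_booster()].
#' @param decline_rate Fixed population decline rate, per day.
#' @param start Starting values for `(B, H)`.
#' @return An `rhd_stage_fit` with `max_effect`, `timing_rate`, `peak_day`.
#' @export
fit_timing <- function(post_diffs, decline_rate, start = c(B = 2, H = 0.1)) {
  stopifnot(nrow(post_diffs) >= 3)
  if (length(unique(post_diffs$t)) < 3)
    stop("timing fit needs observations at >= 3 distinct lags")
  t <- post_diffs$t; y <- post_diffs$dtiter
  resid_fn <- function(p)
    y - (2 * p[["B"]] * (plogis(p[["H"]] * t) - 0.5) + decline_rate * t)
  # H is weakly identified when no lag is shorter than ~2 weeks (the envelope
  # is then nearly saturated everywhere), so the fit is bounded and LM-based
  # rather than routed through nls()'s gradient check.
  m <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                          lower = c(B = 1e-8, H = 1e-4),
                          upper = c(B = 50, H = 2),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- m$par
  stage_fit("timing",
            list(max_effect = unname(est[["B"]]),
                 timing_rate = unname(est[["H"]]),
                 peak_day = peak_day(est[["B"]], est[["H"]], decline_rate),
                 decline_rate_fixed = decline_rate),
            loglik = -0.5 * m$deviance,
            iterations = m$niter,
            converged = m$info %in% 1:4,
            details = list(n_obs = nrow(post_diffs), message = m$message))
}

#' Peak titer changes for the magnitude fit
#'
#' For every booster at least `pre_exclusion` days after the previous one,
#' takes the first measurement between `window[1]` and `window[2]` days after
#' the booster (the approximate response peak) together with the titer at
#' boostering.  Boosters given *after* the booster of interest are not
#' excluded, so low-starting-titer events from the initial series of new
#' donors are retained (the resulting curve bounds the single-booster gain
#' from above).
#'
#' @param records Day-resolved records.
#' @param window Days after boostering considered the peak (26 to 50).
#' @param pre_exclusion Minimum spacing from the previous booster (50 days).
#' @return Data frame with `donor_id`, `booster_day`, `t`, `dtiter` and the
#'   starting titer `T0`.
#' @export
extract_peak_changes <- function(records, window = c(26, 50), pre_exclusion = 50) {
  records <- as_records(records)
  require_days(records, "extract_peak_changes")
  out <- lapply(records, function(r) {
    x <- r$booster_days
    if (!length(x)) return(NULL)
    res <- NULL
    for (j in seq_along(x)) {
      if (j > 1 && x[j] - x[j - 1] < pre_exclusion) next
      t0 <- titer_at_or_before(r, x[j])
      if (is.na(t0)) next
      idx <- which(r$obs_days - x[j] >= window[1] & r$obs_days - x[j] <= window[2])
      if (!length(idx)) next
      k <- idx[1]  # first time point in the window
      res <- rbind(res, data.frame(
        donor_id = r$donor_id, booster_day = x[j],
        t = r$obs_days[k] - x[j],
        dtiter = r$measured_titers[k] - t0,
        T0 = t0))
    }
    res
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(donor_id = character(), booster_day = numeric(),
                      t = numeric(), dtiter = numeric(), T0 = numeric())
  out
}

#' Step 2B: booster magnitude fit
#'
#' Nonlinear least squares for the saturation of the peak booster gain with
#' starting titer, \eqn{C = 2B(1 - 1/(1+e^{-L T_0})) + t D}, with \eqn{D}
#' fixed from Step 1 and \eqn{t} the actual observation lag.
#'
#' @param peak_changes Output of [extract_peak_changes()].
#' @param decline_rate Fixed population decline rate, per day.
#' @param start Starting values for `(B, L)`.
#' @return An `rhd_stage_fit` with `max_effect` and `saturation_speed`.
#' @export
fit_magnitude <- function(peak_changes, decline_rate, start = c(B = 5, L = 0.3)) {
  stopifnot(nrow(peak_changes) >= 3)
  T0 <- peak_changes$T0; t <- peak_changes$t; y <- peak_changes$dtiter
  resid_fn <- function(p)
    y - (2 * p[["B"]] / (1 + exp(p[["L"]] * T0)) + t * decline_rate)
  m <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                          lower = c(B = 1e-8, L = 1e-8),
                          upper = c(B = 50, L = 10),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- m$par
  stage_fit("magnitude",
            list(max_effect = unname(est[["B"]]),
                 saturation_speed = unname(est[["L"]]),
                 decline_rate_fixed = decline_rate),
            loglik = -0.5 * m$deviance,
            iterations = m$niter,
            converged = m$info %in% 1:4,
            details = list(n_obs = nrow(peak_changes), message = m$message))
}

# ---------------------------------------------------------------------------
# Step 3: the integral model

# Per-donor design pieces for the integral fit: differences from the first
# measurement (single origin per donor), booster days relative to it, the
# envelope matrix A (fixed once H is fixed), and measured starting titers as
# the initial latent values.
prepare_integral_data <- function(records, timing_rate) {
  records <- as_records(records)
  require_days(records, "the integral fit")
  lapply(records, function(r) {
    d1 <- r$obs_days[1]
    t_all <- r$obs_days - d1
    C_all <- r$measured_titers - r$measured_titers[1]
    x <- r$booster_days - d1
    keep <- x >= 0
    x <- x[keep]
    T0 <- vapply(x + d1, function(day) titer_at_or_before(r, day), 0)
    t <- t_all[-1]
    A <- if (length(x))
      outer(t, x, function(tt, xx) booster_envelope(tt - xx, timing_rate))
    else matrix(0, length(t), 0)
    list(donor_id = r$donor_id,
         t = t, C = C_all[-1],
         A = A, x = x, T0 = pmax(0, T0),
         first_titer = r$measured_titers[1],
         titers = r$measured_titers[-1])
  })
}

# Forward-sequential model-derived starting titers for one donor:
# each booster sees the prediction from strictly earlier boosters only,
# clamped at 0 before entering the saturation term.
model_starting_titers <- function(prep_i, D, L, B, H) {
  x <- prep_i$x
  m <- length(x)
  T0 <- numeric(m)
  for (j in seq_len(m)) {
    val <- prep_i$first_titer + D * x[j]
    if (j > 1) {
      earlier <- seq_len(j - 1L)
      val <- val + sum(2 * B * booster_envelope(x[j] - x[earlier], H) *
                         booster_saturation(T0[earlier], L))
    }
    T0[j] <- max(0, val)
  }
  T0
}

integral_control <- function(max_loops = 30, loop_tol = 1e-7,
                             estimate_cov = FALSE, optim_iter = 400,
                             verbose = FALSE) {
  list(max_loops = max_loops, loop_tol = loop_tol,
       estimate_cov = estimate_cov, optim_iter = optim_iter,
       verbose = verbose)
}

#' Step 3: integral nonlinear mixed-effects fit
#'
#' Maximum-likelihood fit of the full titer-change model
#' \deqn{C_i(t) = D_i t + \sum_{j : x_{i,j} \le t}
#'   4B(1/(1+e^{-H(t - x_{i,j})}) - 1/2)(1 - 1/(1+e^{-L_i T_i(x_{i,j})})) +
#'   \epsilon}
#' with donor random effects \eqn{(D_i, L_i)}, the timing rate \eqn{H} fixed
#' from Step 2A (its likelihood surface is essentially flat in the integral
#' model), and latent starting titers \eqn{T_i(x_{i,j})}.  The marginal
#' likelihood integrates the random effects by a Laplace approximation (the
#' donor-level modes double as empirical-Bayes estimates).  An outer loop
#' alternates (a) the ML fit given current starting titers with (b)
#' recomputing the starting titers from the current fit, starting from the
#' measured titers at boostering, until every parameter's relative change is
#' below `loop_tol` (default `1e-7`, i.e. stability in the first seven
#' digits) or `max_loops` (default 30) is reached; predicted starting titers
#' below 0 are rounded up to 0 throughout.
#'
#' @param records Day-resolved records (an `rhd_cohort` or list of
#'   [donor_record()]).
#' @param timing_rate Fixed envelope rate \eqn{H}, per day.
#' @param start Named list of starting values: `max_effect`, `mean_decline`,
#'   `sd_decline`, `mean_saturation`, `sd_saturation`, `residual_sd` (rates
#'   per day), normally taken from Steps 1--2B.
#' @param control List from `integral_control()`: `max_loops`, `loop_tol`,
#'   `estimate_cov` (estimate the correlation of \eqn{(D_i, L_i)} instead of
#'   fixing it at 0), `optim_iter`, `verbose`.
#' @return An `rhd_stage_fit` with the fixed effects and hyperparameters,
#'   per-donor empirical-Bayes `donor_effects`, the per-loop parameter
#'   `trace`, and `details` holding the final starting titers and design
#'   pieces.
#' @export
fit_integral <- function(records, timing_rate,
                         start = list(max_effect = 4,
                                      mean_decline = -0.0015,
                                      sd_decline = 0.0012,
                                      mean_saturation = 0.3,
                                      sd_saturation = 0.1,
                                      residual_sd = 0.7),
                         control = integral_control()) {
  control <- do.call(integral_control, control[names(control) %in%
                                                 names(formals(integral_control))])
  prep <- prepare_integral_data(records, timing_rate)
  n_donors <- length(prep)
  stopifnot(n_donors >= 2)

  # optimiser works on an annual / log scale so all parameters are O(1)
  to_par <- function(s, rho = 0) {
    p <- c(B = s$max_effect,
           muD = daily_to_annual(s$mean_decline),
           lsdD = log(daily_to_annual(s$sd_decline)),
           muL = s$mean_saturation,
           lsdL = log(s$sd_saturation),
           lsig = log(s$residual_sd))
    if (control$estimate_cov) p <- c(p, zrho = atanh(rho))
    p
  }
  from_par <- function(p) {
    list(B = unname(p[["B"]]),
         muD = annual_to_daily(unname(p[["muD"]])),
         sdD = annual_to_daily(exp(unname(p[["lsdD"]]))),
         muL = unname(p[["muL"]]),
         sdL = exp(unname(p[["lsdL"]])),
         sig = exp(unname(p[["lsig"]])),
         rho = if (control$estimate_cov) tanh(unname(p[["zrho"]])) else 0)
  }

  cur_prep <- prep  # T0 slots updated between loops
  objective <- function(p) {
    q <- from_par(p)
    .integral_nll_cpp(cur_prep, q$B, q$muD, q$sdD, q$muL, q$sdL, q$rho, q$sig,
                      FALSE)$nll
  }

  lower <- c(B = 1e-3, muD = -20, lsdD = log(1e-4), muL = -5,
             lsdL = log(1e-4), lsig = log(1e-4))
  upper <- c(B = 50, muD = 20, lsdD = log(20), muL = 10,
             lsdL = log(10), lsig = log(10))
  if (control$estimate_cov) {
    lower <- c(lower, zrho = atanh(-0.99)); upper <- c(upper, zrho = atanh(0.99))
  }

  par <- to_par(start)
  prev_nat <- NULL
  trace <- NULL
  converged <- FALSE
  opt <- NULL
  loops <- 0L
  for (loop in seq_len(control$max_loops)) {
    loops <- loop
    opt <- nlminb(par, objective, lower = lower, upper = upper,
                  control = list(iter.max = control$optim_iter,
                                 eval.max = 4 * control$optim_iter))
    par <- opt$par
    q <- from_par(par)
    modes <- .integral_nll_cpp(cur_prep, q$B, q$muD, q$sdD, q$muL, q$sdL,
                               q$rho, q$sig, TRUE)
    for (i in seq_len(n_donors))
      cur_prep[[i]]$T0 <- model_starting_titers(cur_prep[[i]], modes$D[i],
                                                modes$L[i], q$B, timing_rate)
    nat <- c(B = q$B, muD = q$muD, sdD = q$sdD, muL = q$muL, sdL = q$sdL,
             sig = q$sig, rho = q$rho)
    trace <- rbind(trace, c(loop = loop, nat, nll = opt$objective))
    if (control$verbose)
      message(sprintf("loop %2d: nll %.6f  B %.4f  muD(yr) %.4f  muL %.4f",
                      loop, opt$objective, q$B, daily_to_annual(q$muD), q$muL))
    if (!is.null(prev_nat)) {
      rel <- abs(nat - prev_nat) / pmax(abs(prev_nat), 1e-8)
      if (max(rel) < control$loop_tol) { converged <- TRUE; break }
    }
    prev_nat <- nat
  }
  q <- from_par(par)
  modes <- .integral_nll_cpp(cur_prep, q$B, q$muD, q$sdD, q$muL, q$sdL,
                             q$rho, q$sig, TRUE)
  de <- data.frame(donor_id = vapply(cur_prep, `[[`, "", "donor_id"),
                   decline_rate = modes$D,
                   saturation_speed = modes$L)
  stage_fit("integral",
            list(max_effect = q$B, timing_rate = timing_rate,
                 mean_decline = q$muD,
                 mean_decline_annual = daily_to_annual(q$muD),
                 sd_decline = q$sdD,
                 sd_decline_annual = daily_to_annual(q$sdD),
                 mean_saturation = q$muL, sd_saturation = q$sdL,
                 cor_decline_saturation = q$rho,
                 residual_sd = q$sig),
            donor_effects = de,
            loglik = -opt$objective,
            iterations = loops,
            converged = converged,
            trace = trace,
            details = list(prep = cur_prep, timing_rate = timing_rate,
                           starting_titers = lapply(cur_prep, `[[`, "T0"),
                           optimizer_status = opt$convergence,
                           optimizer_message = opt$message))
}

#' Population parameters implied by an integral fit
#'
#' @param fit An integral-stage `rhd_stage_fit`.
#' @return A [population_parameters()] object.
#' @export
fit_population <- function(fit) {
  e <- fit$estimates
  population_parameters(
    max_effect = e$max_effect, timing_rate = e$timing_rate,
    mean_decline = e$mean_decline, sd_decline = e$sd_decline,
    mean_saturation = e$mean_saturation, sd_saturation = e$sd_saturation,
    cov_decline_saturation = e$cor_decline_saturation * e$sd_decline * e$sd_saturation,
    residual_sd = e$residual_sd)
}

#' Per-donor residual diagnostics
#'
#' Mean absolute and mean squared error of the fully predictive model per
#' donor: predictions use each donor's first measurement, booster days and
#' fitted \eqn{(D_i, L_i)} only, with model-derived starting titers and
#' titer predictions below 0 rounded up to 0.  Residuals cover every
#' measurement after the first (which anchors the prediction exactly).
#'
#' @param records Day-resolved records.
#' @param fit An integral-stage `rhd_stage_fit` (or any list with
#'   `estimates` containing `max_effect`, `timing_rate` and a
#'   `donor_effects` frame covering the records).
#' @return Data frame `donor_id`, `n`, `mae`, `mse`, stably sorted by
#'   decreasing MAE.  Donors with a single measurement (nothing to predict)
#'   are omitted.
#' @export
per_donor_residuals <- function(records, fit) {
  records <- as_records(records)
  B <- fit$estimates$max_effect; H <- fit$estimates$timing_rate
  de <- fit$donor_effects
  prep <- prepare_integral_data(records, H)
  rows <- lapply(prep, function(pr) {
    if (!length(pr$t)) return(NULL)  # single-measurement donors: nothing to predict
    i <- match(pr$donor_id, de$donor_id)
    if (is.na(i)) stop("no fitted parameters for donor ", pr$donor_id)
    D <- de$decline_rate[i]; L <- de$saturation_speed[i]
    T0 <- model_starting_titers(pr, D, L, B, H)
    s <- booster_saturation(T0, L)
    predC <- D * pr$t + if (length(T0)) 2 * B * as.numeric(pr$A %*% s) else 0
    pred <- pmax(0, pr$first_titer + predC)
    resid <- pr$titers - pred
    data.frame(donor_id = pr$donor_id, n = length(resid),
               mae = mean(abs(resid)), mse = mean(resid^2))
  })
  out <- do.call(rbind, rows)
  out[order(-out$mae), , drop = FALSE]
}

#' MAP donor parameters from a reference fit
#'
#' Estimates \eqn{(D_i, L_i)} for a donor outside the reference fit by
#' maximising the product of the bivariate-normal population prior and the
#' Gaussian residual likelihood of the donor's titer differences (i.e.
#' minimising the negative log posterior).  The latent starting titers are
#' iterated exactly as in the main fit: the first pass uses the measured
#' titers at boostering, subsequent passes the model-derived values
#' (`iterations` inner updates, stopping early once they are stable).
#'
#' @param record A day-resolved [donor_record()].
#' @param reference An integral-stage `rhd_stage_fit` or a
#'   [population_parameters()] object supplying \eqn{B}, \eqn{H}, the prior
#'   and the residual SD.
#' @param iterations Inner starting-titer updates (default 50).
#' @return [donor_parameters()] with attributes `flag` (`"ok"` or
#'   `"prior_mean"` for donors with fewer than 2 measurements) and
#'   `iterations` used.
#' @export
map_fit_donor <- function(record, reference, iterations = 50) {
  stopifnot(inherits(record, "rhd_record"))
  if (inherits(reference, "rhd_stage_fit")) {
    e <- reference$estimates
    B <- e$max_effect; H <- e$timing_rate
    muD <- e$mean_decline; sdD <- e$sd_decline
    muL <- e$mean_saturation; sdL <- e$sd_saturation
    rho <- e$cor_decline_saturation; sig <- e$residual_sd
  } else {
    B <- reference$max_effect; H <- reference$timing_rate
    muD <- reference$mean_decline; sdD <- reference$sd_decline
    muL <- reference$mean_saturation; sdL <- reference$sd_saturation
    rho <- reference$cov_decline_saturation / (sdD * sdL)
    sig <- reference$residual_sd
  }
  prep <- prepare_integral_data(list(record), H)
  if (length(prep[[1]]$t) < 1) {
    out <- donor_parameters(muD, muL)
    attr(out, "flag") <- "prior_mean"
    attr(out, "iterations") <- 0L
    return(out)
  }
  pr <- prep[[1]]
  used <- 0L
  for (it in seq_len(iterations)) {
    used <- it
    modes <- .integral_nll_cpp(list(pr), B, muD, sdD, muL, sdL, rho, sig, TRUE)
    newT0 <- model_starting_titers(pr, modes$D[1], modes$L[1], B, H)
    delta <- if (length(newT0)) max(abs(newT0 - pr$T0)) else 0
    pr$T0 <- newT0
    if (delta < 1e-10) break
  }
  out <- donor_parameters(modes$D[1], modes$L[1])
  attr(out, "flag") <- "ok"
  attr(out, "iterations") <- used
  out
}

#' Full staged model fit
#'
#' Runs the estimation stages in order: booster-free decline (Step 1),
#' booster timing (Step 2A), booster magnitude (Step 2B) and the integral
#' mixed-effects fit (Step 3), each later stage started from the earlier
#' estimates.
#'
#' @param records Day-resolved records.
#' @param stages Character subset of
#'   `c("decline", "timing", "magnitude", "integral")`; earlier stages
#'   required by a requested later stage are always run.
#' @param control Control list for [fit_integral()].
#' @param verbose Print stage progress.
#' @return Object of class `"rhd_model_fit"`: list with elements `decline`,
#'   `timing`, `magnitude`, `integral` (those requested).
#' @export
fit_titer_model <- function(records,
                            stages = c("decline", "timing", "magnitude", "integral"),
                            control = list(), verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  records <- as_records(records)
  need <- function(s) s %in% stages
  if (need("integral")) stages <- union(stages, c("decline", "timing", "magnitude"))
  if (need("timing") || need("magnitude")) stages <- union(stages, "decline")

  out <- list()
  if (verbose) message("Step 1: natural decline")
  out$decline <- fit_decline(filter_unboostered(records))
  D <- out$decline$estimates$mean_decline

  if ("timing" %in% stages) {
    if (verbose) message("Step 2A: booster timing")
    out$timing <- fit_timing(extract_post_booster(records), D)
  }
  if ("magnitude" %in% stages) {
    if (verbose) message("Step 2B: booster magnitude")
    out$magnitude <- fit_magnitude(extract_peak_changes(records), D)
  }
  if ("integral" %in% stages) {
    if (verbose) message("Step 3: integral mixed-effects fit")
    L0 <- out$magnitude$estimates$saturation_speed
    start <- list(
      max_effect = out$magnitude$estimates$max_effect,
      mean_decline = D,
      sd_decline = if (is.finite(out$decline$estimates$sd_decline) &&
                         out$decline$estimates$sd_decline > 0)
        out$decline$estimates$sd_decline else annual_to_daily(0.3),
      mean_saturation = L0,
      sd_saturation = max(0.3 * abs(L0), 0.02),
      residual_sd = out$decline$estimates$residual_sd)
    ctl <- control
    ctl$verbose <- isTRUE(control$verbose) || verbose
    out$integral <- fit_integral(records, out$timing$estimates$timing_rate,
                                 start = start, control = ctl)
  }
  structure(out, class = "rhd_model_fit")
}

#' @export
print.rhd_model_fit <- function(x, ...) {
  cat("Staged anti-RhD titer model fit\n")
  for (s in x) print(s)
  invisible(x)
}

#' Split-sample validation
#'
#' Refits the staged model on a random subset of donors and estimates the
#' remaining donors' \eqn{(D_i, L_i)} by [map_fit_donor()] under the refit
#' random-effects prior, comparing in-sample and held-out prediction error.
#'
#' @param records Day-resolved records.
#' @param n_fit Number of donors in the refit subset.
#' @param seed Integer seed for the donor split (deterministic).
#' @param control Control list for [fit_integral()].
#' @param map_iterations Starting-titer iterations per held-out donor.
#' @param reference Optional integral-stage `rhd_stage_fit` from a full-data
#'   fit; when given, the relative shift of every hyperparameter in the
#'   subset refit is reported.
#' @return Object of class `"rhd_validation"`: the subset `fit`, per-donor
#'   residual tables `insample` / `heldout`, their mean-MAE summaries,
#'   optional `hyperparameter_shift`, and the split indices.
#' @export
split_validate <- function(records, n_fit = 500, seed = 1, control = list(),
                           map_iterations = 50, reference = NULL) {
  records <- as_records(records)
  n <- length(records)
  stopifnot(n_fit >= 2)
  set.seed(seed)
  idx_fit <- sort(sample(n, min(n_fit, n)))
  idx_out <- setdiff(seq_len(n), idx_fit)

  fit <- fit_titer_model(records[idx_fit], control = control)
  insample <- per_donor_residuals(records[idx_fit], fit$integral)

  heldout <- NULL
  if (length(idx_out)) {
    rows <- lapply(idx_out, function(i) {
      dp <- map_fit_donor(records[[i]], fit$integral, iterations = map_iterations)
      data.frame(donor_id = records[[i]]$donor_id,
                 decline_rate = dp$decline_rate,
                 saturation_speed = dp$saturation_speed,
                 flag = attr(dp, "flag"))
    })
    map_de <- do.call(rbind, rows)
    pseudo <- list(estimates = fit$integral$estimates, donor_effects = map_de)
    heldout <- per_donor_residuals(records[idx_out], pseudo)
    heldout <- merge(heldout, map_de, by = "donor_id", sort = FALSE)
    heldout <- heldout[order(-heldout$mae), , drop = FALSE]
  }

  shift <- NULL
  if (!is.null(reference)) {
    keys <- c("max_effect", "mean_decline", "sd_decline", "mean_saturation",
              "sd_saturation", "residual_sd")
    ref <- unlist(reference$estimates[keys])
    new <- unlist(fit$integral$estimates[keys])
    shift <- (new - ref) / abs(ref)
  }

  structure(list(fit = fit,
                 insample = insample,
                 heldout = heldout,
                 insample_mae = mean(insample$mae),
                 heldout_mae = if (is.null(heldout)) NA_real_ else mean(heldout$mae),
                 hyperparameter_shift = shift,
                 idx_fit = idx_fit, idx_heldout = idx_out, seed = seed),
            class = "rhd_validation")
}

#' @export
print.rhd_validation <- function(x, ...) {
  cat(sprintf("Split-sample validation: %d fit donors, %d held out (seed %d)\n",
              length(x$idx_fit), length(x$idx_heldout), x$seed))
  cat(sprintf("  mean per-donor MAE: in-sample %.3f, held-out %s\n",
              x$insample_mae,
              if (is.na(x$heldout_mae)) "n/a" else sprintf("%.3f", x$heldout_mae)))
  if (!is.null(x$hyperparameter_shift))
    cat("  refit shift vs reference:",
        paste(sprintf("%s %+.1f%%", names(x$hyperparameter_shift),
                      100 * x$hyperparameter_shift), collapse = ", "), "\n")
  invisible(x)
}
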