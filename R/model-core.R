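#' Donor-level kinetic parameters
#'
#' Bundles the two parameters that characterise an individual donor: the
#' natural log2-titer decline rate \eqn{D_i} (log2 titer units per day,
#' negative for declining donors) and the saturation speed \eqn{L_i} (per
#' log2 titer unit) with which the booster response shrinks as the titer at
#' boostering rises.
#'
#' @param decline_rate Log2 titer change per day (typically negative).
#' @param saturation_speed Per log2 titer unit; non-negative for donors whose
#'   booster response saturates with rising titer.
#' @return An object of class `"rhd_donor_params"`.
#' @examples
#' donor_parameters(decline_rate = -0.55 / 365, saturation_speed = 0.34)
#' @export
donor_parameters <- function(decline_rate, saturation_speed) {
  stopifnot(length(decline_rate) == 1L, length(saturation_speed) == 1L,
            is.finite(decline_rate), is.finite(saturation_speed))
  structure(list(decline_rate = as.numeric(decline_rate),
                 saturation_speed = as.numeric(saturation_speed)),
            class = "rhd_donor_params")
}

#' @export
print.rhd_donor_params <- function(x, ...) {
  cat("Donor parameters:\n")
  cat(sprintf("  decline rate D: %.5f /day (%.3f /year)\n",
              x$decline_rate, daily_to_annual(x$decline_rate)))
  cat(sprintf("  saturation speed L: %.4f per log2 unit\n", x$saturation_speed))
  invisible(x)
}

#' Population-level model parameters
#'
#' Fixed effects and random-effects hyperparameters of the titer-dynamics
#' model: the maximum booster effect \eqn{B} (log2 titer, the asymptotic gain
#' at starting titer 0), the booster timing rate \eqn{H} (per day), the
#' bivariate-normal hyperparameters of the donor random effects
#' \eqn{(D_i, L_i)}, and the residual measurement SD \eqn{\sigma_\epsilon}.
#'
#' All rates are on the internal per-day scale; use [daily_to_annual()] /
#' [annual_to_daily()] to convert reported annual rates.
#'
#' @param max_effect Maximum booster-induced log2 titer gain \eqn{B} (> 0).
#' @param timing_rate Logistic speed \eqn{H} of the booster time envelope,
#'   per day (> 0).
#' @param mean_decline,sd_decline Mean and SD of the donor decline rates
#'   \eqn{D_i}, log2 per day.
#' @param mean_saturation,sd_saturation Mean and SD of the donor saturation
#'   speeds \eqn{L_i}, per log2 unit.
#' @param cov_decline_saturation Covariance between \eqn{D_i} and \eqn{L_i}
#'   (default 0; the resulting 2x2 covariance must be positive semi-definite).
#' @param residual_sd Gaussian measurement SD \eqn{\sigma_\epsilon}, log2
#'   titer units (> 0).
#' @return An object of class `"rhd_pop"`.
#' @export
population_parameters <- function(max_effect, timing_rate,
                                  mean_decline, sd_decline,
                                  mean_saturation, sd_saturation,
                                  cov_decline_saturation = 0,
                                  residual_sd) {
  stopifnot(is.finite(max_effect), max_effect > 0,
            is.finite(timing_rate), timing_rate > 0,
            is.finite(mean_decline), is.finite(mean_saturation),
            is.finite(sd_decline), sd_decline > 0,
            is.finite(sd_saturation), sd_saturation > 0,
            is.finite(residual_sd), residual_sd > 0,
            is.finite(cov_decline_saturation))
  if (cov_decline_saturation^2 > sd_decline^2 * sd_saturation^2)
    stop("covariance of (D, L) implies |correlation| > 1; not positive semi-definite")
  structure(list(max_effect = as.numeric(max_effect),
                 timing_rate = as.numeric(timing_rate),
                 mean_decline = as.numeric(mean_decline),
                 sd_decline = as.numeric(sd_decline),
                 mean_saturation = as.numeric(mean_saturation),
                 sd_saturation = as.numeric(sd_saturation),
                 cov_decline_saturation = as.numeric(cov_decline_saturation),
                 residual_sd = as.numeric(residual_sd)),
            class = "rhd_pop")
}

#' @export
print.rhd_pop <- function(x, ...) {
  cat("Population parameters (rates per day internally):\n")
  cat(sprintf("  B (max booster effect): %.4f log2\n", x$max_effect))
  cat(sprintf("  H (timing rate):        %.4f /day\n", x$timing_rate))
  cat(sprintf("  D ~ N(%.5f, %.5f^2) /day  [annual mean %.3f]\n",
              x$mean_decline, x$sd_decline, daily_to_annual(x$mean_decline)))
  cat(sprintf("  L ~ N(%.4f, %.4f^2) per log2 unit\n",
              x$mean_saturation, x$sd_saturation))
  cat(sprintf("  cov(D, L): %.3g\n", x$cov_decline_saturation))
  cat(sprintf("  residual SD: %.4f log2\n", x$residual_sd))
  invisible(x)
}

#' Mean donor implied by a population
#'
#' @param pop A [population_parameters()] object.
#' @return The [donor_parameters()] at the population means.
#' @export
population_mean_donor <- function(pop) {
  donor_parameters(pop$mean_decline, pop$mean_saturation)
}

#' One donor's longitudinal record
#'
#' Ordered donation days, the log2 titers measured at those donations, and
#' the days of booster (hyper-immunisation) events.  Donations are at least
#' 14 days apart; measured titers are non-negative (a discrete log2 dilution
#' assay yields integers, though the container accepts continuous values).
#'
#' Anonymised records (the deposited supplementary format strips all timing
#' information) carry `obs_days = NULL`; such records support counting and
#' magnitude-style summaries only, not the fitting pipeline.
#'
#' @param donor_id Opaque identifier (coerced to character).
#' @param obs_days Strictly increasing integer days since the first record,
#'   or `NULL` for records without timing information.
#' @param measured_titers Non-negative log2 titers, one per donation.
#' @param booster_days Ordered days of booster events (must be a subset of
#'   `obs_days` when days are present, as boosters are administered at
#'   donations).
#' @return An object of class `"rhd_record"`.
#' @export
donor_record <- function(donor_id, obs_days = NULL, measured_titers,
                         booster_days = integer(0)) {
  stopifnot(length(donor_id) == 1L)
  measured_titers <- as.numeric(measured_titers)
  if (any(!is.finite(measured_titers)) || any(measured_titers < 0))
    stop("measured titers must be finite and >= 0")
  if (any(measured_titers > 20))
    warning("measured titer above log2 20: outside the plausible assay range")
  if (!is.null(obs_days)) {
    obs_days <- as.numeric(obs_days)
    if (length(obs_days) != length(measured_titers))
      stop("obs_days and measured_titers must have equal length")
    if (length(obs_days) > 1 && any(diff(obs_days) <= 0))
      stop("obs_days must be strictly increasing")
    if (length(obs_days) > 1 && any(diff(obs_days) < 14))
      warning("consecutive donations fewer than 14 days apart")
    booster_days <- as.numeric(booster_days)
    if (is.unsorted(booster_days, strictly = TRUE) && length(booster_days) > 1)
      stop("booster_days must be strictly increasing")
  }
  structure(list(donor_id = as.character(donor_id),
                 obs_days = obs_days,
                 measured_titers = measured_titers,
                 booster_days = booster_days),
            class = "rhd_record")
}

#' @export
print.rhd_record <- function(x, ...) {
  cat(sprintf("Donor %s: %d titer measurements, %d booster events%s\n",
              x$donor_id, length(x$measured_titers), length(x$booster_days),
              if (is.null(x$obs_days)) " (no day information)" else
                sprintf(", follow-up %g days", max(x$obs_days))))
  invisible(x)
}

has_days <- function(record) !is.null(record$obs_days)

#' Logistic time envelope of the booster effect
#'
#' The booster response develops along a logistic time course,
#' \eqn{2(1/(1+e^{-Ht}) - 1/2)} for \eqn{t > 0} and 0 at or before the
#' booster instant.  It rises strictly with time and saturates at 1.
#'
#' @param days_since_booster Days elapsed since the booster (vectorised).
#' @param timing_rate Logistic rate \eqn{H} per day (> 0).
#' @return Values in \eqn{[0, 1)}.
#' @examples
#' booster_envelope(26, 0.2)  # 0.98905...
#' @export
booster_envelope <- function(days_since_booster, timing_rate) {
  if (!all(is.finite(days_since_booster)) || !is.finite(timing_rate))
    stop("non-finite input to booster_envelope")
  if (timing_rate <= 0) stop("timing_rate must be > 0")
  ifelse(days_since_booster <= 0, 0,
         2 * (plogis(timing_rate * days_since_booster) - 0.5))
}

#' Saturation of the booster effect with starting titer
#'
#' The booster-induced gain shrinks logistically with the titer at
#' boostering: \eqn{1 - 1/(1+e^{-L T_0})}.  Equals 1/2 at starting titer 0
#' and falls towards 0 as the starting titer grows (for \eqn{L > 0}).
#'
#' @param starting_titer Log2 titer at the booster instant (>= 0; predicted
#'   starting titers are clamped at 0 upstream).
#' @param saturation_speed Donor saturation speed \eqn{L} per log2 unit.
#' @return Values in \eqn{(0, 1]}.
#' @examples
#' booster_saturation(10, 0.3)  # 0.04743...
#' @export
booster_saturation <- function(starting_titer, saturation_speed) {
  if (!all(is.finite(starting_titer)) || !is.finite(saturation_speed))
    stop("non-finite input to booster_saturation")
  if (any(starting_titer < 0))
    stop("starting_titer must be >= 0 (clamp predicted titers upstream)")
  plogis(-saturation_speed * starting_titer)
}

#' Expected log2 titer gain from one booster
#'
#' The product form \eqn{4B(1/(1+e^{-H(t-x)}) - 1/2)(1 - 1/(1+e^{-L T_0}))},
#' i.e. `2 * B * envelope * saturation`.  At starting titer 0 the asymptotic
#' (large \eqn{t}) gain equals \eqn{B}, the maximum booster effect.
#'
#' @param starting_titer Log2 titer at boostering (>= 0).
#' @param days_since_booster Days since the booster.
#' @param max_effect Maximum booster effect \eqn{B} (log2).
#' @param timing_rate Envelope rate \eqn{H} per day.
#' @param saturation_speed Saturation speed \eqn{L} per log2 unit.
#' @return Non-negative log2 titer gain.
#' @export
booster_gain <- function(starting_titer, days_since_booster,
                         max_effect, timing_rate, saturation_speed) {
  2 * max_effect *
    booster_envelope(days_since_booster, timing_rate) *
    booster_saturation(starting_titer, saturation_speed)
}

#' Predict a donor's titer trajectory under a booster schedule
#'
#' Evaluates the integral titer model
#' \deqn{T(t) = T(0) + D t + \sum_{j : x_j \le t} 2B\,e(t - x_j)\,s(T(x_j))}
#' where \eqn{e} is the [booster_envelope()] and \eqn{s} the
#' [booster_saturation()] at the model's own predicted starting titer
#' \eqn{T(x_j)}.  Starting titers are computed forward-sequentially: the
#' titer at each booster is the model prediction using strictly earlier
#' boosters only, clamped at 0 before it enters the saturation term.  Only
#' boosters already administered (\eqn{x_j \le t}) contribute at time
#' \eqn{t}.  Reported titers are clamped at 0; the unclamped values are kept
#' alongside.
#'
#' @param booster_days Sorted days of booster events (or an [donor_record()]
#'   whose booster schedule is used).
#' @param baseline_titer Log2 titer at day 0.
#' @param donor [donor_parameters()].
#' @param pop [population_parameters()] supplying \eqn{B} and \eqn{H}.
#' @param eval_days Days (>= 0) at which to evaluate the trajectory.
#' @return An object of class `"rhd_trajectory"`: a list with `eval_days`,
#'   `titer` (clamped at 0), `titer_unclamped`, `booster_days` and
#'   `booster_starting_titers`.
#' @export
predict_trajectory <- function(booster_days, baseline_titer, donor, pop,
                               eval_days) {
  if (inherits(booster_days, "rhd_record")) booster_days <- booster_days$booster_days
  booster_days <- as.numeric(booster_days)
  if (length(booster_days) > 1 && is.unsorted(booster_days, strictly = TRUE))
    stop("booster_days must be sorted strictly increasing")
  if (any(eval_days < 0)) stop("eval_days must be >= 0")
  B <- pop$max_effect; H <- pop$timing_rate
  D <- donor$decline_rate; L <- donor$saturation_speed

  m <- length(booster_days)
  T0 <- numeric(m)
  for (j in seq_len(m)) {
    x <- booster_days[j]
    val <- baseline_titer + D * x
    if (j > 1) {
      earlier <- seq_len(j - 1L)
      val <- val + sum(2 * B * booster_envelope(x - booster_days[earlier], H) *
                         booster_saturation(pmax(0, T0[earlier]), L))
    }
    T0[j] <- max(0, val)  # predicted starting titers below 0 are rounded up to 0
  }

  raw <- baseline_titer + D * eval_days
  for (j in seq_len(m)) {
    raw <- raw + 2 * B * booster_envelope(eval_days - booster_days[j], H) *
      booster_saturation(T0[j], L)
  }
  structure(list(eval_days = eval_days,
                 titer = pmax(0, raw),
                 titer_unclamped = raw,
                 booster_days = booster_days,
                 booster_starting_titers = T0),
            class = "rhd_trajectory")
}

#' @export
print.rhd_trajectory <- function(x, ...) {
  cat(sprintf("Titer trajectory over %d days, %d boosters\n",
              as.integer(max(x$eval_days)), length(x$booster_days)))
  if (length(x$booster_days))
    cat("  starting titers at boosters:",
        paste(sprintf("%.2f", x$booster_starting_titers), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a log2 titer change to a percent change in absolute titer
#'
#' \eqn{100(2^d - 1)}: a decline of 0.55 log2 per year is a 32% annual loss
#' of absolute titer; a gain of 4.26 log2 is +1816%.
#'
#' @param delta_log2 Log2 titer change (vectorised).
#' @return Percent change of the absolute (linear-scale) titer.
#' @seealso [log2_change()] for the inverse.
#' @export
percent_change <- function(delta_log2) {
  stopifnot(all(is.finite(delta_log2)))
  100 * (2^delta_log2 - 1)
}

#' Convert a percent change in absolute titer back to a log2 change
#'
#' @param percent Percent change (> -100).
#' @return Log2 titer change; inverse of [percent_change()].
#' @export
log2_change <- function(percent) {
  stopifnot(all(is.finite(percent)), all(percent > -100))
  log2(1 + percent / 100)
}

#' @rdname rate_conversion
#' @export
annual_to_daily <- function(rate_per_year) rate_per_year / DAYS_PER_YEAR

#' Convert rates between per-day and per-year scales
#'
#' Internal computations use days; results are reported per year using
#' 365 days/year.  The conversion is exact and invertible.
#'
#' @param rate_per_year,rate_per_day Rates to convert.
#' @name rate_conversion
#' @export
daily_to_annual <- function(rate_per_day) rate_per_day * DAYS_PER_YEAR

#' Day of the peak titer response after a booster
#'
#' The post-booster mean response \eqn{2B(1/(1+e^{-Ht}) - 1/2) + Dt} is
#' maximised where \eqn{2BH p(1-p) = -D} with \eqn{p} the logistic at
#' \eqn{Ht}.  A finite positive peak exists iff \eqn{0 < -D < BH/2}; the
#' stationary point then has the closed form
#' \eqn{t^* = \mathrm{logit}(1/2 + \sqrt{1/4 + D/(2BH)})/H}.  For \eqn{D \ge 0}
#' the response increases monotonically and `Inf` is returned ("no finite
#' peak"); for \eqn{-D \ge BH/2} the decline dominates from the start and the
#' peak is at 0.
#'
#' @param max_effect Maximum booster effect \eqn{B}.
#' @param timing_rate Envelope rate \eqn{H} per day (> 0).
#' @param decline_rate Population decline rate \eqn{D} per day.
#' @return Peak day (possibly 0 or `Inf`).
#' @export
peak_day <- function(max_effect, timing_rate, decline_rate) {
  stopifnot(timing_rate > 0, is.finite(max_effect), is.finite(decline_rate))
  if (decline_rate >= 0) return(Inf)
  q <- -decline_rate / (2 * max_effect * timing_rate)
  if (q >= 0.25) return(0)        # derivative non-positive everywhere past 0
  qlogis(0.5 + sqrt(0.25 - q)) / timing_rate
}
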