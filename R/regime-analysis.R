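# Steady-state analysis of fixed-interval boostering: under a fixed
# boostering frequency a donor's titer settles into a dynamic plateau where
# the gain from each booster balances the decline over the interval.

#' Steady-state titer under fixed-interval boostering
#'
#' Iterates the one-interval map
#' \eqn{T_{pre} \mapsto \max(0,\, T_{pre} + gain(T_{pre}, \Delta) + D\Delta)}
#' (interval \eqn{\Delta} = 365/frequency) to its fixed point, at which the
#' booster gain equals the decline over one interval.  Because the gain
#' decreases with titer the map is a contraction and the plateau is stable.
#' Reports the pre-booster trough, the titer at the response peak
#' ([peak_day()]), and the time-average titer over one cycle (numerical
#' quadrature of the within-cycle trajectory).
#'
#' @param frequency Boosters per year (> 0).
#' @param donor [donor_parameters()].
#' @param pop [population_parameters()] (supplies \eqn{B} and \eqn{H}).
#' @param tol Convergence tolerance on the trough titer.
#' @param max_cycles Iteration cap; non-convergence is flagged.
#' @return Object of class `"rhd_regime"`: `frequency`, `trough_titer`,
#'   `peak_titer`, `mean_titer`, `converged`, `cycles`.
#' @export
steady_state <- function(frequency, donor, pop, tol = 1e-10,
                         max_cycles = 10000) {
  stopifnot(frequency > 0)
  interval <- DAYS_PER_YEAR / frequency
  B <- pop$max_effect; H <- pop$timing_rate
  D <- donor$decline_rate; L <- donor$saturation_speed

  step <- function(Tpre)
    max(0, Tpre + booster_gain(Tpre, interval, B, H, L) + D * interval)

  Tpre <- max(0, 10)
  converged <- FALSE
  cycles <- 0L
  for (i in seq_len(max_cycles)) {
    cycles <- i
    Tnew <- step(Tpre)
    if (abs(Tnew - Tpre) < tol) { Tpre <- Tnew; converged <- TRUE; break }
    Tpre <- Tnew
  }

  tp <- peak_day(B, H, D)
  tp <- min(tp, interval)  # peak cannot lie beyond the next booster
  cycle_titer <- function(s)
    pmax(0, Tpre + D * s + booster_gain(Tpre, s, B, H, L))
  peak <- if (is.finite(tp)) cycle_titer(tp) else cycle_titer(interval)
  mean_titer <- integrate(cycle_titer, 0, interval,
                          subdivisions = 500L)$value / interval

  structure(list(frequency = frequency, trough_titer = Tpre,
                 peak_titer = peak, mean_titer = mean_titer,
                 converged = converged, cycles = cycles,
                 interval = interval),
            class = "rhd_regime")
}

#' @export
print.rhd_regime <- function(x, ...) {
  cat(sprintf(paste0("Boostering %.2g times/year (interval %.0f d): plateau ",
                     "trough %.2f, peak %.2f, mean %.2f log2%s\n"),
              x$frequency, x$interval, x$trough_titer, x$peak_titer,
              x$mean_titer, if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Booster-gain and plateau summary table
#'
#' Builds the standard report of the fitted model: per-booster asymptotic
#' gains \eqn{2B(1 - 1/(1+e^{-L T_0}))} at a set of starting titers, and
#' plateau (steady-state) mean titers at a set of boostering frequencies, for
#' the population-average donor and the quartiles of the fitted donor
#' population.  Quartile rows pair the upper quartile of the decline rate
#' (slow decline) with the lower quartile of the saturation speed (strong
#' response) and vice versa; with per-donor estimates the empirical quantiles
#' are used, otherwise the normal quantiles of the population distribution.
#' Percent-scale conversions of the gains are appended.
#'
#' @param pop [population_parameters()] or an integral-stage
#'   `rhd_stage_fit` (whose per-donor estimates then feed the quantile rows).
#' @param starting_titers Log2 starting titers for the gain columns.
#' @param frequencies Boosters per year for the plateau columns (all > 0).
#' @return Data frame, one row per donor summary
#'   (`population_average`, `upper_quartile`, `median`, `lower_quartile`).
#' @export
regime_table <- function(pop, starting_titers = c(3, 9, 11, 13),
                         frequencies = c(0.5, 1, 1.5)) {
  if (any(frequencies <= 0))
    stop("boostering frequencies must be > 0 per year")
  donors_df <- NULL
  if (inherits(pop, "rhd_stage_fit")) {
    donors_df <- pop$donor_effects
    pop <- fit_population(pop)
  }
  q3 <- qnorm(0.75)
  rows <- list(
    population_average = c(pop$mean_decline, pop$mean_saturation),
    upper_quartile = if (is.null(donors_df))
      c(pop$mean_decline + q3 * pop$sd_decline,
        pop$mean_saturation - q3 * pop$sd_saturation)
    else c(quantile(donors_df$decline_rate, 0.75, names = FALSE),
           quantile(donors_df$saturation_speed, 0.25, names = FALSE)),
    median = if (is.null(donors_df)) c(pop$mean_decline, pop$mean_saturation)
    else c(median(donors_df$decline_rate), median(donors_df$saturation_speed)),
    lower_quartile = if (is.null(donors_df))
      c(pop$mean_decline - q3 * pop$sd_decline,
        pop$mean_saturation + q3 * pop$sd_saturation)
    else c(quantile(donors_df$decline_rate, 0.25, names = FALSE),
           quantile(donors_df$saturation_speed, 0.75, names = FALSE)))

  out <- lapply(names(rows), function(nm) {
    D <- rows[[nm]][1]; L <- rows[[nm]][2]
    gains <- 2 * pop$max_effect * booster_saturation(starting_titers, L)
    plateaus <- vapply(frequencies, function(f)
      steady_state(f, donor_parameters(D, L), pop)$mean_titer, 0)
    df <- data.frame(row = nm, annual_decline = daily_to_annual(D),
                     annual_decline_pct = percent_change(daily_to_annual(D)))
    for (i in seq_along(starting_titers)) {
      df[[sprintf("gain_at_%g", starting_titers[i])]] <- gains[i]
      df[[sprintf("gain_at_%g_pct", starting_titers[i])]] <- percent_change(gains[i])
    }
    for (i in seq_along(frequencies))
      df[[sprintf("plateau_%g_per_yr", frequencies[i])]] <- plateaus[i]
    df
  })
  do.call(rbind, out)
}

#' Render a regime table as aligned plain text
#'
#' @param table Output of [regime_table()].
#' @return Character vector of lines (also printed invisibly friendly).
#' @export
format_regime_table <- function(table) {
  num <- vapply(table, is.numeric, TRUE)
  tbl <- table
  tbl[num] <- lapply(tbl[num], function(v) sprintf("%8.2f", v))
  widths <- pmax(nchar(names(tbl)), vapply(tbl, function(c) max(nchar(c)), 0))
  pad <- function(v, w) formatC(v, width = w)
  header <- paste(mapply(pad, names(tbl), widths), collapse = "  ")
  body <- apply(mapply(pad, tbl, widths), 1, paste, collapse = "  ")
  c(header, body)
}
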