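# Dataset readers/writers.  Two CSV dialects:
#  * "s1": the anonymised deposited format -- donor_id, seq, titer,
#    boostered(0/1); all timing information removed.  Supports counting and
#    magnitude-style summaries only.
#  * "extended": adds a day column; the package's native format for
#    synthetic cohorts and everything the fitting pipeline needs.

# md5 of a deparsed R object, used to stamp outputs with their configuration
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Write donor records to CSV
#'
#' Columns `donor_id, seq, day, titer, boostered` (`day` dropped in the
#' anonymised `"s1"` dialect).  A comment header records the package
#' version, the seed (for synthetic cohorts) and a hash of the generating
#' configuration, so outputs are reproducible from their own metadata.
#'
#' @param x An `rhd_cohort` or list of [donor_record()]s.
#' @param path Output CSV path.
#' @param dialect `"extended"` (default) or `"s1"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(x, path, dialect = c("extended", "s1")) {
  dialect <- match.arg(dialect)
  records <- as_records(x)
  meta <- sprintf("# rhdtiter dataset dialect=%s", dialect)
  if (inherits(x, "rhd_cohort"))
    meta <- paste0(meta, sprintf(" seed=%d config=%s", x$seed,
                                 config_hash(x$config[setdiff(names(x$config), "pop")])))
  rows <- lapply(records, function(r) {
    n <- length(r$measured_titers)
    df <- data.frame(donor_id = rep(r$donor_id, n), seq = seq_len(n),
                     titer = r$measured_titers,
                     boostered = 0L)
    if (has_days(r)) {
      df$day <- r$obs_days
      df$boostered[r$obs_days %in% r$booster_days] <- 1L
      df <- df[, c("donor_id", "seq", "day", "titer", "boostered")]
    }
    df
  })
  df <- do.call(rbind, rows)
  if (dialect == "s1") df$day <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read donor records from CSV
#'
#' @param path CSV path with a header row (comment lines starting `#` are
#'   ignored).
#' @param dialect `"extended"` (day-resolved) or `"s1"` (anonymised, no day
#'   column; the returned records carry no timing information and cannot be
#'   fitted).
#' @param col_map Optional named character vector mapping the standard
#'   column names (`donor_id`, `seq`, `day`, `titer`, `boostered`) to the
#'   names actually used in the file.
#' @return List of [donor_record()]s.
#' @export
read_dataset <- function(path, dialect = c("extended", "s1"), col_map = NULL) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  std <- c("donor_id", "seq", "titer", "boostered",
           if (dialect == "extended") "day")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("mapped column '", col_map[[nm]], "' not found in ", path)
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(std, names(df))
  if (length(missing_cols))
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$titer))) |
                 suppressWarnings(as.numeric(df$titer)) < 0)
  if (length(bad))
    stop("malformed titer value(s) (non-numeric or negative) at data row(s): ",
         paste(head(bad, 10), collapse = ", "))
  df$titer <- as.numeric(df$titer)
  df$donor_id <- as.character(df$donor_id)
  lapply(split(df, df$donor_id)[unique(df$donor_id)], function(g) {
    g <- g[order(g$seq), , drop = FALSE]
    if (dialect == "extended")
      donor_record(g$donor_id[1], obs_days = g$day,
                   measured_titers = g$titer,
                   booster_days = g$day[g$boostered == 1])
    else {
      r <- donor_record(g$donor_id[1], obs_days = NULL,
                        measured_titers = g$titer)
      r$booster_flags <- as.integer(g$boostered)
      r
    }
  })
}

#' Summary counts of a longitudinal titer dataset
#'
#' @param records List of [donor_record()]s (either dialect).
#' @return List with `n_donors`, `n_titers`, `n_boosters`.
#' @export
dataset_summary <- function(records) {
  records <- as_records(records)
  n_boost <- vapply(records, function(r) {
    if (has_days(r)) length(r$booster_days)
    else sum(r$booster_flags)
  }, 0)
  list(n_donors = length(records),
       n_titers = as.integer(sum(vapply(records, function(r)
         length(r$measured_titers), 0))),
       n_boosters = as.integer(sum(n_boost)))
}

#' Serialise a stage fit to plain text
#'
#' Writes a flat one-parameter-per-line key-value file and, when per-donor
#' estimates are present, a companion CSV `<stem>_donors.csv` with
#' `donor_id, decline_rate, saturation_speed` (plus `mae`/`mse` when a
#' residual table is supplied).
#'
#' @param fit An `rhd_stage_fit`.
#' @param stem Output path stem (files `<stem>.txt`, `<stem>_donors.csv`).
#' @param residuals Optional output of [per_donor_residuals()].
#' @return The parameter file path, invisibly.
#' @export
write_fit <- function(fit, stem, residuals = NULL) {
  path <- paste0(stem, ".txt")
  est <- fit$estimates
  lines <- c(sprintf("# rhdtiter stage fit: %s", fit$stage),
             sprintf("stage %s", fit$stage),
             sprintf("converged %s", isTRUE(fit$converged)),
             sprintf("iterations %s", fit$iterations),
             sprintf("loglik %.10g", fit$loglik),
             vapply(names(est), function(nm)
               sprintf("%s %.10g", nm, est[[nm]]), ""))
  writeLines(lines, path)
  if (!is.null(fit$donor_effects)) {
    de <- fit$donor_effects
    if (!is.null(residuals))
      de <- merge(de, residuals[, c("donor_id", "mae", "mse")],
                  by = "donor_id", sort = FALSE)
    write.csv(de, paste0(stem, "_donors.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a serialised stage fit
#'
#' @param stem Path stem used in [write_fit()].
#' @return List with `stage`, `converged`, `iterations`, `loglik`,
#'   `estimates` and (if present) `donor_effects`.
#' @export
read_fit <- function(stem) {
  lines <- readLines(paste0(stem, ".txt"))
  lines <- lines[!startsWith(lines, "#")]
  kv <- strsplit(lines, " ", fixed = TRUE)
  keys <- vapply(kv, `[[`, "", 1)
  vals <- vapply(kv, `[[`, "", 2)
  est_keys <- setdiff(keys, c("stage", "converged", "iterations", "loglik"))
  out <- list(stage = vals[keys == "stage"],
              converged = as.logical(vals[keys == "converged"]),
              iterations = suppressWarnings(as.integer(vals[keys == "iterations"])),
              loglik = as.numeric(vals[keys == "loglik"]),
              estimates = as.list(setNames(as.numeric(vals[match(est_keys, keys)]),
                                           est_keys)))
  donors_path <- paste0(stem, "_donors.csv")
  if (file.exists(donors_path))
    out$donor_effects <- read.csv(donors_path, stringsAsFactors = FALSE)
  out
}
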