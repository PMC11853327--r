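# Reporting odds ratio engine.
#
# For a target drug vs a comparator and a set of evaluated conditions the 2x2
# table is
#       a = evaluated-condition ADRs for the target drug
#       b = all other ADRs for the target drug
#       c = evaluated-condition ADRs for the comparator
#       d = all other ADRs for the comparator
# ROR = (a*d)/(b*c); SE{ln ROR} = sqrt(1/a + 1/b + 1/c + 1/d) (Woolf);
# Wald CI = exp(ln ROR +/- z * SE). The EMA screening rule flags a
# disproportionate signal when a >= 5 reports and the lower CI bound exceeds 1.

#' Build a drug-vs-comparator 2x2 contingency table
#'
#' @param aggs A `drug_aggregates` tibble.
#' @param target Target drug name (normalized).
#' @param comparator Comparator drug name; must differ from `target`.
#' @param conditions Condition labels whose ADR counts form the evaluated
#'   cell (default: ineffectiveness).
#' @return A one-row tibble of class `ror_table`:
#'   `target,comparator,condition,a,b,c,d`.
#' @export
#' @examples
#' aggs <- spec_targets(bevpan_fixture())
#' build_table(aggs, "panitumumab", "bevacizumab", "ineffectiveness")
build_table <- function(aggs, target, comparator,
                        conditions = "ineffectiveness") {
  validate_aggregates(aggs)
  if (identical(target, comparator)) {
    stop("target and comparator must differ", call. = FALSE)
  }
  bad <- setdiff(conditions, condition_levels())
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(target, comparator), unique(aggs$drug))
  if (length(missing) > 0) {
    stop("drug(s) not present in aggregates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  a <- condition_totals(aggs, target, conditions)
  c_ <- condition_totals(aggs, comparator, conditions)
  tab <- tibble::tibble(
    target = target, comparator = comparator,
    condition = paste(conditions, collapse = "+"),
    a = a, b = drug_totals(aggs, target)$n_adrs - a,
    c = c_, d = drug_totals(aggs, comparator)$n_adrs - c_
  )
  class(tab) <- c("ror_table", class(tab))
  tab
}

#' Reporting odds ratio with Wald confidence interval
#'
#' Computes ROR = (a d)/(b c), the Woolf log-scale standard error
#' sqrt(1/a + 1/b + 1/c + 1/d), the Wald interval
#' exp(ln ROR +/- z SE), a two-sided normal p-value for ln ROR = 0, and the
#' EMA signal flag. Any zero cell makes the estimate undefined: `defined` is
#' `FALSE`, the numeric fields are `NA` and no signal is flagged (no
#' continuity correction is applied).
#'
#' @param table A `ror_table` from [build_table()], or anything with columns
#'   `a,b,c,d` (one row per comparison).
#' @param z Normal quantile for the interval; 1.96 gives the conventional
#'   95% CI.
#' @param min_reports Minimum evaluated-reaction reports (`a`) for the signal
#'   rule.
#' @return Tibble of class `ror_result`: the input identifiers plus
#'   `ror, log_se, ci_low, ci_high, p_value, n_reports, defined, signal`.
#' @export
#' @examples
#' tab <- tibble::tibble(a = 328, b = 14723, c = 1414, d = 105671)
#' compute_ror(tab)  # ROR 1.6649, CI 1.4746-1.8797
compute_ror <- function(table, z = 1.96, min_reports = 5L) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(table)))
  a <- as.numeric(table$a); b <- as.numeric(table$b)
  c_ <- as.numeric(table$c); d <- as.numeric(table$d)
  if (any(c(a, b, c_, d) < 0)) stop("negative cell count", call. = FALSE)
  defined <- a > 0 & b > 0 & c_ > 0 & d > 0

  ror <- log_se <- ci_low <- ci_high <- p_value <- rep(NA_real_, length(a))
  ror[defined] <- (a[defined] * d[defined]) / (b[defined] * c_[defined])
  log_se[defined] <- sqrt(1 / a[defined] + 1 / b[defined] +
                            1 / c_[defined] + 1 / d[defined])
  ci_low[defined] <- exp(log(ror[defined]) - z * log_se[defined])
  ci_high[defined] <- exp(log(ror[defined]) + z * log_se[defined])
  p_value[defined] <- 2 * stats::pnorm(-abs(log(ror[defined])) / log_se[defined])

  out <- tibble::as_tibble(table)
  out$ror <- ror
  out$log_se <- log_se
  out$ci_low <- ci_low
  out$ci_high <- ci_high
  out$p_value <- p_value
  out$n_reports <- as.integer(a)
  out$defined <- defined
  out$signal <- classify_signal(out, min_reports = min_reports)
  class(out) <- c("ror_result", class(out))
  out
}

#' EMA disproportionality signal rule
#'
#' A comparison is a disproportionate signal when the estimate is defined, the
#' evaluated reaction has at least `min_reports` reports for the target drug,
#' and the lower bound of the confidence interval is strictly greater than 1.
#'
#' @param result A `ror_result` tibble (or anything with `defined`,
#'   `n_reports`, `ci_low`).
#' @param min_reports Minimum report count (EMA screening uses 5).
#' @return Logical vector.
#' @export
classify_signal <- function(result, min_reports = 5L) {
  stopifnot(all(c("defined", "n_reports", "ci_low") %in% names(result)))
  as.logical(result$defined &
               result$n_reports >= min_reports &
               !is.na(result$ci_low) & result$ci_low > 1)
}

#' Run a comparator panel
#'
#' Screens one target drug against an ordered list of comparators for one
#' condition set, producing a forest-plot-ready signal table. A comparator
#' with a zero cell yields an undefined row; other comparators are unaffected.
#'
#' @param aggs A `drug_aggregates` tibble.
#' @param target Target drug name.
#' @param comparators Character vector of comparator names (order preserved).
#' @param conditions Condition labels for the evaluated cell.
#' @param z,min_reports Passed to [compute_ror()].
#' @return A `ror_result` tibble with one row per comparator.
#' @export
run_panel <- function(aggs, target, comparators,
                      conditions = "ineffectiveness",
                      z = 1.96, min_reports = 5L) {
  if (length(comparators) == 0L) {
    stop("comparator list is empty", call. = FALSE)
  }
  missing <- setdiff(c(target, comparators), unique(aggs$drug))
  if (length(missing) > 0) {
    stop("drug(s) not present in aggregates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tabs <- dplyr::bind_rows(lapply(comparators, function(cmp) {
    build_table(aggs, target, cmp, conditions)
  }))
  compute_ror(tabs, z = z, min_reports = min_reports)
}

#' Write a signal table
#'
#' CSV export of a `ror_result` with the column order
#' `target,comparator,condition,a,b,c,d,ror,ci_low,ci_high,p_value,n_reports,signal,defined`,
#' estimates at 4 decimals.
#'
#' @param result A `ror_result` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(result, path) {
  cols <- c("target", "comparator", "condition", "a", "b", "c", "d",
            "ror", "ci_low", "ci_high", "p_value", "n_reports",
            "signal", "defined")
  stopifnot(all(cols %in% names(result)))
  out <- tibble::as_tibble(result)[cols]
  for (col in c("ror", "ci_low", "ci_high")) out[[col]] <- round(out[[col]], 4)
  out$p_value <- signif(out$p_value, 4)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
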