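# Descriptive reporting statistics over per-drug aggregates.
#
# All printed percentages/ratios use half-up rounding to 2 decimals (the
# convention of the source counts); unrounded values are returned alongside.

#' Round half-up
#'
#' Commercial rounding: `.005` always rounds up, unlike base [round()]'s
#' round-half-to-even. Used for every reported percentage and ratio.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # eps guard: decimals like 1.005 sit just below their printed value in
  # binary, which would otherwise round down
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' ADRs per case report
#'
#' Ratio of reported reactions to distinct case reports for one drug.
#'
#' @param aggs A `drug_aggregates` tibble.
#' @param drug Drug name (normalized).
#' @return List with `value` (half-up, 2 dp) and `raw`.
#' @export
#' @examples
#' aggs <- spec_targets(bevpan_fixture())
#' adrs_per_icsr(aggs, "bevacizumab")$value  # 1.79
adrs_per_icsr <- function(aggs, drug) {
  tot <- drug_totals(aggs, drug)
  if (tot$n_icsrs == 0) {
    stop("undefined ratio: drug has zero ICSRs: ", drug, call. = FALSE)
  }
  raw <- tot$n_adrs / tot$n_icsrs
  list(value = round_half_up(raw, 2), raw = raw)
}

#' Share of a drug's ADRs falling in selected conditions
#'
#' Percentage of the drug's ADR rows whose PT belongs to any of the selected
#' conditions.
#'
#' @param aggs A `drug_aggregates` tibble.
#' @param drug Drug name.
#' @param conditions Character vector of condition labels (see
#'   [condition_levels()]); may be empty (gives 0).
#' @return List with `value` (percentage, half-up 2 dp), `raw`, and `n` (the
#'   selected ADR count).
#' @export
condition_proportion <- function(aggs, drug,
                                 conditions = c("resistance", "ineffectiveness")) {
  bad <- setdiff(conditions, condition_levels())
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tot <- drug_totals(aggs, drug)
  if (tot$n_adrs == 0) {
    stop("undefined proportion: drug has zero ADRs: ", drug, call. = FALSE)
  }
  n <- condition_totals(aggs, drug, conditions)
  raw <- 100 * n / tot$n_adrs
  list(value = round_half_up(raw, 2), raw = raw, n = n)
}

#' Outcome breakdown for one drug and condition
#'
#' Splits the condition's ADR rows by case outcome. Unfavorable means the
#' reported outcome was "Fatal" or "Not recovered/Not resolved". The
#' unfavorable percentage is taken over the condition's ADR rows for that
#' drug; the fatal percentage is taken over the unfavorable rows.
#'
#' @param aggs A `drug_aggregates` tibble.
#' @param drug Drug name.
#' @param condition One condition label.
#' @return Tibble with one row: `drug, condition, n_cases, n_unfavorable,
#'   n_fatal, pct_unfavorable, pct_fatal_of_unfavorable` (percentages half-up,
#'   2 dp; the fatal share is `NA` when nothing was unfavorable).
#' @export
#' @examples
#' aggs <- spec_targets(bevpan_fixture())
#' outcome_breakdown(aggs, "bevacizumab", "ineffectiveness")
outcome_breakdown <- function(aggs, drug, condition) {
  stopifnot(length(condition) == 1L, condition %in% condition_levels())
  rows <- aggs[aggs$drug == drug & aggs$condition == condition, ]
  if (nrow(rows) == 0L) {
    stop("drug not present in aggregates: ", drug, call. = FALSE)
  }
  n_cases <- sum(rows$count)
  if (n_cases == 0L) {
    stop("undefined breakdown: no ", condition, " ADRs for ", drug,
         call. = FALSE)
  }
  n_fatal <- sum(rows$count[rows$outcome == "fatal"])
  n_unfav <- n_fatal + sum(rows$count[rows$outcome == "not_recovered"])
  tibble::tibble(
    drug = drug, condition = condition,
    n_cases = n_cases, n_unfavorable = n_unfav, n_fatal = n_fatal,
    pct_unfavorable = round_half_up(100 * n_unfav / n_cases, 2),
    pct_fatal_of_unfavorable =
      if (n_unfav > 0) round_half_up(100 * n_fatal / n_unfav, 2) else NA_real_
  )
}

#' Preferred-term distribution of a drug's condition ADRs
#'
#' Counts a drug's ADR rows by dictionary PT within one condition, directly
#' from the line listing. PTs of the condition with no reports are included
#' with count 0.
#'
#' @param dataset An [icsr_dataset()].
#' @param drug Drug name (normalized).
#' @param condition `"resistance"` or `"ineffectiveness"`.
#' @param dictionary Dictionary tibble.
#' @return Tibble `pt_name,count` over the condition's dictionary PTs, sorted
#'   by decreasing count then name.
#' @export
pt_distribution <- function(dataset, drug, condition,
                            dictionary = meddra_dictionary()) {
  stopifnot(inherits(dataset, "icsr_dataset"),
            condition %in% c("resistance", "ineffectiveness"))
  rec <- dataset$records
  if (!drug %in% rec$drug) {
    stop("drug not present in dataset: ", drug, call. = FALSE)
  }
  rec <- rec[rec$drug == drug, ]
  rec$condition <- classify_pt(code = rec$pt_code, name = rec$pt_name,
                               dictionary = dictionary)
  rec <- rec[as.character(rec$condition) == condition, ]
  # canonicalize names via the code where present so count keys are uniform
  canon <- dictionary$pt_name[match(rec$pt_code, dictionary$code)]
  nm <- ifelse(is.na(canon), rec$pt_name, canon)
  pts <- dictionary$pt_name[as.character(dictionary$condition) == condition]
  counts <- table(factor(nm, levels = pts))
  out <- tibble::tibble(pt_name = pts, count = as.integer(counts))
  out[order(-out$count, out$pt_name), ]
}

#' All descriptive tables for a dataset
#'
#' Convenience wrapper running [adrs_per_icsr()], [condition_proportion()],
#' [outcome_breakdown()] and [pt_distribution()] for every drug, mirroring the
#' standard descriptive report of an EV disproportionality study.
#'
#' @param dataset An [icsr_dataset()].
#' @param dictionary Dictionary tibble.
#' @return Named list of tibbles: `reporting` (per-drug totals and ADRs/ICSR),
#'   `condition_proportions`, `outcome_breakdowns`, `pt_distributions`.
#' @export
describe_dataset <- function(dataset, dictionary = meddra_dictionary()) {
  aggs <- aggregate_icsr(dataset, dictionary)
  drugs <- sort(unique(aggs$drug))

  reporting <- dplyr::bind_rows(lapply(drugs, function(d) {
    tot <- drug_totals(aggs, d)
    tibble::tibble(drug = d, n_icsrs = tot$n_icsrs, n_adrs = tot$n_adrs,
                   adrs_per_icsr = adrs_per_icsr(aggs, d)$value)
  }))
  props <- dplyr::bind_rows(lapply(drugs, function(d) {
    p <- condition_proportion(aggs, d)
    tibble::tibble(drug = d, conditions = "resistance+ineffectiveness",
                   n = p$n, pct_of_adrs = p$value)
  }))
  breakdowns <- dplyr::bind_rows(lapply(drugs, function(d) {
    dplyr::bind_rows(lapply(c("resistance", "ineffectiveness"), function(cc) {
      if (condition_totals(aggs, d, cc) == 0) return(NULL)
      outcome_breakdown(aggs, d, cc)
    }))
  }))
  ptdist <- dplyr::bind_rows(lapply(drugs, function(d) {
    dplyr::bind_rows(lapply(c("resistance", "ineffectiveness"), function(cc) {
      out <- pt_distribution(dataset, d, cc, dictionary)
      if (sum(out$count) == 0) return(NULL)
      tibble::tibble(drug = d, condition = cc, out)
    }))
  }))
  list(reporting = reporting, condition_proportions = props,
       outcome_breakdowns = breakdowns, pt_distributions = ptdist)
}
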