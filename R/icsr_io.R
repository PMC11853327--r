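# Line-listing and aggregate-table I/O.
#
# Two on-disk formats, both UTF-8 CSV with a header row:
#   line listing : icsr_id,drug,pt_code,pt_name,outcome   (one row per ADR)
#   aggregates   : drug,n_icsrs,n_adrs,condition,outcome,count   (long form)

# EV display labels for case outcomes, keyed by the internal token.
.outcome_labels <- c(
  fatal         = "Fatal",
  not_recovered = "Not recovered/Not resolved",
  recovered     = "Recovered/Resolved",
  recovering    = "Recovering/Resolving",
  unknown       = "Unknown"
)

#' Case-outcome categories
#'
#' @return Character vector of the five outcome tokens: `fatal`,
#'   `not_recovered`, `recovered`, `recovering`, `unknown`. Unfavorable
#'   outcomes are `fatal` and `not_recovered`; favorable outcomes are
#'   `recovered` and `recovering`.
#' @export
outcome_levels <- function() names(.outcome_labels)

# Map outcome strings (EV display labels or internal tokens, case-insensitive)
# to internal tokens. Unknown strings are an error, not silently "unknown":
# dialect drift in an export should surface immediately.
parse_outcome <- function(x) {
  key <- tolower(trimws(as.character(x)))
  lookup <- stats::setNames(
    rep(names(.outcome_labels), 2L),
    c(tolower(.outcome_labels), names(.outcome_labels))
  )
  out <- lookup[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown outcome string(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  factor(unname(out), levels = outcome_levels())
}

#' Normalize an active-ingredient name
#'
#' Trims, lower-cases and collapses internal whitespace. Slash-joined
#' combination products (e.g. trifluridine/tipiracil) stay one token.
#'
#' @param raw Character vector of drug names.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_drug_name("  Bevacizumab ")
#' normalize_drug_name("Trifluridine/Tipiracil")
normalize_drug_name <- function(raw) {
  if (length(raw) == 0L) stop("empty drug name", call. = FALSE)
  out <- gsub("\\s+", " ", trimws(tolower(as.character(raw))))
  if (any(is.na(out) | out == "")) stop("empty drug name", call. = FALSE)
  out
}

#' Construct an ICSR dataset
#'
#' An ICSR dataset is a tibble of ADR records (one row per reported reaction;
#' a case may carry several) with a provenance tag. Used as the common
#' in-memory form for read, generated and synthetic line listings.
#'
#' @param records Tibble/data frame with columns `icsr_id`, `drug`, `pt_code`,
#'   `pt_name`, `outcome`. `pt_code` may be `NA` where only a name was
#'   reported (and vice versa); `outcome` may be given as EV display labels.
#' @param provenance Free-text source tag.
#' @return An object of class `icsr_dataset`.
#' @export
icsr_dataset <- function(records, provenance = "unspecified") {
  records <- tibble::as_tibble(records)
  needed <- c("icsr_id", "drug", "pt_code", "pt_name", "outcome")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- records[needed]
  records$icsr_id <- as.character(records$icsr_id)
  records$drug <- as.character(records$drug)
  records$pt_code <- suppressWarnings(as.integer(records$pt_code))
  records$pt_name <- as.character(records$pt_name)
  if (!is.factor(records$outcome)) records$outcome <- parse_outcome(records$outcome)

  bad_id <- which(is.na(records$icsr_id) | records$icsr_id == "")
  if (length(bad_id) > 0) {
    stop("row(s) with empty icsr_id: ",
         paste(utils::head(bad_id, 10), collapse = ", "), call. = FALSE)
  }
  bad_drug <- which(is.na(records$drug) | trimws(records$drug) == "")
  if (length(bad_drug) > 0) {
    stop("row(s) with empty drug: ",
         paste(utils::head(bad_drug, 10), collapse = ", "), call. = FALSE)
  }
  no_pt <- which(is.na(records$pt_code) &
                   (is.na(records$pt_name) | trimws(records$pt_name) == ""))
  if (length(no_pt) > 0) {
    stop("row(s) with neither pt_code nor pt_name: ",
         paste(utils::head(no_pt, 10), collapse = ", "), call. = FALSE)
  }
  records$drug <- normalize_drug_name(records$drug)
  structure(list(records = records, provenance = provenance),
            class = "icsr_dataset")
}

#' @export
print.icsr_dataset <- function(x, ...) {
  cat(sprintf("<icsr_dataset> %d ADR rows, %d cases, %d drugs (%s)\n",
              nrow(x$records), length(unique(x$records$icsr_id)),
              length(unique(x$records$drug)), x$provenance))
  print(x$records, ...)
  invisible(x)
}

#' Read an ICSR line listing
#'
#' Reads a CSV line listing with schema `icsr_id,drug,pt_code,pt_name,outcome`
#' into an [icsr_dataset()]. Outcome strings must be the EV display labels
#' ("Fatal", "Not recovered/Not resolved", "Recovered/Resolved",
#' "Recovering/Resolving", "Unknown") or the internal tokens; anything else is
#' rejected by name. Rows violating record invariants are rejected with their
#' row numbers.
#'
#' @param path Path to the CSV file.
#' @param dictionary Unused for parsing (classification happens at
#'   aggregation); accepted for interface symmetry.
#' @return An [icsr_dataset()].
#' @export
read_line_listing <- function(path, dictionary = meddra_dictionary()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read everything as character and let icsr_dataset() coerce, so a missing
  # column surfaces as a schema error rather than a parser warning
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  needed <- c("icsr_id", "drug", "pt_code", "pt_name", "outcome")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("line listing is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  icsr_dataset(raw, provenance = path)
}

#' Write an ICSR line listing
#'
#' @param dataset An [icsr_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_line_listing <- function(dataset, path) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  out <- dataset$records
  out$outcome <- unname(.outcome_labels[as.character(out$outcome)])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate a line listing into per-drug count tables
#'
#' Collapses ADR rows into the long-form count structure every downstream
#' stage consumes: one row per (drug, condition, outcome) with its ADR count,
#' plus per-drug totals. The counting unit for all condition counts is the ADR
#' row (reaction); `n_icsrs` counts distinct case identifiers. Counts are
#' complete over the condition x outcome grid (absent combinations are 0), so
#' conservation (sum of counts = `n_adrs`) holds by construction.
#'
#' @param dataset An [icsr_dataset()].
#' @param dictionary Dictionary tibble for PT classification.
#' @return A `drug_aggregates` tibble with columns
#'   `drug,n_icsrs,n_adrs,condition,outcome,count`.
#' @export
aggregate_icsr <- function(dataset, dictionary = meddra_dictionary()) {
  stopifnot(inherits(dataset, "icsr_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0L) stop("dataset has no records", call. = FALSE)

  rec$condition <- classify_pt(code = rec$pt_code, name = rec$pt_name,
                               dictionary = dictionary)
  totals <- dplyr::summarise(
    dplyr::group_by(rec, .data$drug),
    n_icsrs = dplyr::n_distinct(.data$icsr_id),
    n_adrs = dplyr::n(),
    .groups = "drop"
  )
  grid <- full_grid(
    drug = sort(unique(rec$drug)),
    condition = condition_levels(),
    outcome = outcome_levels()
  )
  counts <- dplyr::summarise(
    dplyr::group_by(rec, .data$drug,
                    condition = as.character(.data$condition),
                    outcome = as.character(.data$outcome)),
    count = dplyr::n(), .groups = "drop"
  )
  agg <- dplyr::left_join(grid, counts, by = c("drug", "condition", "outcome"))
  agg$count[is.na(agg$count)] <- 0L
  agg <- dplyr::left_join(agg, totals, by = "drug")
  agg <- agg[, c("drug", "n_icsrs", "n_adrs", "condition", "outcome", "count")]
  agg <- dplyr::arrange(
    agg, .data$drug,
    factor(.data$condition, levels = condition_levels()),
    factor(.data$outcome, levels = outcome_levels())
  )
  new_drug_aggregates(agg)
}

# expand.grid with data.frame-stable character columns and tidy ordering
# (first factor varies slowest), kept dependency-light.
full_grid <- function(...) {
  args <- list(...)
  grid <- rev(expand.grid(rev(args), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(grid)
}

new_drug_aggregates <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("drug_aggregates", class(x))
  validate_aggregates(x)
  x
}

#' Validate a per-drug aggregate table
#'
#' Checks the structural invariants of the long-form count table: counts are
#' non-negative integers, per-drug counts sum to `n_adrs`, and
#' `n_icsrs <= n_adrs` wherever ADRs exist.
#'
#' @param aggs A `drug_aggregates` tibble.
#' @return `aggs`, invisibly; errors name the offending drug otherwise.
#' @export
validate_aggregates <- function(aggs) {
  needed <- c("drug", "n_icsrs", "n_adrs", "condition", "outcome", "count")
  missing_cols <- setdiff(needed, names(aggs))
  if (length(missing_cols) > 0) {
    stop("aggregate table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(aggs$count < 0) || any(aggs$n_adrs < 0) || any(aggs$n_icsrs < 0)) {
    stop("aggregate counts must be non-negative", call. = FALSE)
  }
  bad_cond <- setdiff(unique(aggs$condition), condition_levels())
  if (length(bad_cond) > 0) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         call. = FALSE)
  }
  bad_out <- setdiff(unique(aggs$outcome), outcome_levels())
  if (length(bad_out) > 0) {
    stop("unknown outcome label(s): ", paste(bad_out, collapse = ", "),
         call. = FALSE)
  }
  chk <- dplyr::summarise(
    dplyr::group_by(aggs, .data$drug),
    n_adrs = .data$n_adrs[1], n_icsrs = .data$n_icsrs[1],
    total = sum(.data$count),
    consistent_totals = dplyr::n_distinct(.data$n_adrs) == 1L &&
      dplyr::n_distinct(.data$n_icsrs) == 1L,
    .groups = "drop"
  )
  bad <- chk$drug[!chk$consistent_totals | chk$total != chk$n_adrs |
                    (chk$n_adrs > 0 & chk$n_icsrs > chk$n_adrs) |
                    (chk$n_adrs > 0 & chk$n_icsrs < 1)]
  if (length(bad) > 0) {
    stop("aggregate invariants violated for drug(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(aggs)
}

#' Read / write per-drug aggregate count tables
#'
#' Long-form CSV with schema `drug,n_icsrs,n_adrs,condition,outcome,count`.
#' `read_aggregate_table(write_aggregate_table(x))` is the identity. Reading
#' validates the structural invariants and reports the offending drug on
#' failure.
#'
#' @param path CSV path.
#' @return A validated `drug_aggregates` tibble.
#' @export
read_aggregate_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  agg <- readr::read_csv(
    path,
    col_types = readr::cols(
      drug = readr::col_character(),
      n_icsrs = readr::col_integer(),
      n_adrs = readr::col_integer(),
      condition = readr::col_character(),
      outcome = readr::col_character(),
      count = readr::col_integer()
    ),
    progress = FALSE
  )
  new_drug_aggregates(agg)
}

#' @rdname read_aggregate_table
#' @param aggs A `drug_aggregates` tibble.
#' @export
write_aggregate_table <- function(aggs, path) {
  validate_aggregates(aggs)
  readr::write_csv(tibble::as_tibble(aggs), path, progress = FALSE)
  invisible(path)
}

# Per-drug condition totals (sum over outcomes); internal helper used by the
# descriptive and disproportionality layers.
condition_totals <- function(aggs, drug, conditions = condition_levels()) {
  rows <- aggs[aggs$drug == drug & aggs$condition %in% conditions, ]
  if (nrow(rows) == 0L && !drug %in% aggs$drug) {
    stop("drug not present in aggregates: ", drug, call. = FALSE)
  }
  sum(rows$count)
}

drug_totals <- function(aggs, drug) {
  rows <- aggs[aggs$drug == drug, ]
  if (nrow(rows) == 0L) {
    stop("drug not present in aggregates: ", drug, call. = FALSE)
  }
  list(n_icsrs = rows$n_icsrs[1], n_adrs = rows$n_adrs[1])
}
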