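# Seeded synthetic ICSR generator.
#
# Two modes:
#   exact  — every target count is reproduced exactly; ADRs are dealt to cases
#            round-robin so aggregate(generate(spec)) inverts the spec.
#   sample — condition/PT/outcome of each ADR row is a multinomial draw around
#            the target proportions; totals n_adrs stay fixed.

#' Build a synthetic ICSR specification
#'
#' A synthetic spec holds, per drug, the target number of distinct cases
#' (`n_icsrs`), ADR rows (`n_adrs`), and per-condition ADR counts broken down
#' by outcome and (optionally) by preferred term. [generate_icsr()] turns it
#' into a line-listing dataset.
#'
#' @param drugs Named list: one entry per drug (name = drug name), each a list
#'   with elements
#'   \describe{
#'     \item{n_icsrs}{target distinct case count;}
#'     \item{conditions}{named list over condition labels, each a list with
#'       `outcomes` (named integer vector over [outcome_levels()], absent
#'       outcomes = 0) and optional `pt_weights` (named numeric vector over
#'       the condition's dictionary PT names; exact mode treats integer
#'       weights as counts, otherwise apportions largest-remainder).}
#'   }
#'   `n_adrs` is implied: the sum of all condition outcome counts.
#' @param mode `"exact"` or `"sample"`.
#' @param seed Integer seed for the generator's pseudo-random stream.
#' @param other_pt_name PT name used for ADRs in the `other` condition (a
#'   stand-in for the long tail of unrelated PTs; it carries no MedDRA code).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(drugs, mode = c("exact", "sample"), seed = 1L,
                           other_pt_name = "Nausea") {
  mode <- match.arg(mode)
  stopifnot(is.list(drugs), length(drugs) > 0, !is.null(names(drugs)))
  names(drugs) <- normalize_drug_name(names(drugs))
  if (anyDuplicated(names(drugs)) > 0) {
    stop("duplicate drug names in spec after normalization", call. = FALSE)
  }
  drugs <- lapply(drugs, function(d) {
    conds <- d$conditions
    bad <- setdiff(names(conds), condition_levels())
    if (length(bad) > 0) {
      stop("unknown condition(s) in spec: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    conds <- lapply(conds, function(cc) {
      oc <- cc$outcomes
      bad_o <- setdiff(names(oc), outcome_levels())
      if (length(bad_o) > 0) {
        stop("unknown outcome(s) in spec: ", paste(bad_o, collapse = ", "),
             call. = FALSE)
      }
      full <- stats::setNames(integer(length(outcome_levels())), outcome_levels())
      full[names(oc)] <- as.integer(oc)
      if (any(full < 0)) stop("negative outcome count in spec", call. = FALSE)
      list(outcomes = full, pt_weights = cc$pt_weights)
    })
    n_adrs <- sum(vapply(conds, function(cc) sum(cc$outcomes), numeric(1)))
    n_icsrs <- as.integer(d$n_icsrs)
    if (is.na(n_icsrs) || n_icsrs < 0) {
      stop("n_icsrs must be a non-negative integer", call. = FALSE)
    }
    if (n_adrs > 0 && (n_icsrs < 1 || n_icsrs > n_adrs)) {
      stop("infeasible spec: need 1 <= n_icsrs <= n_adrs (got n_icsrs=",
           n_icsrs, ", n_adrs=", n_adrs, ")", call. = FALSE)
    }
    if (n_adrs == 0 && n_icsrs != 0) {
      stop("infeasible spec: n_icsrs > 0 with no ADRs", call. = FALSE)
    }
    list(n_icsrs = n_icsrs, n_adrs = as.integer(n_adrs), conditions = conds)
  })
  structure(list(drugs = drugs, mode = mode, seed = as.integer(seed),
                 other_pt_name = other_pt_name),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> mode=%s seed=%d, %d drug(s):\n",
              x$mode, x$seed, length(x$drugs)))
  for (nm in names(x$drugs)) {
    d <- x$drugs[[nm]]
    cat(sprintf("  %-22s n_icsrs=%7d n_adrs=%7d\n", nm, d$n_icsrs, d$n_adrs))
  }
  invisible(x)
}

# Apportion `total` over `weights` with the largest-remainder rule; ties go to
# the earlier name. Deterministic; exact when weights are already counts.
apportion <- function(total, weights) {
  if (total == 0L) return(stats::setNames(integer(length(weights)), names(weights)))
  if (sum(weights) <= 0) stop("weights must have positive sum", call. = FALSE)
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    order_idx <- order(quota - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

# Resolve per-PT counts for one condition block of exact mode.
resolve_pt_counts <- function(cond_label, total, pt_weights, dictionary,
                              other_pt_name) {
  if (cond_label == "other") {
    return(stats::setNames(as.integer(total), other_pt_name))
  }
  pts <- dictionary$pt_name[as.character(dictionary$condition) == cond_label]
  if (is.null(pt_weights)) {
    pt_weights <- stats::setNames(rep(1, length(pts)), pts)
  } else {
    bad <- setdiff(names(pt_weights), pts)
    if (length(bad) > 0) {
      stop("pt_weights name(s) not in the ", cond_label, " dictionary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    missing <- setdiff(pts, names(pt_weights))
    pt_weights <- c(pt_weights, stats::setNames(rep(0, length(missing)), missing))
    pt_weights <- pt_weights[pts]
  }
  apportion(total, pt_weights)
}

# Run `expr` under a private RNG stream seeded with `seed`; the caller's
# .Random.seed is untouched.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic ICSR line listing
#'
#' In exact mode the generated dataset aggregates back to the spec's targets
#' exactly: each (condition, PT, outcome) cell contributes precisely its
#' target number of ADR rows, and rows are dealt to `n_icsrs` case ids
#' round-robin, so the distinct-case count is exact and ADRs-per-case is as
#' uniform as the totals allow. In sample mode each of the `n_adrs` rows draws
#' its (condition, PT, outcome) cell from the multinomial distribution given
#' by the target proportions; equal spec and seed give identical output.
#'
#' @param spec A [synthetic_spec()].
#' @param dictionary Dictionary tibble for PT names and codes.
#' @return An [icsr_dataset()] (provenance `"synthetic:<mode>:<seed>"`).
#' @export
generate_icsr <- function(spec, dictionary = meddra_dictionary()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  per_drug <- lapply(names(spec$drugs), function(drug) {
    d <- spec$drugs[[drug]]
    if (d$n_adrs == 0L) return(NULL)
    cells <- drug_cells(d, dictionary, spec$other_pt_name)
    if (spec$mode == "sample") {
      idx <- with_rng(spec$seed + match(drug, names(spec$drugs)), {
        sample.int(nrow(cells), size = d$n_adrs, replace = TRUE,
                   prob = cells$n / sum(cells$n))
      })
      rows <- cells[idx, c("pt_code", "pt_name", "outcome")]
    } else {
      rows <- cells[rep.int(seq_len(nrow(cells)), cells$n),
                    c("pt_code", "pt_name", "outcome")]
    }
    n <- nrow(rows)
    rows$icsr_id <- sprintf("%s-%06d", toupper(substr(drug, 1, 3)),
                            ((seq_len(n) - 1L) %% d$n_icsrs) + 1L)
    rows$drug <- drug
    rows[, c("icsr_id", "drug", "pt_code", "pt_name", "outcome")]
  })
  records <- dplyr::bind_rows(per_drug)
  icsr_dataset(records,
               provenance = sprintf("synthetic:%s:%d", spec$mode, spec$seed))
}

# Expand one drug block into (condition, pt, outcome) cells with target counts.
drug_cells <- function(d, dictionary, other_pt_name) {
  out <- list()
  for (cond in names(d$conditions)) {
    cc <- d$conditions[[cond]]
    cond_total <- sum(cc$outcomes)
    if (cond_total == 0L) next
    pt_counts <- resolve_pt_counts(cond, cond_total, cc$pt_weights,
                                   dictionary, other_pt_name)
    pt_counts <- pt_counts[pt_counts > 0]
    # joint PT x outcome allocation: lay PT blocks end-to-end, then deal the
    # outcome multiset across them in a fixed order (totals only are pinned)
    pt_seq <- rep.int(names(pt_counts), pt_counts)
    outcome_seq <- rep.int(names(cc$outcomes), cc$outcomes)
    grid <- tibble::tibble(pt_name = pt_seq, outcome = outcome_seq)
    cell <- dplyr::summarise(
      dplyr::group_by(grid, .data$pt_name, .data$outcome),
      n = dplyr::n(), .groups = "drop"
    )
    cell$pt_code <- dictionary$code[match(cell$pt_name, dictionary$pt_name)]
    cell$condition <- cond
    out[[cond]] <- cell
  }
  cells <- dplyr::bind_rows(out)
  cells[order(match(cells$condition, condition_levels()),
              cells$pt_name, match(cells$outcome, outcome_levels())), ]
}

# Split n into unfavorable-complement outcome counts: half favorable (split
# evenly recovered/recovering) and half unknown; deterministic integer split.
split_non_unfavorable <- function(n) {
  fav <- n %/% 2L
  c(recovered = (fav + 1L) %/% 2L, recovering = fav %/% 2L,
    unknown = n - fav)
}

#' Study fixture: published bevacizumab/panitumumab aggregates
#'
#' Returns the exact-mode [synthetic_spec()] encoding the published
#' EudraVigilance aggregates for bevacizumab (BEV) and panitumumab (PAN) as of
#' 1 December 2024: ICSR/ADR totals (BEV 59,693 / 107,085; PAN 7,178 /
#' 15,051), resistance and ineffectiveness ADR counts (91/18 and 1,414/328),
#' the published per-PT splits, and the unfavorable outcome breakdowns
#' (resistance: 10/1 unfavorable with 8/1 fatal; ineffectiveness: 181/16
#' unfavorable with 92/4 fatal). Counts not published are filled
#' deterministically: remaining PT mass within a condition is spread uniformly
#' over the condition's unlisted dictionary PTs, and non-unfavorable outcomes
#' are split half favorable, half unknown.
#'
#' @param seed Seed stored in the spec (exact mode is deterministic; the seed
#'   only matters if the spec is switched to sample mode).
#' @return A `synthetic_spec` whose generated dataset aggregates back to every
#'   published count.
#' @export
bevpan_fixture <- function(seed = 20241201L) {
  dict <- meddra_dictionary()
  ineff_pts <- dict$pt_name[as.character(dict$condition) == "ineffectiveness"]

  # helper: named PT counts with the remainder spread uniformly over the rest
  pt_split <- function(listed, total, pts) {
    rest <- setdiff(pts, names(listed))
    remainder <- total - sum(listed)
    stopifnot(remainder >= 0)
    c(listed, apportion(remainder, stats::setNames(rep(1, length(rest)), rest)))
  }
  outcome_block <- function(total, unfavorable, fatal) {
    not_rec <- unfavorable - fatal
    stopifnot(not_rec >= 0, unfavorable <= total)
    rest <- split_non_unfavorable(total - unfavorable)
    c(fatal = fatal, not_recovered = not_rec, rest)
  }

  bev <- list(
    n_icsrs = 59693L,
    conditions = list(
      resistance = list(
        outcomes = outcome_block(91L, 10L, 8L),
        pt_weights = c("Drug resistance" = 82, "Multiple drug resistance" = 9)
      ),
      ineffectiveness = list(
        outcomes = outcome_block(1414L, 181L, 92L),
        pt_weights = pt_split(
          c("Drug ineffective" = 768, "Therapy partial responder" = 179,
            "Therapy non-responder" = 136,
            "Therapeutic product effect incomplete" = 112),
          1414L, ineff_pts
        )
      ),
      other = list(outcomes = outcome_block(107085L - 1505L, 0L, 0L))
    )
  )
  pan <- list(
    n_icsrs = 7178L,
    conditions = list(
      resistance = list(
        outcomes = outcome_block(18L, 1L, 1L),
        pt_weights = c("Drug resistance" = 17, "Multiple drug resistance" = 1)
      ),
      ineffectiveness = list(
        outcomes = outcome_block(328L, 16L, 4L),
        pt_weights = pt_split(
          c("Drug ineffective" = 60, "Therapy partial responder" = 172,
            "Therapy non-responder" = 14,
            "Therapeutic product effect incomplete" = 52),
          328L, ineff_pts
        )
      ),
      other = list(outcomes = outcome_block(15051L - 346L, 0L, 0L))
    )
  )
  synthetic_spec(list(bevacizumab = bev, panitumumab = pan),
                 mode = "exact", seed = seed)
}

#' Target aggregates implied by a synthetic spec
#'
#' Computes, without generating any records, the `drug_aggregates` table an
#' exact-mode [generate_icsr()] run must reproduce. Useful for round-trip
#' checks and for feeding downstream stages with pinned counts directly.
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `drug_aggregates` tibble.
#' @export
spec_targets <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  for (drug in sort(names(spec$drugs))) {
    d <- spec$drugs[[drug]]
    for (cond in condition_levels()) {
      oc <- if (cond %in% names(d$conditions)) {
        d$conditions[[cond]]$outcomes
      } else {
        stats::setNames(integer(length(outcome_levels())), outcome_levels())
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        drug = drug, n_icsrs = d$n_icsrs, n_adrs = d$n_adrs,
        condition = cond, outcome = outcome_levels(),
        count = as.integer(oc[outcome_levels()])
      )
    }
  }
  new_drug_aggregates(dplyr::bind_rows(rows))
}
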