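# Shared fixtures and independent oracles for the suite.

# Tiny in-memory line listing (3 cases, 2 drugs, 4 ADR rows).
tiny_records <- function() {
  tibble::tibble(
    icsr_id = c("C1", "C1", "C2", "C3"),
    drug = c("Bevacizumab", "Bevacizumab", "Panitumumab", "Bevacizumab"),
    pt_code = c(10059866L, NA, 10013709L, NA),
    pt_name = c("Drug resistance", "Nausea", NA, "Headache"),
    outcome = c("Fatal", "Recovered/Resolved", "Unknown",
                "Not recovered/Not resolved")
  )
}

tiny_dataset <- function() icsr_dataset(tiny_records(), provenance = "test")

# The published-aggregate fixture dataset is expensive-ish (122k rows); build
# it once per test run.
.fixture_cache <- new.env(parent = emptyenv())
fixture_dataset <- function() {
  if (is.null(.fixture_cache$ds)) {
    .fixture_cache$ds <- generate_icsr(bevpan_fixture())
  }
  .fixture_cache$ds
}
fixture_aggs <- function() {
  if (is.null(.fixture_cache$aggs)) {
    .fixture_cache$aggs <- aggregate_icsr(fixture_dataset())
  }
  .fixture_cache$aggs
}

# Random feasible synthetic spec with small counts: 2-4 drugs, arbitrary
# condition/outcome/PT splits. Draws from the current RNG stream.
random_spec <- function(mode = "exact", seed = 1L) {
  dict <- meddra_dictionary()
  n_drugs <- sample(2:4, 1)
  drugs <- stats::setNames(vector("list", n_drugs),
                           paste0("drug", sample.int(1000, n_drugs)))
  for (i in seq_along(drugs)) {
    conds <- list()
    for (cond in condition_levels()) {
      if (stats::runif(1) < 0.25) next  # some conditions absent
      oc <- sample(0:8, 5, replace = TRUE)
      names(oc) <- outcome_levels()
      if (sum(oc) == 0) next
      block <- list(outcomes = oc)
      if (cond != "other" && stats::runif(1) < 0.5) {
        pts <- dict$pt_name[as.character(dict$condition) == cond]
        w <- sample(seq_along(pts))
        block$pt_weights <- stats::setNames(w, pts)
      }
      conds[[cond]] <- block
    }
    if (length(conds) == 0) {
      conds$other <- list(outcomes = c(unknown = 1L))
    }
    n_adrs <- sum(vapply(conds, function(cc) sum(cc$outcomes), numeric(1)))
    drugs[[i]] <- list(n_icsrs = sample.int(n_adrs, 1), conditions = conds)
  }
  synthetic_spec(drugs, mode = mode, seed = seed)
}

# Independent brute-force 2x2 tally from a raw line listing: classify each row
# by direct dictionary lookup and count with a plain loop. Deliberately avoids
# classify_pt / aggregate_icsr.
brute_force_table <- function(records, target, comparator, conditions) {
  dict <- meddra_dictionary()
  a <- b <- cc <- d <- 0L
  for (i in seq_len(nrow(records))) {
    drug <- tolower(trimws(records$drug[i]))
    if (!drug %in% c(target, comparator)) next
    code <- records$pt_code[i]
    if (!is.na(code)) {
      hit <- which(dict$code == code)
    } else {
      hit <- which(tolower(dict$pt_name) == tolower(trimws(records$pt_name[i])))
    }
    cond <- if (length(hit) == 1) as.character(dict$condition[hit]) else "other"
    evaluated <- cond %in% conditions
    if (drug == target) {
      if (evaluated) a <- a + 1L else b <- b + 1L
    } else {
      if (evaluated) cc <- cc + 1L else d <- d + 1L
    }
  }
  c(a = a, b = b, c = cc, d = d)
}

# Independent ROR oracle: literal textbook cross-product ratio and Woolf CI.
oracle_ror <- function(a, b, c, d, z = 1.96) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, ci_low = exp(log(ror) - z * se),
       ci_high = exp(log(ror) + z * se))
}
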