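#!/usr/bin/env Rscript
# Stage 4 — reporting odds ratio screening.
#
# Head-to-head panitumumab vs bevacizumab for both conditions (all four cells
# derive from published counts), then a demonstration panel against the
# study's twelve comparator drugs. The portal does not publish the
# comparators' condition counts, so the panel runs on synthetic aggregates
# with plausible reporting volumes; its numbers illustrate the screening
# machinery, not the published comparator estimates.

suppressMessages(library(rorsignal))

if (!file.exists("results/aggregates.csv")) {
  stop("run analysis/02_aggregate.R first (expects results/aggregates.csv)")
}
aggs <- read_aggregate_table("results/aggregates.csv")

head2head <- dplyr::bind_rows(
  compute_ror(build_table(aggs, "panitumumab", "bevacizumab", "resistance")),
  compute_ror(build_table(aggs, "panitumumab", "bevacizumab", "ineffectiveness"))
)
write_signal_table(head2head, "results/signal_pan_vs_bev.csv")
cat("panitumumab vs bevacizumab:\n")
print(as.data.frame(head2head[, c("condition", "a", "ror", "ci_low",
                                  "ci_high", "signal")]), row.names = FALSE)

# Synthetic comparator panel: systemic, targeted and immunotherapy agents
# used in colorectal cancer. Volumes are round stand-ins (not published data);
# the panel exercises ordering, undefined rows and the signal rule at scale.
comparators <- c("capecitabine", "5-fluorouracil", "oxaliplatin", "irinotecan",
                 "trifluridine/tipiracil", "adagrasib", "aflibercept",
                 "regorafenib", "sotorasib", "dostarlimab", "nivolumab",
                 "pembrolizumab")
mk <- function(n_res, n_ineff, n_other, n_icsrs) {
  list(n_icsrs = n_icsrs, conditions = list(
    resistance = list(outcomes = c(unknown = n_res)),
    ineffectiveness = list(outcomes = c(unknown = n_ineff)),
    other = list(outcomes = c(unknown = n_other))
  ))
}
panel_spec <- synthetic_spec(c(
  list(panitumumab = mk(18L, 328L, 14705L, 7178L)),
  stats::setNames(lapply(seq_along(comparators), function(i) {
    mk(5L * i, 40L * i, 20000L + 1000L * i, 10000L + 500L * i)
  }), comparators)
), mode = "exact", seed = 42L)
panel_aggs <- aggregate_icsr(generate_icsr(panel_spec))

panel <- dplyr::bind_rows(
  run_panel(panel_aggs, "panitumumab", comparators, "resistance"),
  run_panel(panel_aggs, "panitumumab", comparators, "ineffectiveness")
)
write_signal_table(panel, "results/signal_panel_synthetic.csv")
cat(sprintf("\nsynthetic comparator panel: %d comparisons, %d flagged\n",
            nrow(panel), sum(panel$signal)))
cat("wrote results/signal_pan_vs_bev.csv and results/signal_panel_synthetic.csv\n")
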