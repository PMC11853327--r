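#!/usr/bin/env Rscript
# Stage 2 — collapse the line listing into per-drug count tables.
#
# Counting unit: the ADR row (reaction); n_icsrs counts distinct cases. The
# long-form table (drug, condition, outcome, count) feeds both the
# descriptive and the disproportionality stages.

suppressMessages(library(rorsignal))

if (!file.exists("results/line_listing.csv")) {
  stop("run analysis/01_simulate.R first (expects results/line_listing.csv)")
}
dataset <- read_line_listing("results/line_listing.csv")
aggs <- aggregate_icsr(dataset)
write_aggregate_table(aggs, "results/aggregates.csv")

for (drug in unique(aggs$drug)) {
  rows <- aggs[aggs$drug == drug, ]
  cat(sprintf("%-12s %6d ICSRs, %6d ADRs (%d resistance, %d ineffectiveness)\n",
              drug, rows$n_icsrs[1], rows$n_adrs[1],
              sum(rows$count[rows$condition == "resistance"]),
              sum(rows$count[rows$condition == "ineffectiveness"])))
}
cat("wrote results/aggregates.csv\n")
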