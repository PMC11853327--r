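#!/usr/bin/env Rscript
# Stage 3 — descriptive reporting statistics.
#
# Per drug: ADRs per case report, the share of ADRs tied to resistance or
# ineffectiveness, the PT distribution within each condition, and the
# unfavorable-outcome breakdown (unfavorable = Fatal or Not recovered).

suppressMessages(library(rorsignal))

if (!file.exists("results/line_listing.csv")) {
  stop("run analysis/01_simulate.R first (expects results/line_listing.csv)")
}
dataset <- read_line_listing("results/line_listing.csv")
desc <- describe_dataset(dataset)

for (nm in names(desc)) {
  readr::write_csv(desc[[nm]], file.path("results", paste0(nm, ".csv")))
}

cat("reporting intensity:\n")
print(as.data.frame(desc$reporting), row.names = FALSE)
cat("\nshare of ADRs tied to resistance or ineffectiveness:\n")
print(as.data.frame(desc$condition_proportions), row.names = FALSE)
cat("\noutcome breakdowns (percent unfavorable; percent fatal of those):\n")
print(as.data.frame(desc$outcome_breakdowns), row.names = FALSE)
cat("\nwrote", length(desc), "tables under results/\n")
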