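#!/usr/bin/env Rscript
# Stage 1 — materialize the study dataset.
#
# The EudraVigilance web portal only exposes aggregated counts, so the study
# dataset is reconstructed synthetically: the exact-count generator emits an
# ICSR line listing whose aggregates are pinned to every published
# bevacizumab/panitumumab count (ICSR/ADR totals, per-condition ADR counts,
# PT splits, unfavorable-outcome breakdowns).

suppressMessages(library(rorsignal))
dir.create("results", showWarnings = FALSE)

spec <- bevpan_fixture()
print(spec)
write_synthetic_spec(spec, "results/bevpan_spec.json")

dataset <- generate_icsr(spec)
print(dataset, n = 3)
write_line_listing(dataset, "results/line_listing.csv")

cat(sprintf("wrote %d ADR rows across %d cases to results/line_listing.csv\n",
            nrow(dataset$records), length(unique(dataset$records$icsr_id))))
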