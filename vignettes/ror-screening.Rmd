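---
title: "Reporting odds ratio screening for drug resistance and ineffectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio screening for drug resistance and ineffectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rorsignal)
```

## The problem

Spontaneous reporting databases such as EudraVigilance collect Individual
Case Safety Reports (ICSRs); each report carries one or more adverse drug
reactions (ADRs) coded as MedDRA preferred terms (PTs). Lack of benefit is
itself reportable: PTs such as "Drug resistance" or "Drug ineffective"
describe treatment that stopped working or never worked. For drugs used in
the same clinical context, comparing how often such PTs are reported for one
drug versus another is a cheap, hypothesis-generating screen for differential
real-world effectiveness — here, bevacizumab (BEV) and panitumumab (PAN),
monoclonal antibodies used first-line in metastatic colorectal cancer.

Disproportionality analysis quantifies "more often than expected" with the
reporting odds ratio (ROR). It is a screening statistic on reporting
behaviour, not an incidence or risk estimate: spontaneous data are
under-reported, duplicated, and confounded by prescription volume and
channeling, so a flagged comparison is a prompt for pharmacological
follow-up, never a causal claim.

## Model and signal rule

For a target drug, a comparator, and a set of evaluated conditions, the ADR
rows cross-tabulate as `a` (evaluated, target), `b` (other, target), `c`
(evaluated, comparator), `d` (other, comparator). The package computes

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{SE}\{\ln \mathrm{ROR}\} = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},$$

the Wald interval $\exp(\ln \mathrm{ROR} \pm z\,\mathrm{SE})$ with $z = 1.96$,
and a two-sided normal p-value for $\ln \mathrm{ROR} = 0$. The EMA-style
screening rule flags a signal when $a \ge 5$ and the lower CI bound exceeds 1
strictly. Key numerical choices:

* **Zero cells.** Any empty cell makes the estimate undefined (`defined =
  FALSE`, numeric fields `NA`). No Haldane–Anscombe continuity correction is
  applied: screening practice drops such pairs, and a corrected estimate
  would silently change the flagged set.
* **Counting unit.** All condition counts are ADR rows (reactions), not
  cases, matching the definition of `b` as the target drug's *other ADRs*;
  `n_icsrs` counts distinct case identifiers and is reported separately.
  `n_reports` in the signal rule is `a`, the evaluated-reaction row count.
* **Precision.** Estimates are carried unrounded and written at 4 decimals;
  reported percentages use half-up rounding at 2 decimals (with an epsilon
  guard so decimals stored just below their printed value, like 1.005, still
  round up).
* **No multiplicity adjustment** across a comparator panel — the convention
  in screening; a caveat for interpretation, since a 12-comparator panel at
  the 95% level will flag spurious pairs at a non-trivial rate.
* `z` and `min_reports` are arguments (`compute_ror(z =)`,
  `classify_signal(min_reports =)`) for sensitivity analyses; defaults 1.96
  and 5 are the screening convention.

## The PT dictionary

The dictionary is data, not code: a packaged CSV
(`inst/extdata/meddra_conditions.csv`) with 13 entries — 2 resistance PTs and
11 ineffectiveness PTs. Classification is by MedDRA code when present,
otherwise by case-insensitive exact name after trimming; anything else is
`other`. Fuzzy matching is deliberately absent (a misclassified PT silently
moves counts between `a` and `b`), and when a row's code and name disagree
the code wins with a warning. Users can point `meddra_dictionary(path =)` at
an extended CSV for other conditions; the run manifest records the
dictionary's checksum so a changed term set is visible in outputs.

## The synthetic generator

The public EV portal exposes aggregated counts, not row-level exports, so the
package reconstructs a line listing synthetically.

**Exact mode** inverts aggregation: every (drug, condition, PT, outcome)
target count is emitted exactly, and rows are dealt to `n_icsrs` case ids
round-robin, making ADRs-per-case as uniform as the totals allow. This is the
mode behind `bevpan_fixture()`, which pins every published BEV/PAN aggregate:
59,693/7,178 ICSRs, 107,085/15,051 ADRs, resistance 91/18, ineffectiveness
1,414/328, the published PT splits (e.g. "Drug resistance" 82/17, "Drug
ineffective" 768/60, "Therapy partial responder" 179/172), and the
unfavorable-outcome breakdowns (10/1 resistance with 8/1 fatal; 181/16
ineffectiveness with 92/4 fatal).

Counts the aggregates do not pin are filled by fixed, documented defaults:

* remaining PT mass within a condition spreads uniformly over the
  condition's unlisted dictionary PTs (largest-remainder apportionment);
* outcomes not reported as unfavorable split half favorable (recovered /
  recovering, evenly) and half unknown — an arbitrary 50/50 choice, since
  favorable and unknown counts are not published separately; only the
  unfavorable cells feed the reproduced statistics, so this choice affects no
  reported number;
* `other`-condition ADRs carry the placeholder PT "Nausea" with no code.

**Sample mode** keeps each drug's `n_adrs` fixed and draws every row's
(condition, PT, outcome) cell from the multinomial given by the target
proportions. One explicit seed (per spec, offset per drug) drives the stream,
the caller's RNG state is untouched, and equal spec + seed gives
byte-identical files.

**What the fixture is not.** It emulates marginal counts only: no reporting
dynamics over time, no duplicate reports, no within-case PT correlation, no
drug–drug interaction structure, and a single placeholder PT for the
unrelated-ADR mass. Tests passing on it validate the arithmetic of the
pipeline — classification, aggregation, descriptive ratios, the ROR engine —
on data whose margins match reality; they say nothing about data-quality
pathologies of real spontaneous reports.

## Design choices in the data layer

* File dialects are fixed (UTF-8 CSV, header, quoted fields allowed) so
  fixtures and round-trips are bit-exact.
* Unknown outcome strings are an error naming the string, never silently
  mapped to `unknown`: dialect drift in an export should fail loudly.
* A case listing the same drug on several rows contributes each row; EV
  aggregates are row-based and no deduplication rule is published.
* Drug names normalize to trimmed, lower-case, single-spaced strings;
  slash-joined combinations (trifluridine/tipiracil) stay one token.

## What the workflow reproduces, and what it cannot

With the fixture, the pipeline reproduces the published descriptive figures
(ADRs/ICSR 1.79 and 2.10; condition shares 1.41% and 2.30%; unfavorable
percentages 10.99%, 12.80%, 4.88%; fatal shares 80%, 50.83%, 25.00%) and the
head-to-head ineffectiveness comparison — ROR 1.6649, 95% CI 1.4746–1.8797,
a signal — while the resistance comparison (ROR 1.41, CI 0.85–2.33) correctly
fails the rule. `scripts/acceptance.R` recomputes exactly these quantities
end-to-end.

```{r example}
aggs <- aggregate_icsr(generate_icsr(bevpan_fixture()))
compute_ror(build_table(aggs, "panitumumab", "bevacizumab",
                        "ineffectiveness"))[, c("a", "ror", "ci_low",
                                                "ci_high", "signal")]
```

Two published quantities are *not* reproducible from printed counts and are
deliberately out of reach:

* the comparator-panel RORs (nivolumab, pembrolizumab, oxaliplatin, …) —
  the comparators' condition counts are not published, so those panels run on
  synthetic aggregates only (`analysis/04_disproportionality.R`);
* the "0.53%" unfavorable share quoted for PAN resistance — the raw counts
  give 1/18 = 5.56%, and no published denominator yields 0.53; the package
  reports 5.56 from the counts and leaves the discrepancy documented here.

## Problem sizes

The study fixture is desk-scale: 122,136 ADR rows across two drugs, generated
and aggregated in about a second. Property-style tests run the generator
round-trip, brute-force tally equivalence and the engine's invariants
(antisymmetry under target/comparator swap, CI log-symmetry, monotonicity,
invariance under cell scaling) over 100 randomized small panels, and
sample-mode convergence is checked at 10^5 draws within three standard
errors.
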