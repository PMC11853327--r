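# rorsignal

Disproportionality analysis of spontaneous adverse-drug-reaction (ADR)
reports, built around the comparative safety question: are **drug resistance**
and **drug ineffectiveness** reported more often for one colorectal-cancer
drug than another? The package reproduces a complete EudraVigilance-style
workflow for bevacizumab (BEV) and panitumumab (PAN) — two monoclonal
antibodies used first-line in metastatic colorectal cancer — and generalizes
it to any drug/comparator panel.

## Who it is for

Pharmacovigilance analysts and pharmacoepidemiologists working with
spontaneous-report line listings (EudraVigilance, FAERS, VigiBase exports) who
need reproducible, scriptable signal screening instead of ad-hoc web
calculators.

## The statistic

Reports are Individual Case Safety Reports (ICSRs); each carries one or more
ADRs coded as MedDRA preferred terms (PTs). A fixed dictionary maps 13 PTs to
two conditions: *resistance* (2 PTs, e.g. 10059866 "Drug resistance") and
*ineffectiveness* (11 PTs, e.g. 10013709 "Drug ineffective"). For a target
drug vs a comparator and one condition, the 2×2 table is

|                      | evaluated ADRs | other ADRs |
|----------------------|----------------|------------|
| target drug          | a              | b          |
| comparator           | c              | d          |

and the screening statistic is the reporting odds ratio with its Wald
interval on the log scale (Woolf standard error):

    ROR = (a·d) / (b·c)
    SE{ln ROR} = √(1/a + 1/b + 1/c + 1/d)
    95% CI = exp(ln ROR ± 1.96 · SE)

A comparison is flagged as a **disproportionality signal** (EMA screening
practice) when the evaluated reaction has at least 5 reports (`a ≥ 5`) and
the lower CI bound is strictly greater than 1. Tables with a zero cell are
reported as undefined rather than continuity-corrected.

## Worked example

The public EV portal exposes only aggregated counts, so the package ships an
exact-count synthetic generator whose BEV/PAN fixture reproduces every
published aggregate (59,693 / 7,178 ICSRs; 107,085 / 15,051 ADRs; 91 / 18
resistance and 1,414 / 328 ineffectiveness ADRs, with their PT and outcome
splits):

```r
library(rorsignal)

dataset <- generate_icsr(bevpan_fixture())
aggs    <- aggregate_icsr(dataset)

adrs_per_icsr(aggs, "bevacizumab")$value   # 1.79  ADRs per case report
adrs_per_icsr(aggs, "panitumumab")$value   # 2.10
condition_proportion(aggs, "bevacizumab")$value  # 1.41 % of ADRs are
condition_proportion(aggs, "panitumumab")$value  # 2.30 % resistance/ineff.

tab <- build_table(aggs, "panitumumab", "bevacizumab", "ineffectiveness")
compute_ror(tab)[, c("a", "b", "c", "d", "ror", "ci_low", "ci_high", "signal")]
#>       a     b     c      d   ror ci_low ci_high signal
#>     328 14723  1414 105671  1.66   1.47    1.88   TRUE
```

Read: ineffectiveness is reported for panitumumab with 1.66 times the odds of
bevacizumab (95% CI 1.47–1.88); with 328 reports and a lower bound above 1,
this meets the screening rule. The same comparison for resistance gives ROR
1.41 (0.85–2.33) — the interval spans 1, so no signal.

## The analysis workflow

Numbered drivers under `analysis/` run the study end-to-end and write their
tables under `results/`:

| script | does | writes |
|---|---|---|
| `01_simulate.R` | generate the pinned BEV/PAN line listing | `line_listing.csv`, `bevpan_spec.json` |
| `02_aggregate.R` | collapse to per-drug condition × outcome counts | `aggregates.csv` |
| `03_descriptives.R` | ADRs/ICSR, condition shares, PT and outcome tables | `reporting.csv`, `outcome_breakdowns.csv`, … |
| `04_disproportionality.R` | PAN-vs-BEV RORs + a synthetic 12-comparator panel | `signal_pan_vs_bev.csv`, `signal_panel_synthetic.csv` |

`run_pipeline(run_config(...))` runs the same stages as one seeded,
byte-reproducible call with a JSON run manifest; stages also compose on disk
through the CSV interfaces.

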