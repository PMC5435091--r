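# copdemr

Rule-based case finding for physician-diagnosed chronic obstructive
pulmonary disease (COPD) in primary-care electronic medical records (EMRs),
together with the full validation harness used to judge such algorithms
against a chart-abstraction reference standard.

The package is aimed at EMR phenotyping and health-services researchers who
need to (a) run transparent, auditable COPD case definitions over chart
data, (b) quantify their diagnostic accuracy with the field's standard
statistics, and (c) prototype and test all of that without access to real
(access-restricted) clinical records, via a calibrated synthetic-cohort
generator.

## What it computes

A phenotyping algorithm is a monotone boolean expression over four kinds of
atomic chart criteria:

- **CPP mention** — a COPD term (acronym, full spelling, synonym,
  misspelling) appears in the cumulative patient profile (problem list /
  past medical history), *not* preceded in the same entry by an uncertainty
  marker ("?", "possible"). Trailing qualifiers (e.g. "Asthma/COPD") do not
  exclude.
- **Billing count** — at least *m* diagnostic claims with codes 491
  (chronic bronchitis), 492 (emphysema) or 496 (other COPD), either ever or
  within a rolling window of *w* consecutive days (both endpoints
  inclusive). Subcoded claims ("491.2") match on their 3-digit stem.
- **Drug class** — a prescription for a COPD-specific anticholinergic:
  tiotropium, ipratropium, or combined ipratropium/salbutamol, matched by
  generic and trade names, longest variant first; scope "ever" or
  "currently active".
- **Smoking history** — the most recent structured smoking record is
  "current" or "ex".

Against charts labeled by manual abstraction (reference positive =
"definite COPD"), each algorithm yields a confusion matrix (TP, FP, FN, TN)
and:

- sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
  NPV = TN/(TN+FN), each with an exact Clopper–Pearson 95% CI from beta
  quantiles;
- LR+ = sens/(1−spec) and LR− = (1−sens)/spec with Simel log-method CIs;
- diagnostic odds ratio DOR = (TP·TN)/(FP·FN) with a log-Wald (Woolf) CI,
  and the Haldane–Anscombe 0.5 correction (flagged) when a cell is zero;
- predicted prevalence 100·(TP+FP)/n, and Cohen's kappa for
  abstractor agreement.

A discordance module categorizes every false negative
(`uncertainty_phrasing`, `insufficient_billing`, `incomplete_cpp`, `other`)
and false positive (`billing_only`, `ambiguous_or_stale_cpp`, `other`) by
the documentation mechanism that caused it.

The shipped catalog (`catalog_algorithms()`) freezes 12 algorithms, from
single-component rules (CPP only, billing thresholds, individual drugs,
smoking status) to the combination rule optimizing PPV and sensitivity:
*CPP mention OR tiotropium OR (ipratropium AND ≥1 billing code) OR ≥3
billing codes within 1 year*.

## Worked example

```r
library(copdemr)

params <- default_params()      # calibrated study-cohort structure
params$n <- 1000L
params$seed <- 42L
cohort <- generate_cohort(params)

lex <- default_lexicon()
report <- build_report(cohort,
                       catalog_algorithms()[c("cpp_only", "billing_ge2_1yr",
                                              "combo_final")], lex)
round_report(report)[, c("algorithm", "tp", "fp", "fn", "tn",
                         "sens", "spec", "ppv", "npv", "dor")]
#>         algorithm tp fp fn  tn sens spec  ppv  npv     dor
#> 1        cpp_only 36  1 29 934 55.4 99.9 97.3 97.0  1159.4
#> 2 billing_ge2_1yr 18  3 47 932 27.7 99.7 85.7 95.2   119.0
#> 3     combo_final 61  1  4 934 93.8 99.9 98.4 99.6 14243.5
```

Reading the rows: on this simulated 1000-patient cohort (65 reference COPD
cases) the CPP entry alone finds 55% of cases but almost never
false-alarms; two billing codes within a year are highly specific but miss
nearly three quarters of cases; the combination rule recovers most cases
while keeping a positive predictive value of 98%. The same trade-off
pattern — combination rules trading a little PPV for much higher
sensitivity — is what the validation statistics are designed to expose.

Why were cases still missed?

```r
res <- classify_cohort(cohort, catalog_algorithms()$combo_final, lex)
discordance_summary(discordance_records(cohort, res, lex))
#>       error_type             category n pct
#> 2 false_negative insufficient_billing 3  75
#> 1 false_negative       incomplete_cpp 1  25
#> 3 false_positive                other 1 100
```

Single estimates are available directly:

```r
proportion_with_ci(280, 364)
#> 76.92 (95% CI 72.25-81.15) [clopper_pearson]
```

## Command line

```sh
inst/cli/copdemr simulate --n 5889 --seed 7 --out cohort.jsonl
inst/cli/copdemr evaluate --charts cohort.jsonl --out report.csv
inst/cli/copdemr discordance --charts cohort.jsonl --algorithm combo_final --out disc.csv
```

Charts travel as JSON Lines (one patient per line; see `?read_charts`),
reports as RFC-4180 CSV plus a JSON mirror. Exit codes: 0 ok, 2 usage,
3 data validation, 4 internal.

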