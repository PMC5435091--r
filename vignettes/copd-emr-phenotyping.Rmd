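---
title: "Methods: COPD case-finding in primary-care EMRs and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COPD case-finding in primary-care EMRs and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copdemr)
```

## The problem

Primary-care EMRs hold several partly redundant traces of a COPD diagnosis:
free-text problem-list entries, diagnostic billing claims, prescriptions for
COPD-specific bronchodilators, and smoking history. None is complete on its
own — problem lists go stale, billing reflects encounters rather than
diagnoses, and prescriptions may originate outside the practice. A
*phenotyping algorithm* is a transparent boolean rule over these traces that
labels each patient as a COPD case or non-case; its worth is measured
against a reference standard produced by manual chart abstraction, where
only charts judged *definite COPD* count as reference positives (charts
judged "possible", "ruled out" or with no mention are all reference
negatives — a deliberate, conservative choice that penalizes algorithms for
promoting merely suspected disease).

`copdemr` implements the atomic criteria, an engine for monotone AND/OR
combinations of them, the accuracy statistics with their interval methods, a
discordance taxonomy for the errors, and a synthetic-cohort generator so the
whole pipeline can be exercised without access to real charts.

## Atomic criteria and their assumptions

**CPP mention.** Matching is boundary-aware substring search after
lowercasing and whitespace collapsing — no stemming, no general clinical
NLP. This mirrors how such rules are actually deployed on problem-list
text, and it makes every decision auditable: a match either is or is not in
the entry. The exclusion rule is deliberately narrow: a match is discarded
only when an uncertainty marker (defaults: `?` and `possible`) occurs in
the *same entry before* the term. The lookback defaults to the whole entry
(`lookback = Inf`, in tokens) because profile entries are short clause-like
lines. Two asymmetries are intentional and consequential:

- markers *after* the term never exclude (`"COPD?"` still counts), and
- compound phrasings such as `"Asthma/COPD"` are *not* excluded, although
  they often encode an unresolved differential. They are positive
  documentation under this rule — a known source of false positives that
  the discordance module surfaces as `ambiguous_or_stale_cpp`.

A wider marker set (`query`, `r/o`, `rule out`) is available through
`uncertainty_markers_extended()` but is off by default: those phrasings are
rarer in profile lines and widening the net trades false positives for
false negatives in a way users should opt into, not inherit. The term list
ships with synonymous diagnoses (emphysema, chronic bronchitis) and common
misspellings; `default_lexicon(strict = TRUE)` narrows to COPD proper,
because whether synonym free text should count as COPD documentation is a
judgment call that affects CPP-based rules. Both lists are fully
overridable from a YAML/JSON config (`read_lexicon()`).

**Billing counts.** "Within 1 year" means some window of 365 *consecutive
days*, endpoints inclusive, contains at least `min_count` qualifying
claims. We read "in the span of a year" as a duration, not a calendar
artifact: two claims in December and January are a year's span apart in no
clinically meaningful sense. The rolling check anchors candidate windows at
each qualifying event date, which is sufficient because any qualifying
window can be slid left until it starts on its earliest event; the test
suite nevertheless verifies it against a brute force over *every* candidate
start day. A `calendar_year = TRUE` switch restores calendar grouping for
sensitivity analysis. Same-day duplicate claims each count once per record,
since claim-level data give no principled de-duplication rule;
`dedup_same_day = TRUE` collapses them. Codes compare on their 3-character
stem (`"491.2"` → `"491"`) so subcoded claims match the 3-digit targets;
the original string stays on the chart for audit.

**Drug classes.** Only the three COPD-specific anticholinergics are
classifiable (tiotropium; ipratropium; combined ipratropium/salbutamol).
Short-acting beta-agonists are excluded by construction — they are
prescribed for asthma and acute bronchitis too, and admitting them is a
documented route to misclassification. Variant matching is
longest-variant-first so combination products beat their components
(`"ipratropium/salbutamol"` never classifies as plain ipratropium). Scope
`"ever"` (any prescription at any time) is the catalog default; an
`"active"`-only scope exists because the two framings answer different
questions (lifetime exposure vs current management).

**Smoking.** The most-recent-dated structured record governs, taken
literally: a `non` record after an earlier `current` yields *not positive*,
even though such a patient is arguably an ex-smoker. We do not reinterpret
records, because the structured field is what an automated rule sees; date
ties go to the record appearing later in chart order. Free-text smoking
narratives are not parsed.

## The algorithm engine and catalog

Expressions are AND/OR trees over atomic leaves, with no NOT nodes: every
cataloged rule is monotone, so adding positive evidence to a chart can only
keep or gain a positive call (a property the suite tests directly). All
leaves are evaluated without short-circuiting so that `fired_criteria`
records the complete evidence pattern; the discordance taxonomy depends on
this audit trail. The 12-rule catalog spans the single components, the
PPV-optimizing combination (CPP OR tiotropium OR ipratropium-with-a-billing-
code OR ≥3 codes/365 d), the higher-sensitivity alternative (CPP OR any
COPD drug OR ≥2 codes/365 d), and both combinations with smoking history
added. In the ipratropium clause the paired billing code may occur anywhere
in the chart — no time proximity to the prescription is required, since a
proximity rule would need a window no published evidence pins down.

## Statistical methods

The four proportions use exact Clopper–Pearson intervals in the
beta-quantile form: lower `qbeta(α/2, k, n−k+1)`, upper
`qbeta(1−α/2, k+1, n−k)`, with the lower bound 0 at `k = 0` and the upper
bound 100 at `k = n`. The ratio metrics use log-scale normal intervals:
Simel's method for LR± (e.g. `se(log LR+) = sqrt((1−sens)/TP + spec/FP)`)
and Woolf's log-Wald for the DOR (`sqrt(1/TP+1/FP+1/FN+1/TN)`), with
`z = qnorm(0.975)`. When a required cell is zero the Haldane–Anscombe
correction adds 0.5 to all four cells for the ratio metrics only — never
for the proportions, which remain exact — and the estimates carry a
`corrected` flag.

Cohen's kappa is the standard chance-corrected agreement; when both raters
use a single identical label throughout, expected agreement is 1 and kappa
is returned as `NA` with an `undefined` attribute rather than a misleading
number.

Display rounding is half-up (not R's round-half-even): proportions, LR+
and DOR to 1 decimal, LR− to 2 decimals. Internal values keep full
precision; only `round_report()`/`write_validation_report()` apply display
rounding, and a written report re-reads bit-identically at that rounding.

The validation-table reproduction tests deliberately omit two published
rows whose printed counts are internally inconsistent (their cells cannot
be reconciled with their own printed metrics), and carry a one-unit-in-the-
last-digit allowance on two isolated cells where a printed value differs
from what its own counts imply; no corrected values are guessed.

## The synthetic-cohort generator

`default_params()` encodes the validation study's structure: n = 5889,
reference prevalence 6.2%, and per-label conditional rates for CPP
documentation, billing intensity, the two drug exposures, smoking
recording and status mix, pulmonary-function-test presence, age
(normal, truncated at 35) and sex. Charts are *rendered*, not abstracted:
CPP text is drawn from lexicon-compatible templates including planted
`"?COPD"`/`"possible COPD"` phrasings (at 5/205 of case mentions, matching
the handful of uncertainty-phrasing false negatives the discordance
analysis reports) and `"Asthma/COPD"` compounds among non-case mentions;
billing events are *placed to realize the drawn tier* (a ≥3-in-a-year
patient really gets ≥3 claims inside one 365-day span, a tier-1 patient
never gets two claims within a year); prescriptions use generic and trade
name variants; the most recent smoking record carries the drawn status.

Two modelling choices deserve emphasis:

- **The ≥3-codes-in-a-year rate is an assumption.** No marginal for it is
  published; we set 75/364 for cases (between the ≥2/year rate and the
  final combination's residual) and 8/5525 for non-cases (the count of
  billing-only false positives). It is a calibration default, not a fact.
- **Features are independent given the label** (`dependence = 0`), because
  only marginal rates are published. Joint behavior of combination
  algorithms on synthetic cohorts is therefore *not* expected to reproduce
  the published combination rows — under independence the final
  combination's synthetic sensitivity runs several points above the
  published 76.9%, precisely because real documentation channels are
  positively correlated (patients with sparse charts are sparse
  everywhere). The `dependence` knob (one latent per-patient
  "documentation completeness" score shifting all documentation
  probabilities on the logit scale, scale factor 1.5) lets users induce
  such correlation; it is a modelling device, not an estimate.

Consequently, passing pipeline tests show that the machinery — matching,
windows, tree evaluation, tallying, intervals — is correct on data with
the study's marginal structure; they do not show that real charts behave
like the generator. Free-text messiness (abbreviations outside the shipped
lists, OCR noise, scanned documents), longitudinal disease progression and
inter-practice variation are all outside what the generator emulates.

Generation is deterministic given `seed` (RNG kind pinned, global RNG state
restored afterwards), and every generated chart satisfies the data-model
invariants, is ≥35 years old at the fixed index date (2010-12-31), and
round-trips unchanged through the JSON Lines interchange format.

## Discordance taxonomy

False negatives are categorized in priority order: excluded-by-phrasing
first (the distinguishing first cut — the chart *does* document COPD, the
rule discarded it), then sub-threshold billing when any COPD claim exists,
then `incomplete_cpp` when the profile is silent and billing gives nothing
to count, else `other`. False positives: `billing_only` when only billing
leaves fired; `ambiguous_or_stale_cpp` when the firing CPP entry carries
compound phrasing or an extended (non-default) uncertainty marker; else
`other`. Every discordant chart receives exactly one category; summaries
report raw per-error-type percentages at one decimal, with no denominator
adjustments.

## Problem sizes and numerical tolerances in the test suite

The suite exercises one full-size cohort (n = 5889, one fixed seed) for
marginal-recovery and pipeline-closure checks at three binomial standard
errors, and smaller cohorts (100–2000 charts) elsewhere; the rolling-window
oracle comparison runs 1000 random event sets (≤7 events, windows of
14–730 days), sizes chosen to probe the logic densely while keeping the
default run fast. Statistical equalities are asserted at 1e-9 to 1e-12;
agreement with published display values is asserted exactly at their
printed rounding (with the two print-discrepancy allowances noted above).

## Known limitations

- String search only: no negation scope beyond the marker rule, no
  spelling correction beyond the shipped variant lists.
- PFT presence is a boolean; reports are not parsed.
- The reference-standard abstraction process itself is out of scope; only
  its label enum is modelled, so kappa has no published anchor to compare
  against.
- Synthetic cohorts are a test surface, not evidence about any real
  population.
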