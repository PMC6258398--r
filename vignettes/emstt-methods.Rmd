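---
title: "Methods: trigger screening, reliability, and U-chart surveillance in emstt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trigger screening, reliability, and U-chart surveillance in emstt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstt)
```

`emstt` operationalises emergency-medical-services trigger-tool (EMSTT)
methodology: biweekly samples of prehospital patient care records (PCRs)
are screened against eight deterministic trigger rules; trigger-positive
records are reviewed by two independent raters for adverse events (AEs) and
harm, classified under two harm taxonomies; and the resulting counts are
tracked as rates per 10,000 patient encounters on U-charts with
Nelson-rule special-cause detection. This vignette records the modelling
conventions the package commits to, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices that make the outputs reproducible.

## The record model

A PCR is one EMS encounter: a time-ordered series of vital-sign
observations (SpO2 %, systolic blood pressure mmHg, temperature °C, pain
0–10, respiratory rate, heart rate, AVPU consciousness), interventions,
medication administrations, a disposition, and exclusion flags
(care-pathway cases, high-risk procedures/medications, infrequent
procedures, inter-facility transports — the high-risk/low-frequency cohorts
that belong in 100% audit frameworks rather than sampled review).
Timestamps are ISO-8601 with explicit offsets and all comparisons happen in
absolute time, so the 24-hour return-call window is unambiguous. JSON is
the canonical lossless format; the CSV dialect spreads a cohort over four
flat files joined on `record_id` because CSV cannot nest. Validation is
total — `validate_record()` reports violations rather than throwing — and
readers validate on ingest.

## Trigger semantics

Every threshold comparison is strict; boundary values never fire. Where the
item wording admits more than one reading, the package fixes one and makes
it configurable:

* **C2 direction.** "Change > 20%" is read as *absolute* relative change
  from the first measurement, rise or fall — the conservative screen, since
  both hypotension and an abrupt rise are reviewable. Set
  `c2_direction = "drop"` to restrict to falls.
* **"Without subsequent reduction" (C3/C4).** The qualifying value is the
  series maximum above the threshold (first occurrence on ties); the item
  fires unless some strictly later reading is strictly lower. A single
  supra-threshold reading with no later reading fires: the absence of a
  documented reduction is the screenable fact. Whether the reduction must
  re-cross the threshold is left out of the rule deliberately — any
  decrease counts.
* **C1 temporal scope.** The relieving intervention (supplemental oxygen
  for the < 94% clause, assisted ventilation for the < 85% clause) must be
  documented at or after the *first* qualifying low reading; oxygen given
  earlier and discontinued is out of model. This is the simplest defensible
  reading of "without".
* **EWS (C5).** No specific early-warning-score instrument is mandated by
  the item, so the score table is configuration, not a constant. The
  shipped default (`default_ews_table()`) is an aggregate-weighted table of
  the familiar national-early-warning-score shape over respiratory rate,
  SpO2, systolic pressure, heart rate, temperature and consciousness, with
  half-open bands `[lo, hi)`. Vitals absent from an observation contribute
  0 points, so a sparser later observation cannot inflate the increase; a
  value outside every band of its parameter is a configuration error, not a
  silent 0. C5 compares each later observation with the first.
* **M1.** Order-free: an opioid (configurable name list, no ontology
  mapping) and naloxone anywhere in the same record. Requiring
  opioid-before-antagonist ordering would miss records whose administration
  times are incompletely documented.
* **P1.** "Inappropriate" is undirected, so the default `mismatch` mode
  fires both on immobilisation applied without documented indication and on
  indicated immobilisation not performed; `applied_without_indication`
  restricts to the first. An immobilisation entry with *no* documented
  indication is indeterminate: the item returns no hit and logs a
  documentation warning rather than guessing.
* **R1.** The hit attaches to the *return* encounter (the reviewable
  event), with a half-open window: 0 < return start − refusal end ≤ 24 h.
* Items are binary per record — multiple qualifying observations produce
  one hit per item — so per-item counts are case counts.

`screen()` evaluates all eight items in a fixed order (C1..C5, M1, P1, R1)
and is a pure function of the records and configuration; tests verify it
against an independently coded brute-force re-evaluation.

## Review, consensus and reliability

Two reviewers decide, per case: each trigger item, AE presence, harm
presence, a modified NCC MERP category, and (in the severity era) a
seven-code severity rating. Consensus is field-wise: agreement stands;
disagreement is decided by the third reviewer's adjudication, and a
disagreement with no adjudication is an unresolved-case error.

Percent agreement is computed by rounding half-up to **one** decimal and
displayed with two (97.4647 → 97.50). This single rounding routine
(`round_half_up()`) is shared by every percentage the package prints —
agreement rows, trigger shares, cross-tab percentages — so all tables
follow one convention.

Cohen's kappa is computed over the full paired decision vector, including
trigger-negative cases, with an absent classification treated as its own
category. When expected agreement is 1 — both raters constant, as happens
for items never observed — kappa is undefined and the package returns a
typed sentinel (`kappa_undefined()`), never a silent zero or a propagating
`NaN`: a zero would misread "no variation to agree about" as "agreement at
chance".

## Harm classification

The NCC MERP index is used with category C modified for EMS (C_EMS: the
error reached the patient and harm was possible but not conclusively
determinable over the short duration of prehospital care). For reporting,
C_EMS and E–I count as harm-positive; A, B and D do not. Category D is
retained in the model although rarely observed, for generality. AE and harm
flags are reviewer annotations, *not* derived from the MERP category —
the two need not be mutually reconstructible, and only harm-positivity is a
derived quantity. The severity rating index runs only from its introduction
sample onward (`severity_era_filter()`, default sample 10); a severity code
on an earlier sample is a validation error. Cross-tabs take their
percentage denominator explicitly because the two systems cover different
case sets (full sample vs. severity-era subset); totals rows are recomputed
from the item rows, never copied in.

## Outcome measures and control charts

Counts are the trigger/AE/harm events found in each period's reviewed
sample; encounters are the period's *total* service-level patient
encounters, supplied per period. The modified-AE measure adds AE and harm
counts. With `n_i = encounters_i / 10,000`:

* `u_i = count_i / n_i`, `u_bar = Σcount / Σn`,
* `sigma_i = sqrt(u_bar / n_i)`, limits `u_bar ± 3·sigma_i`, LCL floored at
  0.

Limits vary per point with the denominator — the standard treatment for
U-charts with unequal subgroup sizes — and the Nelson rules use each
point's own `sigma_i` for its 1/2/3-sigma zones. A degenerate all-zero
chart (`u_bar = 0`, `sigma_i = 0`) standardises every point to 0 so no rule
fires spuriously. Rule scans report the final point of every maximal
violating window, deduplicated per rule (a nine-point run extended to ten
is one signal, not two). Chart rendering (`plot.u_chart()`) is a
convenience; the canonical output is tabular.

Whether sampled counts should be extrapolated to the full encounter base is
a design choice the package leaves to the analyst: rates use raw sample
counts over encounter denominators by default, and `run_pipeline()`'s
`screen_scope = "cohort"` provides the whole-cohort alternative used for
prevalence recovery.

## The synthetic cohort generator

The generator emulates the *study conditions*, not clinical case-mix: 36
half-month periods; Poisson encounter denominators with mean 9,750 per
period (a service answering 600–700 calls a day); per-item trigger
prevalences pooling to 8.20 per 10,000 encounters split in the observed
proportions (C2 4.56, C5 2.62, C1 0.42, C4 0.30, P1 0.17, C3 0.13, M1 and
R1 0); AE probability 0.30 per trigger and harm probability 0.14 per AE
(pooling to 2.48 and 0.34 per 10,000); classification label distributions
matching the observed category mix; and a reviewer error rate of 0.05,
under which two independent reviewers agree on `0.05² + 0.95² = 0.905` of
binary decisions — the order of the observed agreement range.

Implementation choices worth knowing:

* **Sparse materialisation.** Each encounter carries each trigger
  independently with probability `prevalence/10,000`; equivalently, planted
  counts per period are Binomial(encounters, p). Only planted records plus
  a configurable number of trigger-negative background records are
  materialised as full PCRs; the remaining encounters exist only in the
  denominators. This keeps million-encounter cohorts in memory while
  leaving every rate estimator's distribution unchanged.
* **Plants are engine-verified.** `plant_trigger()` edits a record so that
  the engine fires *exactly* the requested item, and asserts this by
  re-screening (engine-as-oracle). Plant values are chosen to avoid
  cross-firing — e.g. a planted C2 is a 25% pressure *rise* between
  0-scoring EWS bands, and a planted C1 record carries a single observation
  so the EWS-increase item cannot co-fire. R1 is planted at cohort level as
  a refusal record plus a return 1–23 h later for the same patient.
* **Background records are provably negative**: constant in-encounter
  vitals drawn from configurable baselines, truncated to non-scoring bands
  (SpO2 ≥ 95, SBP 115–175, temp ≤ 37.8 °C, pain ≤ 4).
* **Reviewer error stands in for record illegibility.** Real disagreement
  is driven largely by documentation quality, which a structured generator
  cannot represent; an independent per-decision flip probability is the
  tractable surrogate. Categorical labels are replaced by a uniformly
  chosen different category. The flips are deliberately unconstrained, so
  two same-way errors can yield a trigger-positive consensus with no
  classification; the pipeline codes such cases to the minimal categories
  (MERP A, severity 7).
* **One master seed, split streams.** Cohort construction, planting/labels,
  review simulation and sampling each draw from an independently derived
  stream, so changing the reviewer error rate cannot perturb the cohort.

What passing tests on these cohorts shows: the screening rules, sampling
design, reliability statistics, classification tables and SPC machinery are
correct and internally consistent. What they do not show: performance on
real PCRs, where vitals co-vary, documentation is incomplete or illegible,
trigger items correlate with each other and with AEs, and reviewer error is
neither independent nor symmetric.

## Sampling design

Per period, 30 records are drawn uniformly without replacement from the
eligible pool by a seeded PRNG permutation (standing in for a physical
random number table; the seed is recorded in the batch for audit). The
review set is the first 20; any member found excludable after the draw is
replaced in order by the spares in positions 21–30, and a shortfall after
exhausting the spares is recorded as a warning rather than an error.
Reviewed-case totals are therefore emergent (20 × periods minus
shortfalls), not assumed.

## Validation scale and reproducibility

The test suite validates the engine against independently coded

* brute-force per-item screening on random cohorts,
* a direct-formula kappa oracle on 1,000 random rater pairings,
* a sliding-window Nelson evaluator on 10,000 random charts of up to 40
  points,

and recovers configured prevalences within three binomial standard errors
on a cohort of one million encounters. The acceptance script repeats the
rate recovery at roughly ten million encounters, which keeps the
Monte-Carlo standard error of the rare harm rate (≈0.35 per 10,000) below
0.02, and reruns the reporting routines on study-shaped count fixtures; its
rate-recovery runs use an error-free reviewer model because they measure
the estimation machinery, not reviewer noise. All randomness flows from the
single seed supplied on the command line.

A note on denominators: the severity-era cross-tab in the classic EMSTT
reporting layout uses the count of severity-era cases as its percentage
denominator, which can differ by one from the severity-era *decision* count
if a case is dropped between systems; `classification_crosstab()` takes the
denominator explicitly so either convention can be reproduced exactly.

## Known limitations

* Free-text/narrative triggers are out of scope; only structured fields are
  screened.
* AE and harm are generated and reviewed as labels, not simulated
  physiology — the tool's AE determination is reviewer judgment, and the
  package does not attempt automated MERP/severity assignment.
* Tests of association between trigger items and AE/harm rates are out of
  scope.
* The U-chart assumes Poisson-distributed counts per exposure unit;
  over-dispersed processes will signal spuriously and need wider-limit
  variants the package does not provide.
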