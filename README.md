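# emstt — an EMS trigger tool pipeline for adverse-event surveillance

Adverse events (AEs) — injuries caused by medical management rather than the
patient's underlying condition — are poorly characterised in prehospital
emergency care. Trigger-tool methodology replaces exhaustive chart audit
with targeted review: small consecutive samples of patient care records
(PCRs) are screened for *triggers* (screenable clues such as abnormal
vital-sign patterns or medication pairings), and only trigger-positive
records receive full review for AEs and harm. `emstt` implements the
emergency-medical-services variant of this methodology as a tested,
reusable R pipeline for EMS quality-and-safety teams and patient-safety
researchers.

## What the package computes

**Trigger screening.** Eight deterministic rules evaluated per record, with
strict thresholds (a value exactly at a threshold never fires):

| Item | Rule |
|------|------|
| C1 | SpO2 < 94% without supplemental oxygen, or < 85% without assisted ventilation |
| C2 | Change in systolic blood pressure > 20% from the first measurement |
| C3 | Pain score > 4/10 without subsequent reduction |
| C4 | Temperature > 38 °C without subsequent reduction |
| C5 | Increase in early warning score (EWS) > 1 point |
| M1 | Opioid analgesic and naloxone administered to the same patient |
| P1 | Inappropriate spinal immobilisation |
| R1 | Return to the same patient within 24 h of a refusal of transport |

**Review and reliability.** Dual independent review with third-reviewer
adjudication (`consensus()`), percent agreement and Cohen's kappa
(`irr_table()`), with kappa's undefined case (both raters constant, expected
agreement p_e = 1) surfaced as a typed sentinel.

**Harm classification.** The NCC MERP index with category C modified for
EMS (C_EMS), a seven-code AE severity rating index, the harm-positivity
convention (C_EMS and E–I count as harm), and item-by-category cross-tabs.

**Outcome measures and SPC.** Triggers, AEs, harm and modified AEs
(AE + harm) per 10,000 patient encounters, pooled and as U-charts with
per-period variable limits

    u_i = count_i / n_i,  u_bar = Σcount / Σn,  n_i = encounters_i / 10,000
    UCL_i/LCL_i = u_bar ± 3·sqrt(u_bar / n_i)   (LCL floored at 0)

and all eight Nelson rules for special-cause variation.

**Synthetic cohorts.** Because operational PCR streams are not publicly
available, `generate_cohort()` builds seeded cohorts with known ground
truth: trigger positives are planted by running the rules in reverse and
verified against the engine itself, and paired reviewer annotations are
simulated with a configurable error rate. Every downstream stage is
testable end to end with no external data.

## Worked example

```r
library(emstt)
cfg <- generator_config(seed = 7, n_periods = 12,
                        encounters_per_period_mean = 5000,
                        background_per_period = 30)
report <- run_pipeline(cfg)
report
```

```
Emergency medical services trigger tool summary
  records: 406 materialised, 14 excluded, 240 reviewed; 59,882 encounters
  triggers found: 24
    C2: 12 (50.0%)
    C4: 4 (16.7%)
    C5: 7 (29.2%)
    P1: 1 (4.2%)
  pooled rates per 10,000 encounters: triggers 4.01, AE 1.17, harm 0.00, modified AE 1.17
  Nelson signals across the four charts: 2
```

Twelve half-month periods were simulated (about 60,000 encounters); each
period had 30 records drawn and the first 20 reviewed (240 reviewed cases).
Screening the reviewed samples found 24 triggers, dominated by the blood
pressure item (C2, 50.0%), and the pooled rates are the sample counts over
the service-level encounter denominators. Note that sample-scope rates
undercount the configured cohort prevalence (8.2 triggers per 10,000 by
default) because only the reviewed fraction of each period's encounters can
contribute counts; use `run_pipeline(cfg, screen_scope = "cohort")` for
prevalence-recovery analyses.

The U-chart machinery is available directly:

```r
chart <- build_u_chart(data.frame(period_id = c("a", "b", "c"),
                                  count = c(2, 4, 3),
                                  encounters = rep(10000, 3)))
chart$data
#   period_id count encounters u    sigma      ucl lcl
# 1         a     2      10000 2 1.732051 8.196152   0
# 2         b     4      10000 4 1.732051 8.196152   0
# 3         c     3      10000 3 1.732051 8.196152   0
nelson_violations(chart)
plot(chart)
```

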