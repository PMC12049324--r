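---
title: "Methods: the UACR testing cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the UACR testing cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uacrcea)
```

This vignette documents the model implemented by `uacrcea`: its structure
and assumptions, the parameters that matter and their defaults, the
conventions chosen where the source material leaves the design open, what
the synthetic data generators do and do not emulate, and the model's known
limitations.

## Model structure

The analysis compares three strategies for detecting kidney damage in a
non-diabetic screening cohort — regular UACR testing, regular UPCR testing,
and no urine testing — all alongside regular eGFR testing, over a lifetime
horizon (age 60 to 100, annual cycles, 2%/yr discounting, 2023 JPY,
healthcare-system perspective).

**Classification (decision tree).** Because every arm measures eGFR, the
true G stage is always known; the arms differ only in the *diagnosed*
albuminuria class. UACR is treated as the diagnostic gold standard. The
no-testing arm diagnoses everyone A1 (kidney damage is simply never seen).
The UPCR arm is derived from re-test data in which the same cohort was
classified by both tests. Only marginal class counts are available, so the
joint distribution is reconstructed under *nested detection*: a patient is
never classified more severely by UPCR than by UACR, and a missed case
drops exactly one class. This is the only reconstruction consistent with
the re-test table's own footnote, which moves UPCR-severe/UACR-A2 patients
down a class on the same reasoning. Per-class sensitivity is then a count
ratio (unstratified: 75/198 for A2, 13/13 for A3), and `detection_profile()`
exposes the resulting conditional matrix. A full joint table, if available,
can be supplied by replacing the reclassification table.

**Treatment.** Diagnosis drives eligibility: ACEi/ARBs for G1–G4 patients
diagnosed A2–A3 (RRR 0.21 on progression, 0.1 on mortality; ¥4015/yr), and
in the emerging-treatment scenario additionally SGLT2 inhibitors for
G3a–G4/A2 or G1–G4/A3 (combined progression RRR 0.35; +¥96,725/yr).
Eligibility keys on the *diagnosed* class but the *true* G stage — a
misclassified patient is treated according to what the clinician saw.

**Markov cohort.** Six mutually exclusive states follow the KDIGO prognosis
heatmap: low, moderate, high, very high CKD risk, ESKD and death. The 18
(G, A) heatmap cells map onto these states via the standard 2012 bands
(`kdigo_risk_map()`). The starting occupancy is the outer product of the
cohort's eGFR and albuminuria marginals (see "Design choices"). Transitions
are constructed in two phases, following the source model's description:

1. *First transition*: each cell uses the state-level base transition row
   with its worsening-direction entries multiplied by a cell-specific
   adjustment factor (derived from meta-analysis risk gradients), the
   member's treatment RRR, and cell-specific mortality.
2. *Subsequent transitions*: state-average rows, identical across arms for
   untreated members. While a member remains in their initial health state
   the treatment flag stays active (default `treatment_scope:
   initial_state`); on leaving it they join the common state-level pool.
   This implements the source statement that testing-strategy differences
   affect treatment and management only up to the transition out of the
   initial state. `treatment_scope: lifetime` keeps the flag for life.

Mortality composes an age-indexed background probability `q_bg(age)` with a
CKD hazard ratio on the rate scale, `q = 1 − (1 − q_bg)^HR`, which stays a
probability for any HR (the largest cell HR is 12). State-level HRs are
occupancy-weighted means of cell HRs, weighted by the starting
distribution. Cardiovascular events are cost-generating side events only —
no state change, mortality or disutility — with annual probability derived
from a 10-year reference risk of 0.109 in the low-risk state
(`q1 = 1 − (1 − 0.109)^(1/10)` ≈ 0.0115/yr) scaled by state HRs on the rate
scale.

**Outcomes.** Occupancy at the start of each model year accrues that year's
state costs (consultations at per-visit rates, annualised test/prescription
bundles, eGFR and arm-specific urine tests, dialysis in ESKD), drug costs
for the treated mass, and one-time event costs (vascular-access surgery per
incident ESKD entry; the event-mix-weighted acute CV cost), discounted by
`1/(1+r)^t`. QALYs weight living occupancy by state utilities (0.940 low →
0.789 ESKD). Everything is scaled to a 1000-person cohort. Clinical event
counts (dialysis initiations, CV events) are reported undiscounted.

## Parameters that matter

| Parameter | Default | Units | Why it matters |
|---|---|---|---|
| `run.discount_rate` | 0.02 | /yr | Japanese HTA guideline rate; lifetime costs are back-loaded (dialysis), so the ICER is sensitive to it |
| `treatment.base.rrr_progression` | 0.21 | — | the engine of all between-arm differences |
| `treatment.base.rrr_mortality` | 0.1 | — | drives the survival component of the QALY gain |
| `cv.reference_risk_10yr` | 0.109 | 10-y risk | with the ESKD HR of 12, CV care is a third of lifetime cost |
| `costs: dialysis` | 5,456,714 | ¥/yr | dominates ESKD state cost; averted ESKD years are the main saving |
| `costs: uacr_test / upcr_test` | 1730 / 810 | ¥ | the price of information; accrued at per-state annual frequencies |
| utilities | 0.940…0.789 | — | convert survival into QALYs; bounded by 1 |

`dsa_default_params()` varies this driver set ±20% in the one-way DSA.

## Design choices where the source was open

- **Independent starting marginals.** Only the eGFR and albuminuria
  marginals of the screening cohort are published; the joint cell occupancy
  assumes independence after renormalising each marginal to 1 (the printed
  albuminuria column sums to 100.1%). A joint cross-tabulation can be
  supplied as `starting_cells` to `run_cohort()`.
- **Accrual timing.** Year *t* outcomes are valued at the start of the year
  (`1/(1+r)^t`, first year undiscounted), the usual spreadsheet cohort
  convention; this reproduces the published absolute life-year and cost
  levels, whereas end-of-cycle accrual understates them by ~6%. Flags
  `accrual: cycle_end` and `half_cycle: true` select the alternatives.
- **CV reference "incidence rate" read as a 10-year risk.** Read as an
  annual probability, the ESKD hazard ratio of 12 would imply an absurd
  >70%/yr event probability; the 10-year reading reproduces the magnitude
  of ~0.34 CV events per person-lifetime. `cv_rate_basis: annual` restores
  the literal reading.
- **Hazard-ratio composition on the rate scale** rather than `q × HR`
  (which exceeds 1 at high HRs); `hr_composition: linear` is available for
  comparison at small HRs.
- **Mortality RRR scales the whole effective hazard ratio**
  (`mortality_rrr_basis: total`); `excess` scales only the excess over 1,
  which is more conservative.
- **Worsening-only scaling.** Adjustment factors and treatment RRRs apply to
  transitions toward higher risk or ESKD; improvement transitions (e.g.
  moderate→low, 0.337) are never scaled, since the RRR is a progression
  risk reduction. Order of operations is fixed: adjustment → treatment →
  mortality thinning → residual to "remain".
- **Subarachnoid haemorrhage cost.** No unit cost is published; it is
  priced at the intracerebral-haemorrhage rate (nearest printed category;
  `sah_cost_basis: other` uses the other-CV rate instead).
- **ESKD resource use.** Beyond dialysis and four annual eGFR/urine tests,
  consultations are assumed bundled into the dialysis cost.
- **Dipstick strata as conditioned cohorts.** A stratum's gold-standard
  class mix conditions the starting albuminuria marginal, and its own
  re-test rows drive the detection profile; dipstick testing is not
  modelled as a paid first test stage.
- **Dominance labelling.** Extra cost with exactly zero QALY gain is
  labelled "DOMINATED", matching the published subgroup reporting, although
  strict dominance usually requires a QALY loss.

## Synthetic data

Two generators make the package self-contained:

- `synth_life_table()` produces a Gompertz–Makeham table,
  `q(age) = 1 − exp(−(A + B·e^{c·age}))`, with defaults A = 3×10⁻⁴,
  B = 8×10⁻⁶, c = 0.105 chosen from the hazard shape of a modern
  high-longevity population: remaining life expectancy ≈ 26.6 years at age
  60 and q(60) ≈ 0.0047. It stands in for a national life table, which is
  not redistributable here; the packaged default configuration uses it
  (shipped as `life_table_synthetic.csv`). It reproduces realistic
  *levels* of background mortality but not cohort effects, sex differences
  (the table is unisex; the screening cohort is 46.7% female) or old-age
  mortality deceleration.
- `synth_retest_counts()` draws a re-test cohort: multinomial true classes,
  gold-standard observation, and nested UPCR detection with per-class
  sensitivities. It emulates the *statistical structure* of the published
  re-test table — not the dipstick-stratum correlations of the real
  screening population — so passing recovery tests shows the
  reconstruction in `detection_profile()` is consistent with its own
  generating assumptions, not that nested detection is biologically true.

## Numerical choices

- Occupancy is conserved to 1e-9 per cycle and every constructed row sums
  to 1 exactly by residual construction; probabilities are clamped to
  `[0, 1)` only at the hazard-composition step.
- When all active treatment RRRs are zero, the regimen columns of the
  cohort bookkeeping are merged before iteration, making the occupancy
  trace *exactly* (bit-for-bit) independent of the testing arm rather than
  equal up to float rounding; drug-cost masses are carried by per-cell
  regimen shares, which are constant while a member remains in the initial
  state.
- Starting marginals are renormalised exactly to 1 before the product is
  taken; degenerate subgroup cohorts that empty a state fall back to
  configured-marginal (then unweighted) HR aggregation weights for that
  state.
- The validation suite compares the cohort engine against an independent
  200,000-individual microsimulation sharing only the per-cycle
  probability constructors (agreement within 3 Monte-Carlo standard errors
  on life years, ESKD entries and CV events), a closed-form geometric
  survival model, and a cycle-by-cycle spreadsheet-style recomputation of
  the outcome aggregation (1e-6 relative). Monte-Carlo checks use 200
  replicates of cohorts of 10,000 for sensitivity recovery; these sizes
  make the full suite run in well under a minute while keeping Monte-Carlo
  error far below the asserted tolerances.

## Limitations

- The packaged defaults reproduce the published *absolute* per-arm levels
  closely, and the calibration check in the acceptance suite compares the
  resulting ICERs with the published ones at a ±15% bar; under the default
  conventions the incremental effects are smaller than published, so that
  comparison is expected to fail until the unpublished modelling details —
  the actual national life table, the hazard-ratio aggregation weights and
  the exact treatment scope of the original spreadsheet — are supplied.
  The qualitative findings (UACR > UPCR > no testing in QALYs;
  cost-effectiveness at the ¥5M threshold; dominance at high starting risk
  and pure cost at low risk; improvement under combination therapy) are
  robust across the convention flags.
- CV events carry costs but no mortality or disutility; benefits of early
  detection outside the modelled treatment effects are excluded.
- No treatment adherence, no age- or sex-specific treatment effects, no
  probabilistic sensitivity analysis (the DSA is one-way deterministic).
- Costs are consumed as printed 2023 JPY; no inflation or currency
  conversion is performed.
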