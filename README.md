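# uacrcea

Cost-effectiveness modelling of urine albumin-to-creatinine ratio (UACR)
testing for chronic kidney disease (CKD) in a non-diabetic population, from
the perspective of the Japanese healthcare system.

Nearly half of early-stage CKD goes undiagnosed because kidney damage is
asymptomatic. Damage is graded by albuminuria class (A1 normo-, A2 micro-,
A3 macroalbuminuria), ideally with a UACR test; in Japanese non-diabetic
practice the less sensitive urine protein-creatinine ratio (UPCR) test is
reimbursed instead, and many patients receive no urine testing at all. This
package implements a decision-tree plus Markov cohort model that quantifies
what regular UACR testing buys — earlier treatment, slower progression,
prevented dialyses — and what it costs, for health economists and HTA
analysts who want to reproduce, stress or extend the analysis.

## The model

- **Decision tree.** All arms receive regular eGFR testing, so the true
  eGFR stage (G1–G5) is always observed. The diagnosed albuminuria class
  depends on the testing strategy: UACR observes the true class (gold
  standard), no-testing diagnoses everyone as A1, and UPCR is reconstructed
  from re-test classification data under nested detection — per-class
  sensitivity `s_k = n_detected(k) / n_true(k)`, with missed cases
  classified one class lower. Patients diagnosed in KDIGO categories G1–G4,
  A2–A3 start ACEi/ARBs (relative risk reduction 0.21 on progression, 0.1
  on mortality); an emerging-treatment scenario adds SGLT2 inhibitors
  (combined RRR 0.35) for G3a–G4/A2 and G1–G4/A3 diagnoses.
- **Markov cohort.** Six states from the KDIGO prognosis heatmap: low,
  moderate, high and very high CKD risk, ESKD (dialysis) and death, run in
  annual cycles from age 60 to 100. The first transition uses
  KDIGO-cell-specific adjustment factors; thereafter state-average dynamics
  apply, and (by default) treatment acts only on transitions taken from the
  initial health state. Mortality composes a background life-table
  probability with CKD hazard ratios on the rate scale,
  `q = 1 − (1 − q_bg)^HR`; cardiovascular events enter as cost-generating
  side events from a 10-year reference risk scaled by state hazard ratios.
- **Outcomes.** Discounted (2%/yr) costs in 2023 JPY, life years, QALYs,
  dialysis initiations and CV events per 1000 persons, and pairwise
  incremental cost-effectiveness ratios `ICER = Δcost / ΔQALY` judged
  against the Japanese willingness-to-pay threshold of ¥5,000,000/QALY,
  with subgroup (starting risk state, prior dipstick result), scenario and
  one-way deterministic sensitivity analyses.

The packaged default parameter set transcribes the published Japanese
inputs (re-test classification, Yamagata starting distribution, transition
probabilities and adjustment factors, mortality and CV hazard ratios,
treatment effects, fee-schedule costs, resource use, utilities). Background
mortality ships as a clearly labelled synthetic Gompertz–Makeham life table
(`life_table_synthetic.csv`, life expectancy ≈ 26.6 y at age 60); swap in a
national life table via the `life_table` slot of `model.yaml` for
calibration work.

## Worked example

```r
library(uacrcea)
cfg <- default_config()
res <- run_base_case(cfg)
res$incremental$uacr_vs_none
#> <uacr_incremental> UACR vs NONE
#>   delta cost: 10,292,085 JPY   delta QALYs: 16.12   delta LYs: 15.76
#>   delta dialysis: -0.78   delta CV events: -0.80
#>   ICER: 638,406 JPY/QALY
res$summaries$UACR
#> <uacr_summary> arm UACR, scenario base (per 1000 persons, discounted)
#>   cost: 1,624,926,974 JPY
#>   LYs: 19004.77   QALYs: 17715.89
#>   dialysis initiations: 19.61   CV events: 339.79
is_cost_effective(res$incremental$uacr_vs_none)
#> [1] TRUE
```

Per 1000 people tested with UACR rather than not tested, the model spends
an extra ¥10.3M (tests and drugs, partly offset by averted dialysis and CV
care), gains 16.1 QALYs, and prevents 0.78 dialysis initiations — about
¥0.64M per QALY, well under the ¥5M threshold. `run_scenario(cfg, "combo")`,
`run_subgroup(cfg, state = "MODERATE")`,
`run_subgroup(cfg, stratum = "DIPSTICK_NEGATIVE")` and `one_way_dsa(cfg)`
cover the scenario, subgroup and sensitivity analyses; `exec/uacr-cea` is an
equivalent command-line wrapper. See `vignettes/uacr-cea-methods.Rmd` for
the modelling conventions and their rationale.

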