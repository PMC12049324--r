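# Default model manifest: non-diabetic CKD screening cost-effectiveness model,
# Japanese healthcare-system perspective, 2023 JPY. Table files are resolved
# relative to this manifest.
run:
  starting_age: 60
  max_age: 100
  cycle_length: 1
  discount_rate: 0.02
  cohort_scale: 1000
  female_proportion: 0.467
starting_distribution:
  egfr: {G1: 0.285, G2: 0.642, G3a: 0.066, G3b: 0.004, G4: 0.002, G5: 0.001}
  albuminuria: {A1: 0.830, A2: 0.160, A3: 0.011}
treatment:
  base:
    rrr_progression: 0.21
    rrr_mortality: 0.1
  combo:
    rrr_progression: 0.35
    rrr_mortality: 0.1
flags:
  # treatment (and the test-strategy difference it carries) modifies
  # transitions taken from the initial health state only; "lifetime" keeps the
  # treatment flag after leaving the initial state
  treatment_scope: initial_state
  # the published cardiovascular reference incidence 0.109 is read as a
  # 10-year risk ("annual" reads it as an annual probability directly)
  cv_rate_basis: per10y
  # hazard ratios compose on the rate scale, q = 1 - (1 - q0)^HR
  # ("linear" uses q = min(q0 * HR, 1))
  hr_composition: rate
  # the treatment mortality RRR scales the whole effective hazard ratio
  # ("excess" scales only the excess over HR = 1)
  mortality_rrr_basis: total
  half_cycle: false
  # outcomes of model year t (ages start+t to start+t+1) are valued at the
  # start of the year, discounted by 1/(1+r)^t ("cycle_end" values them at
  # year end, 1/(1+r)^(t+1))
  accrual: cycle_start
  # subarachnoid haemorrhage has no published unit cost; costed at the
  # intracerebral-haemorrhage rate ("other" uses the other-CV-event rate)
  sah_cost_basis: ich
tables:
  transitions: transitions.csv
  adjustment_factors: adjustment_factors.csv
  mortality_hr: mortality_hr.csv
  cv: cv.csv
  costs: costs.csv
  resource_use: resource_use.csv
  utilities: utilities.csv
  reclassification: reclassification.csv
  life_table: life_table_synthetic.csv
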