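# Shared fixtures: configurations are built once per test run.

DEFAULT_CFG <- default_config()

# all treatment effects switched off (both scenarios)
zero_rrr_config <- function() {
  load_config(overrides = list(treatment = list(
    base  = list(rrr_progression = 0, rrr_mortality = 0),
    combo = list(rrr_progression = 0, rrr_mortality = 0)
  )))
}

# single-state cohort with constant background mortality and no progression:
# survival is a pure geometric decay
single_state_config <- function(q = 0.02, hr_one = TRUE) {
  tp <- DEFAULT_CFG$tables$transitions
  tp$probability <- 0
  lt <- DEFAULT_CFG$tables$life_table
  lt$qx <- q
  hrt <- DEFAULT_CFG$tables$mortality_hr
  if (hr_one) hrt$hr <- 1
  load_config(overrides = list(
    starting_distribution = list(
      egfr = list(G1 = 1, G2 = 0, G3a = 0, G3b = 0, G4 = 0, G5 = 0),
      albuminuria = list(A1 = 1, A2 = 0, A3 = 0)
    ),
    tables = list(transitions = tp, life_table = lt, mortality_hr = hrt)
  ))
}

# near-immortal, frozen cohort (conservation tests)
frozen_config <- function() {
  tp <- DEFAULT_CFG$tables$transitions
  tp$probability <- 0
  lt <- DEFAULT_CFG$tables$life_table
  lt$qx <- 1e-12
  load_config(overrides = list(tables = list(transitions = tp, life_table = lt)))
}
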