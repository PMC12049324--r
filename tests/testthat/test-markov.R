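BASE_TP <- uacrcea:::cfg_base_transitions(DEFAULT_CFG)
HR_CELLS <- uacrcea:::cfg_hr_cells(DEFAULT_CFG)
LIFE <- uacrcea:::cfg_life_table(DEFAULT_CFG)

test_that("state mortality HR aggregates cell HRs by occupancy weight", {
  expect_equal(state_mortality_hr("MODERATE", c("G1:A2" = 1), HR_CELLS), 1.88)
  expect_equal(state_mortality_hr("VERY_HIGH", c("G4:A1" = 0.5, "G4:A2" = 0.5),
                                  HR_CELLS), (4.71 + 4.41) / 2)
  expect_equal(state_mortality_hr("HIGH", c("G3b:A1" = 1e-9), HR_CELLS), 2.59)
  expect_error(state_mortality_hr("LOW", numeric(0), HR_CELLS), "empty")
})

test_that("death probability composes the hazard ratio on the rate scale", {
  lt <- c("70" = 0.01)
  expect_equal(death_probability(70, 1, lt), 0.01)
  expect_equal(death_probability(70, 2, lt), 1 - 0.99^2)
  # treated probability is strictly smaller
  expect_lt(death_probability(70, 2, lt, treated = TRUE, rrr_mort = 0.1),
            death_probability(70, 2, lt))
  expect_error(death_probability(200, 1, lt), "outside")

  # per-day hazard discretisation oracle: scale the daily hazard by the HR
  # and compound over 365 days
  q_bg <- 0.04; hr <- 3.2
  h_day <- -log(1 - q_bg) / 365
  q_oracle <- 1 - (1 - hr * h_day)^365
  expect_equal(death_probability(70, hr, c("70" = q_bg)), q_oracle,
               tolerance = 1e-3)
})

test_that("progression rows compose adjustment, treatment, mortality and residual", {
  row <- progression_row("LOW", BASE_TP)
  expect_equal(unname(row["MODERATE"]), 0.085)
  expect_equal(unname(row["HIGH"]), 0.002)
  expect_equal(unname(row["LOW"]), 0.913)
  expect_equal(sum(row), 1)

  treated <- progression_row("LOW", BASE_TP, treated = TRUE, rrr_prog = 0.21)
  expect_equal(unname(treated["MODERATE"]), 0.085 * 0.79)

  # neutral settings reproduce the base row exactly
  expect_identical(progression_row("LOW", BASE_TP, adjustment_factor = 1,
                                   treated = TRUE, rrr_prog = 0),
                   progression_row("LOW", BASE_TP))

  # improvement transitions are never scaled
  r2 <- progression_row("MODERATE", BASE_TP, adjustment_factor = 0.5,
                        treated = TRUE, rrr_prog = 0.5)
  expect_equal(unname(r2["LOW"]), 0.337)
  expect_equal(unname(r2["HIGH"]), 0.067 * 0.5 * 0.5)

  # mortality thins all living entries proportionally
  r3 <- progression_row("LOW", BASE_TP, death_prob = 0.1)
  expect_equal(unname(r3["DEATH"]), 0.1)
  expect_equal(unname(r3["MODERATE"]), 0.085 * 0.9)
  expect_equal(sum(r3), 1)

  expect_error(progression_row("VERY_HIGH", BASE_TP, adjustment_factor = 10),
               "adjustment overflow")
})

test_that("every constructed transition row is row-stochastic", {
  set.seed(7)
  for (i in 1:200) {
    s <- sample(LIVING_STATES, 1)
    row <- progression_row(s, BASE_TP,
                           adjustment_factor = stats::runif(1, 0.3, 1.6),
                           treated = stats::runif(1) < 0.5,
                           rrr_prog = stats::runif(1, 0, 0.5),
                           death_prob = stats::runif(1, 0, 0.5))
    expect_true(all(row >= 0 & row <= 1))
    expect_equal(sum(row), 1, tolerance = 1e-12)
  }
})

test_that("CV event probability converts the 10-year reference risk and is monotone in HR", {
  cvp <- uacrcea:::cfg_cv(DEFAULT_CFG)
  q_low <- cv_annual_probability("LOW", cvp)
  expect_equal(q_low, 1 - (1 - 0.109)^(1 / 10), tolerance = 1e-12)
  expect_equal(q_low, 0.0114747, tolerance = 1e-5)
  q <- vapply(LIVING_STATES, cv_annual_probability, numeric(1), cv = cvp)
  expect_true(all(diff(q[c("LOW", "MODERATE", "HIGH", "VERY_HIGH", "ESKD")]) > 0))
  # HR = 1 reproduces the reference annual probability exactly
  cvp1 <- cvp; cvp1$hr[] <- 1
  expect_equal(cv_annual_probability("HIGH", cvp1), q_low)
})

test_that("cohort traces conserve mass with monotone death and non-negative events", {
  for (arm in TEST_STRATEGIES) {
    tr <- run_cohort(DEFAULT_CFG, arm)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, "DEATH"]) >= 0))
    expect_true(all(tr$incident_eskd >= 0))
    expect_true(all(tr$cv_events >= 0))
    expect_true(all(tr$occupancy >= 0))
  }
})

test_that("a frozen cohort (no transitions, negligible mortality) stays put", {
  tr <- run_cohort(frozen_config(), "UACR")
  T1 <- nrow(tr$occupancy)
  for (s in LIVING_STATES) {
    expect_equal(tr$occupancy[T1, s], tr$occupancy[1, s], tolerance = 1e-9)
  }
})

test_that("arms are equivalent when treatment does nothing", {
  cfg0 <- zero_rrr_config()
  tr <- lapply(stats::setNames(TEST_STRATEGIES, TEST_STRATEGIES),
               function(a) run_cohort(cfg0, a))
  expect_identical(tr$UACR$occupancy, tr$NONE$occupancy)
  expect_identical(tr$UPCR$occupancy, tr$NONE$occupancy)
  expect_identical(tr$UACR$incident_eskd, tr$NONE$incident_eskd)
  expect_identical(tr$UACR$cv_events, tr$NONE$cv_events)
})

test_that("single-state survival matches the geometric series closed form", {
  q <- 0.02
  cfg <- single_state_config(q)
  tr <- run_cohort(cfg, "NONE")
  T <- cfg$run$max_age - cfg$run$starting_age
  # undiscounted person-years at start-of-year occupancy: sum_{t=0}^{T-1} (1-q)^t
  ly <- sum(tr$occupancy[1:T, LIVING_STATES])
  expect_equal(ly, (1 - (1 - q)^T) / q, tolerance = 1e-12)
  expect_equal(unname(tr$occupancy[T + 1, "DEATH"]), 1 - (1 - q)^T,
               tolerance = 1e-12)
})

test_that("stronger progression treatment weakly reduces ESKD entries and extends life", {
  eskd <- ly <- numeric(0)
  for (rrr in c(0, 0.21, 0.5)) {
    cfg <- load_config(overrides = list(treatment = list(
      base = list(rrr_progression = rrr))))
    tr <- run_cohort(cfg, "UACR")
    eskd <- c(eskd, sum(tr$incident_eskd))
    T <- length(tr$cycles) - 1
    ly <- c(ly, sum(tr$occupancy[1:T, LIVING_STATES]))
  }
  expect_true(all(diff(eskd) <= 0))
  expect_true(all(diff(ly) >= 0))
})

test_that("lifetime treatment scope amplifies the arm contrast", {
  cfg_lt <- load_config(overrides = list(flags = list(treatment_scope = "lifetime")))
  tr_i <- run_cohort(DEFAULT_CFG, "UACR")
  tr_l <- run_cohort(cfg_lt, "UACR")
  # treated mass persists rather than decaying with tunnel exit
  expect_gt(tr_l$acei_mass[20], tr_i$acei_mass[20])
  T <- length(tr_i$cycles) - 1
  expect_gt(sum(tr_l$occupancy[1:T, LIVING_STATES]),
            sum(tr_i$occupancy[1:T, LIVING_STATES]))
})
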