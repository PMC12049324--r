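fake_summary <- function(cost, qaly, arm = "UACR") {
  structure(list(arm = arm, scenario = "base", stratum = "UNSTRATIFIED",
                 cost = cost, qaly = qaly, ly = qaly, dialysis = 0,
                 cv_events = 0,
                 undiscounted = list(cost = cost, ly = qaly, qaly = qaly),
                 cohort_scale = 1000), class = "uacr_summary")
}

test_that("incremental comparisons classify the cost-effectiveness plane", {
  b <- fake_summary(100, 10, "NONE")
  expect_equal(incremental(fake_summary(120, 12), b)$icer, 10)
  expect_equal(incremental(fake_summary(120, 10), b)$label, "DOMINATED")
  expect_equal(incremental(fake_summary(120, 9), b)$label, "DOMINATED")
  expect_equal(incremental(fake_summary(90, 12), b)$label, "DOMINANT")
  expect_equal(incremental(fake_summary(90, 10), b)$label, "DOMINANT")
  expect_equal(incremental(fake_summary(100, 10), b)$label, "identical")
  # cheaper and worse: ICER is reported, not a dominance label
  sw <- incremental(fake_summary(80, 8), b)
  expect_equal(sw$label, "ICER")
  expect_equal(sw$icer, 10)
})

test_that("incremental is antisymmetric in its arguments", {
  cfg <- DEFAULT_CFG
  a <- accumulate(run_cohort(cfg, "UACR"), cfg)
  b <- accumulate(run_cohort(cfg, "NONE"), cfg)
  ab <- incremental(a, b); ba <- incremental(b, a)
  for (f in c("delta_cost", "delta_qaly", "delta_ly", "delta_dialysis",
              "delta_cv_events")) {
    expect_equal(ab[[f]], -ba[[f]])
  }
})

test_that("willingness-to-pay classification at the 5M JPY threshold", {
  b <- fake_summary(0, 0, "NONE")
  expect_true(is_cost_effective(incremental(fake_summary(4e6, 1), b)))
  expect_false(is_cost_effective(incremental(fake_summary(6e6, 1), b)))
  expect_true(is_cost_effective(incremental(fake_summary(-1, 1), b)))
  expect_false(is_cost_effective(incremental(fake_summary(1, 0), b)))
})

test_that("base case is deterministic and internally consistent", {
  res1 <- run_base_case(DEFAULT_CFG)
  res2 <- run_base_case(DEFAULT_CFG)
  j1 <- jsonlite::toJSON(incremental_table(res1), digits = NA)
  j2 <- jsonlite::toJSON(incremental_table(res2), digits = NA)
  expect_identical(j1, j2)

  # pairwise consistency: (UACR - NONE) - (UPCR - NONE) = (UACR - UPCR)
  inc <- res1$incremental
  expect_equal(inc$uacr_vs_none$delta_cost - inc$upcr_vs_none$delta_cost,
               inc$uacr_vs_upcr$delta_cost, tolerance = 1e-9)
  expect_equal(inc$uacr_vs_none$delta_qaly - inc$upcr_vs_none$delta_qaly,
               inc$uacr_vs_upcr$delta_qaly, tolerance = 1e-9)

  # detection ordering carries through to effectiveness
  sm <- res1$summaries
  expect_gt(sm$UACR$qaly, sm$UPCR$qaly)
  expect_gt(sm$UPCR$qaly, sm$NONE$qaly)
})

test_that("null treatment effects collapse all effect deltas to zero", {
  res <- run_base_case(zero_rrr_config())
  for (inc in res$incremental) {
    expect_identical(inc$delta_qaly, 0)
    expect_identical(inc$delta_ly, 0)
    expect_identical(inc$delta_dialysis, 0)
    expect_identical(inc$delta_cv_events, 0)
  }
  # the testing arms still pay for their tests and drugs
  expect_gt(res$incremental$uacr_vs_none$delta_cost, 0)
})

test_that("risk-state subgroups reproduce the published qualitative pattern", {
  # low risk: no treatment follows an A1 diagnosis, so testing adds cost only
  low <- run_subgroup(DEFAULT_CFG, state = "LOW")
  expect_identical(low$incremental$uacr_vs_none$delta_qaly, 0)
  expect_gt(low$incremental$uacr_vs_none$delta_cost, 0)
  expect_equal(low$incremental$uacr_vs_none$label, "DOMINATED")
  # high-risk starting states: testing saves money
  for (st in c("HIGH", "VERY_HIGH")) {
    sub <- run_subgroup(DEFAULT_CFG, state = st)
    expect_lt(sub$incremental$uacr_vs_none$delta_cost, 0)
    expect_gt(sub$incremental$uacr_vs_none$delta_qaly, 0)
  }
  expect_error(run_subgroup(DEFAULT_CFG), "exactly one")
  expect_error(run_subgroup(DEFAULT_CFG, state = "LOW", stratum = "DIPSTICK_TRACE"),
               "exactly one")
})

test_that("dipstick strata condition both the cohort and the detection profile", {
  neg_cells <- uacrcea:::starting_cells_for(DEFAULT_CFG, "DIPSTICK_NEGATIVE")
  a_marg <- tapply(neg_cells, kdigo_cells()$a, sum)
  expect_equal(as.numeric(a_marg[c("A1", "A2", "A3")]),
               c(989, 120, 0) / 1109, tolerance = 1e-12)
  res <- run_subgroup(DEFAULT_CFG, stratum = "DIPSTICK_NEGATIVE")
  expect_s3_class(res, "uacr_cea")
  # no macroalbuminuria in the negative stratum
  expect_equal(sum(neg_cells[kdigo_cells()$a == "A3"]), 0)
})

test_that("the combination-therapy scenario strengthens the UACR vs UPCR contrast", {
  base <- run_base_case(DEFAULT_CFG, "base")
  combo <- run_scenario(DEFAULT_CFG, "combo")
  expect_gt(combo$incremental$uacr_vs_upcr$delta_qaly,
            base$incremental$uacr_vs_upcr$delta_qaly)
  # free SGLT2is can only lower the incremental cost
  costs0 <- DEFAULT_CFG$tables$costs
  costs0$yen[costs0$category == "sglt2i"] <- 0
  cfg0 <- load_config(overrides = list(tables = list(costs = costs0)))
  combo0 <- run_base_case(cfg0, "combo")
  expect_lt(combo0$incremental$uacr_vs_upcr$delta_cost,
            combo$incremental$uacr_vs_upcr$delta_cost)
})

test_that("one-way DSA re-runs bounds, orders by spread, and validates paths", {
  specs <- data.frame(
    parameter = "discount_rate", path = "run.discount_rate",
    low = 0, high = 0.04, stringsAsFactors = FALSE)
  rec <- one_way_dsa(DEFAULT_CFG, specs)
  expect_equal(nrow(rec), 1)
  expect_true(is.finite(rec$icer_low) && is.finite(rec$icer_high))
  expect_equal(rec$spread, abs(rec$icer_high - rec$icer_low))

  expect_equal(nrow(one_way_dsa(DEFAULT_CFG, specs[0, ])), 0)
  expect_error(one_way_dsa(DEFAULT_CFG, data.frame(
    parameter = "x", path = "no.such.path", low = 1, high = 2)), "no.such.path")

  # weakening the progression effect monotonically shrinks the QALY gain
  dq <- vapply(c(0.05, 0.13, 0.21), function(rrr) {
    cfg <- load_config(overrides = list(treatment = list(
      base = list(rrr_progression = rrr))))
    run_base_case(cfg)$incremental$uacr_vs_none$delta_qaly
  }, numeric(1))
  expect_true(all(diff(dq) > 0))
})

test_that("default DSA parameter set spans the standard drivers", {
  specs <- dsa_default_params(DEFAULT_CFG)
  expect_true(all(c("rrr_progression", "discount_rate", "dialysis_cost",
                    "cv_reference_risk", "utility_eskd") %in% specs$parameter))
  expect_true(all(specs$low <= specs$high))
  # utility bounds never exceed 1
  expect_true(all(specs$high[grepl("^utility", specs$parameter)] <= 1))
})
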