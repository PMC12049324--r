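## Costs, utilities, discounting, outcome aggregation ------------------------

#' Per-cycle discount factor
#'
#' Outcomes of model year `t` are multiplied by `1 / (1 + rate)^t`: the first
#' year (cycle 0) is undiscounted and cycle-1 outcomes are multiplied by
#' `1 / (1 + rate)` (the usual spreadsheet cohort-model convention; see the
#' `accrual` flag for valuing at year end instead).
#'
#' @param cycle Cycle index (>= 0; vectorised).
#' @param rate Annual discount rate (>= 0).
#' @return `1 / (1 + rate)^cycle`.
#' @examples
#' discount_factor(1, 0.02)
#' @export
discount_factor <- function(cycle, rate) {
  stopifnot(all(cycle >= 0), rate >= 0)
  1 / (1 + rate)^cycle
}

state_cost_suffix <- c(LOW = "low", MODERATE = "moderate", HIGH = "high",
                       VERY_HIGH = "very_high")

#' Annual cost of occupying a health state
#'
#' Sums, per person-year: consultation counts times unit consultation costs,
#' the state's annualised test/prescription/other bundles, eGFR tests, the
#' arm's urine test at the state's annual frequency (testing arms only;
#' urine testing continues in ESKD), annual dialysis cost in ESKD, and the
#' annual drug cost of the active treatment regimen.
#'
#' @param state Living health state.
#' @param arm Test strategy (`"UACR"`, `"UPCR"`, `"NONE"`).
#' @param cfg A `uacr_config`.
#' @param regimen Active treatment regimen (`"NONE"`, `"ACEI_ARB"`,
#'   `"ACEI_ARB_PLUS_SGLT2I"`).
#' @return Cost in JPY per person-year.
#' @examples
#' annual_state_cost("LOW", "NONE", default_config())   # 3710
#' annual_state_cost("LOW", "UACR", default_config())   # 5440
#' @export
annual_state_cost <- function(state, arm, cfg, regimen = "NONE") {
  stopifnot(state %in% LIVING_STATES)
  arm <- match.arg(arm, TEST_STRATEGIES)
  regimen <- match.arg(regimen, REGIMENS)
  ru <- cfg_resource_use(cfg)
  total <- ru[state, "gp_consultation"] * cfg_cost(cfg, "gp_consultation") +
    ru[state, "nephrologist_consultation"] * cfg_cost(cfg, "nephrologist_consultation") +
    ru[state, "egfr_test"] * cfg_cost(cfg, "egfr_test")
  if (state %in% names(state_cost_suffix)) {
    sfx <- state_cost_suffix[[state]]
    for (bundle in c("gp_tests_", "gp_prescription_", "nephrologist_tests_",
                     "nephrologist_prescription_", "other_nephrologist_")) {
      total <- total + cfg_cost(cfg, paste0(bundle, sfx))
    }
  } else {
    total <- total + cfg_cost(cfg, "dialysis")
  }
  if (arm != "NONE") {
    test_cost <- cfg_cost(cfg, if (arm == "UACR") "uacr_test" else "upcr_test")
    total <- total + ru[state, "urine_test"] * test_cost
  }
  if (regimen != "NONE") {
    total <- total + cfg_cost(cfg, "acei_arb")
    if (regimen == "ACEI_ARB_PLUS_SGLT2I") total <- total + cfg_cost(cfg, "sglt2i")
  }
  total
}

#' Expected acute-event cost for one cycle
#'
#' Incident ESKD entries each trigger one vascular-access surgery;
#' cardiovascular events are costed at the event-mix-weighted mean of the
#' acute care costs (subarachnoid haemorrhage carries no published cost and
#' is costed at the intracerebral-haemorrhage rate by default). Only acute
#' care costs are attached to CV events.
#'
#' @param incident_eskd Expected incident ESKD entries in the cycle.
#' @param cv_events Expected CV events in the cycle (total across types).
#' @param cfg A `uacr_config`.
#' @return Cost in JPY.
#' @export
event_cost <- function(incident_eskd, cv_events, cfg) {
  stopifnot(incident_eskd >= 0, cv_events >= 0)
  incident_eskd * cfg_cost(cfg, "vascular_access_surgery") +
    cv_events * cv_event_unit_cost(cfg)
}

#' @rdname event_cost
#' @export
cv_event_unit_cost <- function(cfg) {
  mix <- cfg_cv(cfg)$mix
  sah_as <- if (identical(cfg$flags$sah_cost_basis, "other")) "other_cv_event"
            else "stroke_ich"
  unit <- c(myocardial_infarction = cfg_cost(cfg, "myocardial_infarction"),
            stroke_ischemic = cfg_cost(cfg, "stroke_ischemic"),
            stroke_ich = cfg_cost(cfg, "stroke_ich"),
            stroke_sah = cfg_cost(cfg, sah_as),
            other_cv_event = cfg_cost(cfg, "other_cv_event"))
  sum(mix[names(unit)] * unit)
}

#' Aggregate a cohort trace into a per-1000 outcome summary
#'
#' Attaches annual state costs, drug costs, one-time event costs, utilities
#' and survival to each model year of a trace, discounts per
#' [discount_factor()] (occupancy at the start of year `t` accrues that
#' year's outcomes at factor `1/(1+r)^t` by default; the `accrual` and
#' `half_cycle` flags select the alternatives), and scales to the configured
#' cohort size (1000 by default).
#' Clinical event counts (dialysis initiations = cumulative incident ESKD
#' entries; CV events) are reported undiscounted; costs, life years and
#' QALYs are reported discounted with undiscounted twins alongside.
#'
#' @param trace A `uacr_trace` from [run_cohort()].
#' @param cfg The `uacr_config` the trace was run under.
#' @return A `uacr_summary` with fields `cost`, `ly`, `qaly` (discounted),
#'   `dialysis`, `cv_events` (cumulative), and `undiscounted$cost/ly/qaly`,
#'   all per `cfg$run$cohort_scale` persons.
#' @export
accumulate <- function(trace, cfg) {
  T <- length(trace$cycles) - 1
  r <- cfg$run$discount_rate
  u <- cfg_utilities(cfg)[LIVING_STATES]
  state_costs <- vapply(LIVING_STATES, annual_state_cost, numeric(1),
                        arm = trace$arm, cfg = cfg)
  acei_cost <- cfg_cost(cfg, "acei_arb")
  sglt_cost <- cfg_cost(cfg, "sglt2i")

  occ <- trace$occupancy[, LIVING_STATES, drop = FALSE]
  acei <- trace$acei_mass
  sglt <- trace$sglt2i_mass
  if (isTRUE(cfg$flags$half_cycle)) {
    occ <- (occ[1:T, , drop = FALSE] + occ[2:(T + 1), , drop = FALSE]) / 2
    acei <- (acei[1:T] + acei[2:(T + 1)]) / 2
    sglt <- (sglt[1:T] + sglt[2:(T + 1)]) / 2
  } else if (identical(cfg$flags$accrual %||% "cycle_start", "cycle_end")) {
    occ <- occ[2:(T + 1), , drop = FALSE]
    acei <- acei[2:(T + 1)]
    sglt <- sglt[2:(T + 1)]
  } else {
    occ <- occ[1:T, , drop = FALSE]
    acei <- acei[1:T]
    sglt <- sglt[1:T]
  }

  per_cycle_cost <- as.vector(occ %*% state_costs) +
    acei * acei_cost + sglt * sglt_cost +
    trace$incident_eskd[2:(T + 1)] * cfg_cost(cfg, "vascular_access_surgery") +
    trace$cv_events[2:(T + 1)] * cv_event_unit_cost(cfg)
  per_cycle_ly <- rowSums(occ)
  per_cycle_qaly <- as.vector(occ %*% u)

  disc <- if (isTRUE(cfg$flags$half_cycle) ||
              identical(cfg$flags$accrual %||% "cycle_start", "cycle_end")) {
    discount_factor(1:T, r)
  } else {
    discount_factor(0:(T - 1), r)
  }
  scale <- cfg$run$cohort_scale
  structure(list(
    arm = trace$arm, scenario = trace$scenario, stratum = trace$stratum,
    cost = sum(per_cycle_cost * disc) * scale,
    ly = sum(per_cycle_ly * disc) * scale,
    qaly = sum(per_cycle_qaly * disc) * scale,
    dialysis = sum(trace$incident_eskd) * scale,
    cv_events = sum(trace$cv_events) * scale,
    undiscounted = list(cost = sum(per_cycle_cost) * scale,
                        ly = sum(per_cycle_ly) * scale,
                        qaly = sum(per_cycle_qaly) * scale),
    cohort_scale = scale
  ), class = "uacr_summary")
}

#' @export
print.uacr_summary <- function(x, ...) {
  cat(sprintf("<uacr_summary> arm %s, scenario %s (per %d persons, discounted)\n",
              x$arm, x$scenario, x$cohort_scale))
  cat(sprintf("  cost: %s JPY\n", format(round(x$cost), big.mark = ",")))
  cat(sprintf("  LYs: %.2f   QALYs: %.2f\n", x$ly, x$qaly))
  cat(sprintf("  dialysis initiations: %.2f   CV events: %.2f\n",
              x$dialysis, x$cv_events))
  invisible(x)
}

#' @export
as.data.frame.uacr_summary <- function(x, ...) {
  data.frame(arm = x$arm, scenario = x$scenario, stratum = x$stratum,
             cost = x$cost, ly = x$ly, qaly = x$qaly,
             dialysis = x$dialysis, cv_events = x$cv_events,
             cost_undiscounted = x$undiscounted$cost,
             ly_undiscounted = x$undiscounted$ly,
             qaly_undiscounted = x$undiscounted$qaly,
             stringsAsFactors = FALSE)
}

#' Health-state utilities as eGFR-weighted averages
#'
#' Computes each health state's utility as the mean of eGFR-category
#' utilities weighted by the proportion of the state's patients in each
#' category. The packaged default utility set is used directly as published;
#' this operator supports re-deriving it from user-supplied eGFR-level
#' utilities.
#'
#' @param utility_by_egfr Named utilities per eGFR category, each in (0, 1].
#' @param egfr_props_by_state Named list: per state, named proportions over
#'   the eGFR categories (each summing to 1).
#' @return Named vector of per-state utilities.
#' @examples
#' weighted_state_utilities(c(G1 = 0.9, G2 = 0.8),
#'                          list(LOW = c(G1 = 0.75, G2 = 0.25)))
#' @export
weighted_state_utilities <- function(utility_by_egfr, egfr_props_by_state) {
  stopifnot(all(utility_by_egfr > 0), all(utility_by_egfr <= 1))
  vapply(egfr_props_by_state, function(w) {
    if (abs(sum(w) - 1) > 1e-6) stop("state eGFR proportions must sum to 1")
    uu <- utility_by_egfr[names(w)]
    if (anyNA(uu)) stop("utility missing for eGFR category")
    sum(uu * w)
  }, numeric(1))
}
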