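## Incremental cost-effectiveness analysis -----------------------------------

#' Incremental comparison of two arm summaries
#'
#' Differences are `a - b`. The ICER is reported when the quadrant does not
#' imply dominance; a strategy that is cheaper and no less effective is
#' `"DOMINANT"`, and one that is costlier and no more effective is
#' `"DOMINATED"` (including the boundary case of extra cost with exactly
#' zero QALY gain, matching the published subgroup reporting).
#'
#' @param a,b `uacr_summary` objects from [accumulate()], run under the same
#'   configuration apart from arm/scenario.
#' @param comparison Optional label, e.g. `"UACR vs NONE"`.
#' @return A `uacr_incremental`: deltas on cost, QALYs, LYs, dialysis and CV
#'   events, the ICER (JPY per QALY gained; `NA` when dominance applies or
#'   the arms are identical) and a `label` in
#'   `{"ICER", "DOMINANT", "DOMINATED", "identical"}`.
#' @export
incremental <- function(a, b, comparison = paste(a$arm, "vs", b$arm)) {
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  res <- list(
    comparison = comparison,
    delta_cost = d_cost,
    delta_qaly = d_qaly,
    delta_ly = a$ly - b$ly,
    delta_dialysis = a$dialysis - b$dialysis,
    delta_cv_events = a$cv_events - b$cv_events,
    icer = NA_real_,
    label = "ICER"
  )
  if (d_cost == 0 && d_qaly == 0) {
    res$label <- "identical"
  } else if (d_cost < 0 && d_qaly >= 0) {
    res$label <- "DOMINANT"
  } else if (d_cost > 0 && d_qaly <= 0) {
    res$label <- "DOMINATED"
  } else {
    res$icer <- d_cost / d_qaly
  }
  structure(res, class = "uacr_incremental")
}

#' @export
print.uacr_incremental <- function(x, ...) {
  cat(sprintf("<uacr_incremental> %s\n", x$comparison))
  cat(sprintf("  delta cost: %s JPY   delta QALYs: %.2f   delta LYs: %.2f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly, x$delta_ly))
  cat(sprintf("  delta dialysis: %.2f   delta CV events: %.2f\n",
              x$delta_dialysis, x$delta_cv_events))
  if (x$label == "ICER") {
    cat(sprintf("  ICER: %s JPY/QALY\n", format(round(x$icer), big.mark = ",")))
  } else {
    cat(sprintf("  %s\n", x$label))
  }
  invisible(x)
}

#' Cost-effectiveness against a willingness-to-pay threshold
#'
#' @param inc A `uacr_incremental`.
#' @param wtp Willingness-to-pay per QALY (default 5,000,000 JPY, the
#'   threshold used in Japanese health technology assessment).
#' @return `TRUE` iff the comparison is dominant or has an ICER below `wtp`.
#' @export
is_cost_effective <- function(inc, wtp = 5e6) {
  if (inc$label == "DOMINANT") return(TRUE)
  if (inc$label %in% c("DOMINATED", "identical")) return(FALSE)
  inc$icer < wtp && inc$delta_qaly > 0
}

run_arm <- function(cfg, arm, scenario, stratum = "UNSTRATIFIED",
                    starting_cells = NULL) {
  accumulate(run_cohort(cfg, arm, scenario, stratum, starting_cells), cfg)
}

#' Run the three-arm base case
#'
#' Runs the cohort under UACR testing, UPCR testing and no urine testing and
#' reports the three pairwise incremental results (UACR vs none, UPCR vs
#' none, UACR vs UPCR).
#'
#' @param cfg A validated `uacr_config`.
#' @param scenario Treatment scenario (`"base"` or `"combo"`).
#' @param stratum Dipstick stratum (cohort and detection conditioning).
#' @param starting_cells Optional starting cell occupancy override.
#' @return A `uacr_cea`: `summaries` (per arm) and `incremental` (the three
#'   pairs), all deterministic for a fixed configuration.
#' @examples
#' \donttest{
#' res <- run_base_case(default_config())
#' res$incremental$uacr_vs_none
#' }
#' @export
run_base_case <- function(cfg, scenario = c("base", "combo"),
                          stratum = "UNSTRATIFIED", starting_cells = NULL) {
  scenario <- match.arg(scenario)
  sm <- lapply(stats::setNames(TEST_STRATEGIES, TEST_STRATEGIES), run_arm,
               cfg = cfg, scenario = scenario, stratum = stratum,
               starting_cells = starting_cells)
  structure(list(
    summaries = sm,
    incremental = list(
      uacr_vs_none = incremental(sm$UACR, sm$NONE),
      upcr_vs_none = incremental(sm$UPCR, sm$NONE),
      uacr_vs_upcr = incremental(sm$UACR, sm$UPCR)
    ),
    scenario = scenario, stratum = stratum
  ), class = "uacr_cea")
}

#' @export
print.uacr_cea <- function(x, ...) {
  cat(sprintf("<uacr_cea> scenario %s, stratum %s\n", x$scenario, x$stratum))
  for (inc in x$incremental) print(inc)
  invisible(x)
}

#' @export
as.data.frame.uacr_cea <- function(x, ...) {
  arms <- do.call(rbind, lapply(x$summaries, as.data.frame))
  rownames(arms) <- NULL
  arms
}

#' Incremental results for a data.frame of the three comparisons
#'
#' @param x A `uacr_cea`.
#' @return A data.frame, one row per pairwise comparison.
#' @export
incremental_table <- function(x) {
  do.call(rbind, lapply(x$incremental, function(i) {
    data.frame(comparison = i$comparison, delta_cost = i$delta_cost,
               delta_qaly = i$delta_qaly, delta_ly = i$delta_ly,
               delta_dialysis = i$delta_dialysis,
               delta_cv_events = i$delta_cv_events,
               icer = i$icer, label = i$label, stringsAsFactors = FALSE)
  }))
}

#' Run the analysis for a subgroup
#'
#' Either restricts the starting cohort to one CKD risk state (the cycle-0
#' occupancy is concentrated on that state's KDIGO cells, renormalised), or
#' swaps in a dipstick stratum: the stratum's gold-standard class mix
#' conditions the starting albuminuria marginal and its re-test rows drive
#' the detection profile.
#'
#' @param cfg A validated `uacr_config`.
#' @param state Starting risk state (`"LOW"`, `"MODERATE"`, `"HIGH"`,
#'   `"VERY_HIGH"`), or `NULL`.
#' @param stratum Dipstick stratum, or `NULL`. Exactly one of `state` and
#'   `stratum` must be given.
#' @param scenario Treatment scenario.
#' @return A `uacr_cea`.
#' @export
run_subgroup <- function(cfg, state = NULL, stratum = NULL,
                         scenario = c("base", "combo")) {
  scenario <- match.arg(scenario)
  if (is.null(state) == is.null(stratum))
    stop("give exactly one of 'state' or 'stratum'")
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, DIPSTICK_STRATA)
    return(run_base_case(cfg, scenario, stratum = stratum))
  }
  state <- match.arg(state, CKD_STATES)
  cells <- starting_cells_for(cfg, "UNSTRATIFIED")
  keep <- kdigo_risk_map(names(cells)) == state
  cells[!keep] <- 0
  if (sum(cells) <= 0) stop("empty subgroup: no starting mass in ", state)
  run_base_case(cfg, scenario, starting_cells = cells / sum(cells))
}

#' Run a treatment scenario
#'
#' Convenience wrapper: the combination scenario widens eligibility to
#' SGLT2 inhibitors (G3a--G4 diagnosed A2 or G1--G4 diagnosed A3), applies
#' the stronger progression effect and adds the SGLT2i drug cost.
#'
#' @inheritParams run_base_case
#' @export
run_scenario <- function(cfg, scenario = c("base", "combo")) {
  run_base_case(cfg, scenario = match.arg(scenario))
}

## One-way deterministic sensitivity analysis --------------------------------

set_param <- function(cfg, path, value) {
  if (grepl("^cost:", path)) {
    cat_name <- sub("^cost:", "", path)
    i <- which(cfg$tables$costs$category == cat_name)
    if (length(i) != 1) stop("unknown parameter path: ", path)
    cfg$tables$costs$yen[i] <- value
  } else if (grepl("^utility:", path)) {
    st <- sub("^utility:", "", path)
    i <- which(cfg$tables$utilities$state == st)
    if (length(i) != 1) stop("unknown parameter path: ", path)
    cfg$tables$utilities$utility[i] <- value
  } else if (path == "cv:reference_risk_10yr") {
    i <- which(cfg$tables$cv$item == "reference_risk_10yr")
    cfg$tables$cv$value[i] <- value
  } else {
    keys <- strsplit(path, ".", fixed = TRUE)[[1]]
    node <- cfg
    for (k in keys) {
      if (is.null(node[[k]])) stop("unknown parameter path: ", path)
      node <- node[[k]]
    }
    cfg[[keys]] <- value
  }
  cfg
}

#' Default one-way sensitivity parameter set
#'
#' The standard driver set at +/- 20\% of the base value: treatment effects,
#' discount rate, dialysis and drug costs, state utilities (capped at 1) and
#' the cardiovascular reference risk.
#'
#' @param cfg A `uacr_config`.
#' @param rel Relative half-width of the range (default 0.2).
#' @return A data.frame with columns `parameter`, `path`, `low`, `high`.
#' @export
dsa_default_params <- function(cfg, rel = 0.2) {
  base_of <- function(path) {
    if (grepl("^cost:", path)) {
      cfg$tables$costs$yen[cfg$tables$costs$category == sub("^cost:", "", path)]
    } else if (grepl("^utility:", path)) {
      cfg$tables$utilities$utility[cfg$tables$utilities$state == sub("^utility:", "", path)]
    } else if (path == "cv:reference_risk_10yr") {
      cfg$tables$cv$value[cfg$tables$cv$item == "reference_risk_10yr"]
    } else {
      node <- cfg
      for (k in strsplit(path, ".", fixed = TRUE)[[1]]) node <- node[[k]]
      node
    }
  }
  paths <- c(
    rrr_progression = "treatment.base.rrr_progression",
    rrr_mortality = "treatment.base.rrr_mortality",
    discount_rate = "run.discount_rate",
    dialysis_cost = "cost:dialysis",
    acei_arb_cost = "cost:acei_arb",
    cv_reference_risk = "cv:reference_risk_10yr",
    utility_low = "utility:LOW",
    utility_moderate = "utility:MODERATE",
    utility_high = "utility:HIGH",
    utility_very_high = "utility:VERY_HIGH",
    utility_eskd = "utility:ESKD"
  )
  base <- vapply(paths, base_of, numeric(1))
  low <- base * (1 - rel)
  high <- base * (1 + rel)
  high[grepl("^utility:", paths)] <- pmin(high[grepl("^utility:", paths)], 1)
  data.frame(parameter = names(paths), path = unname(paths),
             low = unname(low), high = unname(high), stringsAsFactors = FALSE)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the base case at the low and high bound of each parameter and
#' records the resulting ICERs of the chosen comparison, sorted by ICER
#' spread (tornado order). The ICER is recorded as the cost/QALY ratio even
#' in dominance quadrants (`NA` when the QALY difference is zero).
#'
#' @param cfg A validated `uacr_config`.
#' @param param_specs A data.frame with columns `parameter`, `path`, `low`,
#'   `high` (see [dsa_default_params()]); an empty data.frame yields an
#'   empty result.
#' @param comparison Which pairwise ICER to track (default
#'   `"uacr_vs_none"`).
#' @param scenario Treatment scenario.
#' @return A data.frame of DSA records: parameter, bounds, low/high ICERs
#'   and absolute spread, in decreasing spread order.
#' @export
one_way_dsa <- function(cfg, param_specs = dsa_default_params(cfg),
                        comparison = c("uacr_vs_none", "upcr_vs_none",
                                       "uacr_vs_upcr"),
                        scenario = c("base", "combo")) {
  comparison <- match.arg(comparison)
  scenario <- match.arg(scenario)
  empty <- data.frame(parameter = character(0), path = character(0),
                      low = numeric(0), high = numeric(0),
                      icer_low = numeric(0), icer_high = numeric(0),
                      spread = numeric(0), stringsAsFactors = FALSE)
  if (is.null(param_specs) || nrow(param_specs) == 0) return(empty)

  icer_at <- function(path, value) {
    res <- run_base_case(set_param(cfg, path, value), scenario = scenario)
    inc <- res$incremental[[comparison]]
    if (inc$delta_qaly == 0) NA_real_ else inc$delta_cost / inc$delta_qaly
  }
  rec <- param_specs
  rec$icer_low <- mapply(icer_at, rec$path, rec$low)
  rec$icer_high <- mapply(icer_at, rec$path, rec$high)
  rec$spread <- abs(rec$icer_high - rec$icer_low)
  rec[order(-rec$spread), , drop = FALSE]
}
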