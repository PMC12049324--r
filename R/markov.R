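## Markov cohort engine ------------------------------------------------------

REGIMENS <- c("NONE", "ACEI_ARB", "ACEI_ARB_PLUS_SGLT2I")

compose_hr <- function(q, hr, composition = c("rate", "linear")) {
  composition <- match.arg(composition)
  out <- if (composition == "rate") 1 - (1 - q)^hr else q * hr
  pmin(pmax(out, 0), 1 - 1e-15)
}

effective_hr <- function(hr, treated, rrr_mort, basis = c("total", "excess")) {
  basis <- match.arg(basis)
  if (!treated || rrr_mort == 0) return(hr)
  if (basis == "total") hr * (1 - rrr_mort) else 1 + (hr - 1) * (1 - rrr_mort)
}

#' Aggregate a state's mortality hazard ratio from its KDIGO cells
#'
#' Each health state groups several KDIGO heatmap cells with distinct
#' published mortality hazard ratios; the state-level hazard ratio is the
#' occupancy-weighted mean of its cell values (ESKD aggregates the G5 cells,
#' weighted by the albuminuria marginal).
#'
#' @param state Health state name (informational; weights define the cells).
#' @param cell_weights Named non-negative weights over the state's `"G:A"`
#'   cells; renormalised internally.
#' @param hr_table Named vector of hazard ratios per cell (e.g.
#'   `uacrcea:::cfg_hr_cells(cfg)`).
#' @return The weighted-mean hazard ratio.
#' @examples
#' cfg <- default_config()
#' state_mortality_hr("MODERATE", c("G1:A2" = 1), uacrcea:::cfg_hr_cells(cfg))
#' @export
state_mortality_hr <- function(state, cell_weights, hr_table) {
  if (length(cell_weights) == 0 || sum(cell_weights) <= 0)
    stop("empty cell weight vector for state ", state)
  hrs <- hr_table[names(cell_weights)]
  if (anyNA(hrs)) stop("hazard ratio missing for cell(s): ",
                       paste(names(cell_weights)[is.na(hrs)], collapse = ", "))
  sum(cell_weights * hrs) / sum(cell_weights)
}

#' Annual death probability from background mortality and a hazard ratio
#'
#' Scales the life-table annual background death probability by a CKD
#' mortality hazard ratio on the rate scale,
#' `q = 1 - (1 - q_bg(age))^hr`, which keeps the result a probability for
#' any positive hazard ratio. Treatment applies its mortality relative risk
#' reduction to the effective hazard ratio.
#'
#' @param age Integer age (must be covered by the life table).
#' @param hr Mortality hazard ratio (> 0).
#' @param life_table Named vector `age -> qx` (e.g.
#'   `uacrcea:::cfg_life_table(cfg)`).
#' @param treated Whether the treatment mortality effect applies.
#' @param rrr_mort Relative risk reduction for mortality while treated.
#' @param composition `"rate"` (default) or `"linear"` (`q_bg * hr`, capped).
#' @param rrr_basis `"total"` scales the whole hazard ratio; `"excess"`
#'   scales only the excess over 1.
#' @return Annual death probability in `[0, 1)`.
#' @export
death_probability <- function(age, hr, life_table, treated = FALSE,
                              rrr_mort = 0, composition = "rate",
                              rrr_basis = "total") {
  q_bg <- life_table[as.character(age)]
  if (anyNA(q_bg)) stop("age ", age, " outside the life table range")
  if (hr <= 0) stop("hazard ratio must be > 0")
  compose_hr(unname(q_bg), effective_hr(hr, treated, rrr_mort, rrr_basis),
             composition)
}

worsening_states <- function(state) {
  i <- match(state, LIVING_STATES)
  LIVING_STATES[seq_along(LIVING_STATES) > i]
}

#' Build one row of the per-cycle transition matrix
#'
#' Composes, in a fixed order, (1) the KDIGO-cell adjustment factor on the
#' worsening-direction probabilities (first transition only), (2) the
#' treatment progression relative risk reduction on the same worsening set,
#' (3) mortality thinning of all living destinations, and (4) the residual
#' mass assigned to remaining in the state. Improvement transitions (e.g.
#' moderate back to low risk) are never scaled: the adjustment factor and
#' treatment effect act on progression risk only.
#'
#' @param state Living state the row leaves from.
#' @param base 5x5 base annual transition matrix over the living states
#'   (`uacrcea:::cfg_base_transitions(cfg)`; diagonal = residual remain).
#' @param adjustment_factor KDIGO-cell factor applied to worsening moves.
#' @param treated Whether the progression treatment effect applies.
#' @param rrr_prog Relative risk reduction for progression while treated.
#' @param death_prob Annual death probability for this row.
#' @return Named length-6 probability vector over the health states, summing
#'   to exactly 1.
#' @examples
#' cfg <- default_config()
#' progression_row("LOW", uacrcea:::cfg_base_transitions(cfg))
#' @export
progression_row <- function(state, base, adjustment_factor = 1,
                            treated = FALSE, rrr_prog = 0, death_prob = 0) {
  stopifnot(state %in% LIVING_STATES, death_prob >= 0, death_prob < 1)
  moves <- base[state, ]
  moves[state] <- 0
  w <- worsening_states(state)
  moves[w] <- moves[w] * adjustment_factor
  if (treated) moves[w] <- moves[w] * (1 - rrr_prog)
  if (sum(moves) > 1) {
    stop("adjustment overflow: worsening mass from ", state, " exceeds 1")
  }
  living <- moves
  living[state] <- 1 - sum(moves)
  row <- c(living * (1 - death_prob), DEATH = death_prob)
  names(row) <- RISK_STATES
  row
}

#' Annual cardiovascular event probability by health state
#'
#' The published reference incidence (0.109 for the low-risk state) is read
#' as a 10-year risk, converted to an annual probability
#' `q1 = 1 - (1 - risk)^(1/10)`, and the state's hazard ratio is applied on
#' the rate scale. CV events are cost-generating side events: they change
#' neither state nor survival in this model.
#'
#' @param state Living health state.
#' @param cv CV parameter list (`uacrcea:::cfg_cv(cfg)`).
#' @param basis `"per10y"` (default) or `"annual"`.
#' @param composition Hazard-ratio composition, as in [death_probability()].
#' @return Annual event probability.
#' @examples
#' cv_annual_probability("LOW", uacrcea:::cfg_cv(default_config()))
#' @export
cv_annual_probability <- function(state, cv, basis = "per10y",
                                  composition = "rate") {
  stopifnot(state %in% LIVING_STATES)
  q1 <- if (basis == "per10y") 1 - (1 - cv$reference_risk_10yr)^(1 / 10)
        else cv$reference_risk_10yr
  compose_hr(q1, unname(cv$hr[state]), composition)
}

#' Run the Markov cohort for one testing arm
#'
#' Traces a closed cohort from the starting KDIGO-cell distribution over
#' annual cycles up to the maximum age. The first transition of each member
#' uses cell-specific rows (base state row times the cell's KDIGO adjustment
#' factor on worsening moves) together with the member's diagnosis-specific
#' treatment flag and cell-specific mortality hazard ratio. While a member
#' remains in the initial health state the treatment flag stays active
#' (without re-applying the adjustment factor); on the first transition out
#' of the initial state the member joins the state-level pool, which under
#' the default `treatment_scope = "initial_state"` evolves with untreated
#' state-average rows identical across arms. `treatment_scope = "lifetime"`
#' instead keeps the treatment flag after leaving the initial state.
#'
#' @param cfg A validated `uacr_config`.
#' @param arm Test strategy (`"UACR"`, `"UPCR"`, `"NONE"`).
#' @param scenario Treatment scenario (`"base"` or `"combo"`).
#' @param stratum Dipstick stratum conditioning the cohort and the detection
#'   profile.
#' @param starting_cells Optional named 18-cell probability vector replacing
#'   the configured starting distribution (used for risk-state subgroups).
#' @return A `uacr_trace`: per cycle `t = 0..T`, occupancy over the six
#'   states, incident ESKD entries, expected CV events, deaths, treated drug
#'   masses and ages.
#' @export
run_cohort <- function(cfg, arm, scenario = c("base", "combo"),
                       stratum = "UNSTRATIFIED", starting_cells = NULL) {
  arm <- match.arg(arm, TEST_STRATEGIES)
  scenario <- match.arg(scenario)
  horizon <- cfg$run$max_age - cfg$run$starting_age
  if (horizon < 1) stop("model horizon must be at least one cycle")

  cells <- kdigo_cells()
  n_cells <- nrow(cells)
  cell_state <- kdigo_risk_map(cells$cell)
  base <- cfg_base_transitions(cfg)
  af <- cfg_adjustment_factors(cfg)
  hr_cells <- cfg_hr_cells(cfg)
  life <- cfg_life_table(cfg)
  cvp <- cfg_cv(cfg)
  flags <- cfg$flags
  lifetime_scope <- identical(flags$treatment_scope, "lifetime")

  rrr_prog <- c(NONE = 0,
                ACEI_ARB = cfg$treatment$base$rrr_progression,
                ACEI_ARB_PLUS_SGLT2I = cfg$treatment$combo$rrr_progression)
  rrr_mort <- c(NONE = 0,
                ACEI_ARB = cfg$treatment$base$rrr_mortality,
                ACEI_ARB_PLUS_SGLT2I = cfg$treatment$combo$rrr_mortality)

  if (is.null(starting_cells)) starting_cells <- starting_cells_for(cfg, stratum)
  if (sum(starting_cells) <= 0) stop("empty starting cohort")
  starting_cells <- starting_cells / sum(starting_cells)

  # state-aggregate mortality HRs, weighted by the starting cell distribution
  state_hr <- vapply(LIVING_STATES, function(s) {
    w <- starting_cells[cell_state == s]
    if (sum(w) <= 0) {
      # subgroup runs can empty a state; fall back to the configured marginals
      w <- starting_cells_for(cfg, "UNSTRATIFIED")[cell_state == s]
    }
    if (sum(w) <= 0) w[] <- 1  # degenerate cohorts: unweighted cell mean
    state_mortality_hr(s, w, hr_cells)
  }, numeric(1))

  q_cv <- vapply(LIVING_STATES, cv_annual_probability, numeric(1),
                 cv = cvp, basis = flags$cv_rate_basis,
                 composition = flags$hr_composition)

  # cycle-0 allocation: diagnosis -> treatment regimen, per cell
  D <- detection_profile(cfg$tables$reclassification, arm, stratum)
  joint <- diagnosed_cell_distribution(starting_cells, D)
  tunnel <- matrix(0, n_cells, 3, dimnames = list(cells$cell, REGIMENS))
  for (k in seq_len(3)) {
    reg <- treatment_assignment(cells$g, A_CLASSES[k], scenario)
    for (r in REGIMENS) tunnel[reg == r, r] <- tunnel[reg == r, r] + joint[reg == r, k]
  }
  pooled <- matrix(0, 5, 3, dimnames = list(LIVING_STATES, REGIMENS))
  dead <- 0

  # Null treatment effects make every regimen's dynamics identical; merging
  # the regimen columns then makes the occupancy trace exactly (not just up
  # to float rounding) invariant to the testing arm, while drug-cost masses
  # are carried by per-cell regimen shares, which are constant within the
  # initial-state tunnel.
  active <- REGIMENS[colSums(tunnel) > 0 & REGIMENS != "NONE"]
  merged <- !lifetime_scope &&
    all(rrr_prog[active] == 0) && all(rrr_mort[active] == 0)
  share_acei <- share_sglt <- numeric(n_cells)
  if (merged) {
    pos <- starting_cells > 0
    share_acei[pos] <- (tunnel[pos, "ACEI_ARB"] +
                        tunnel[pos, "ACEI_ARB_PLUS_SGLT2I"]) / starting_cells[pos]
    share_sglt[pos] <- tunnel[pos, "ACEI_ARB_PLUS_SGLT2I"] / starting_cells[pos]
    tunnel[] <- 0
    tunnel[, "NONE"] <- starting_cells
  }

  occ <- matrix(0, horizon + 1, 6,
                dimnames = list(NULL, RISK_STATES))
  incident_eskd <- cv_events <- deaths <- acei_mass <- sglt2i_mass <-
    numeric(horizon + 1)

  snapshot <- function(t) {
    st <- stats::setNames(numeric(5), LIVING_STATES)
    agg <- rowsum(rowSums(tunnel), cell_state)
    st[rownames(agg)] <- st[rownames(agg)] + agg[, 1]
    st <- st + rowSums(pooled)
    occ[t + 1, ] <<- c(st, DEATH = dead)
    if (merged) {
      acei_mass[t + 1] <<- sum(tunnel[, "NONE"] * share_acei)
      sglt2i_mass[t + 1] <<- sum(tunnel[, "NONE"] * share_sglt)
    } else {
      treated_tot <- colSums(tunnel) + colSums(pooled)
      acei_mass[t + 1] <<- treated_tot["ACEI_ARB"] + treated_tot["ACEI_ARB_PLUS_SGLT2I"]
      sglt2i_mass[t + 1] <<- treated_tot["ACEI_ARB_PLUS_SGLT2I"]
    }
  }
  snapshot(0)

  for (t in seq_len(horizon) - 1L) {
    age <- cfg$run$starting_age + t
    new_tunnel <- matrix(0, n_cells, 3, dimnames = dimnames(tunnel))
    new_pooled <- matrix(0, 5, 3, dimnames = dimnames(pooled))
    d_death <- d_eskd <- d_cv <- 0

    for (r in REGIMENS) {
      treated <- r != "NONE"
      # members still in their initial cell
      for (i in which(tunnel[, r] > 0)) {
        mass <- tunnel[i, r]
        s <- cell_state[i]
        q_d <- death_probability(age, hr_cells[i], life, treated,
                                 rrr_mort[r], flags$hr_composition,
                                 flags$mortality_rrr_basis)
        row <- progression_row(s, base,
                               adjustment_factor = if (t == 0L) af[i] else 1,
                               treated = treated, rrr_prog = rrr_prog[r],
                               death_prob = q_d)
        stay <- row[s]
        new_tunnel[i, r] <- new_tunnel[i, r] + mass * stay
        move_to <- setdiff(LIVING_STATES, s)
        dest_reg <- if (lifetime_scope) r else "NONE"
        new_pooled[move_to, dest_reg] <- new_pooled[move_to, dest_reg] +
          mass * row[move_to]
        d_death <- d_death + mass * row["DEATH"]
        if (s != "ESKD") d_eskd <- d_eskd + mass * row["ESKD"]
        d_cv <- d_cv + mass * q_cv[s]
      }
      # members who have left their initial state (state-average dynamics)
      for (s in LIVING_STATES) {
        mass <- pooled[s, r]
        if (mass <= 0) next
        q_d <- death_probability(age, state_hr[s], life, treated,
                                 rrr_mort[r], flags$hr_composition,
                                 flags$mortality_rrr_basis)
        row <- progression_row(s, base, adjustment_factor = 1,
                               treated = treated, rrr_prog = rrr_prog[r],
                               death_prob = q_d)
        new_pooled[, r] <- new_pooled[, r] + mass * row[LIVING_STATES]
        d_death <- d_death + mass * row["DEATH"]
        if (s != "ESKD") d_eskd <- d_eskd + mass * row["ESKD"]
        d_cv <- d_cv + mass * q_cv[s]
      }
    }

    tunnel <- new_tunnel
    pooled <- new_pooled
    dead <- dead + d_death
    snapshot(t + 1L)
    incident_eskd[t + 2L] <- d_eskd
    cv_events[t + 2L] <- d_cv
    deaths[t + 2L] <- d_death
  }

  structure(list(
    occupancy = occ,
    incident_eskd = incident_eskd,
    cv_events = cv_events,
    deaths = deaths,
    acei_mass = acei_mass,
    sglt2i_mass = sglt2i_mass,
    cycles = 0:horizon,
    ages = cfg$run$starting_age + 0:horizon,
    arm = arm, scenario = scenario, stratum = stratum
  ), class = "uacr_trace")
}

#' @export
print.uacr_trace <- function(x, ...) {
  T <- length(x$cycles) - 1
  cat(sprintf("<uacr_trace> arm %s, scenario %s, %d annual cycles (ages %d-%d)\n",
              x$arm, x$scenario, T, x$ages[1], x$ages[T + 1]))
  cat(sprintf("  survival at horizon: %.4f; cumulative incident ESKD: %.4f\n",
              1 - x$occupancy[T + 1, "DEATH"], sum(x$incident_eskd)))
  cat(sprintf("  expected CV events per person: %.4f\n", sum(x$cv_events)))
  invisible(x)
}

#' Export a cohort trace as a long data.frame
#'
#' @param trace A `uacr_trace`.
#' @return A data.frame with one row per (cycle, state) holding the occupancy,
#'   plus per-cycle incident ESKD, CV events and deaths attached to the first
#'   state row of each cycle for compact CSV export.
#' @export
trace_to_df <- function(trace) {
  T1 <- length(trace$cycles)
  data.frame(
    cycle = rep(trace$cycles, each = 6),
    age = rep(trace$ages, each = 6),
    state = rep(RISK_STATES, times = T1),
    occupancy = as.vector(t(trace$occupancy)),
    incident_eskd = rep(trace$incident_eskd, each = 6),
    cv_events = rep(trace$cv_events, each = 6),
    stringsAsFactors = FALSE
  )
}
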