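# Individual-level microsimulation oracle: samples n independent patient
# trajectories from the same per-cycle transition rows the cohort engine
# uses (progression_row / death_probability), so any disagreement beyond
# Monte-Carlo error indicates a cohort-aggregation defect.

simulate_microcohort <- function(cfg, arm, scenario = "base", n = 2e5,
                                 seed = 42) {
  set.seed(seed)
  cells <- kdigo_cells()
  cell_state <- kdigo_risk_map(cells$cell)
  base <- uacrcea:::cfg_base_transitions(cfg)
  af <- uacrcea:::cfg_adjustment_factors(cfg)
  hr_cells <- uacrcea:::cfg_hr_cells(cfg)
  life <- uacrcea:::cfg_life_table(cfg)
  cvp <- uacrcea:::cfg_cv(cfg)
  start <- uacrcea:::starting_cells_for(cfg, "UNSTRATIFIED")
  horizon <- cfg$run$max_age - cfg$run$starting_age

  state_hr <- vapply(uacrcea::LIVING_STATES, function(s) {
    state_mortality_hr(s, start[cell_state == s], hr_cells)
  }, numeric(1))
  q_cv <- vapply(uacrcea::LIVING_STATES, cv_annual_probability, numeric(1),
                 cv = cvp, basis = cfg$flags$cv_rate_basis,
                 composition = cfg$flags$hr_composition)

  rrr_prog <- c(NONE = 0, ACEI_ARB = cfg$treatment$base$rrr_progression,
                ACEI_ARB_PLUS_SGLT2I = cfg$treatment$combo$rrr_progression)
  rrr_mort <- c(NONE = 0, ACEI_ARB = cfg$treatment$base$rrr_mortality,
                ACEI_ARB_PLUS_SGLT2I = cfg$treatment$combo$rrr_mortality)

  # draw patients: true cell, diagnosed class, regimen
  cell_idx <- sample.int(18, n, replace = TRUE, prob = start)
  D <- detection_profile(cfg$tables$reclassification, arm)
  diag_class <- character(n)
  for (cl in uacrcea::A_CLASSES) {
    idx <- which(cells$a[cell_idx] == cl)
    if (length(idx)) {
      diag_class[idx] <- sample(uacrcea::A_CLASSES, length(idx),
                                replace = TRUE, prob = D[cl, ])
    }
  }
  regimen <- treatment_assignment(cells$g[cell_idx], diag_class, scenario)

  state <- cell_state[cell_idx]
  in_tunnel <- rep(TRUE, n)
  alive <- rep(TRUE, n)
  years_alive <- integer(n)
  eskd_entered <- logical(n)
  cv_count <- integer(n)

  for (t in seq_len(horizon) - 1L) {
    idx <- which(alive)
    if (length(idx) == 0) break
    years_alive[idx] <- years_alive[idx] + 1L
    age <- cfg$run$starting_age + t

    cv_count[idx] <- cv_count[idx] +
      (stats::runif(length(idx)) < q_cv[state[idx]])

    key <- ifelse(in_tunnel[idx],
                  paste0("cell", cell_idx[idx], ":", regimen[idx]),
                  paste0("state", state[idx]))
    for (k in unique(key)) {
      members <- idx[key == k]
      p1 <- members[1]
      if (in_tunnel[p1]) {
        ci <- cell_idx[p1]; reg <- regimen[p1]; s <- state[p1]
        treated <- reg != "NONE"
        q_d <- death_probability(age, hr_cells[ci], life, treated,
                                 rrr_mort[reg], cfg$flags$hr_composition,
                                 cfg$flags$mortality_rrr_basis)
        row <- progression_row(s, base,
                               adjustment_factor = if (t == 0L) af[ci] else 1,
                               treated = treated, rrr_prog = rrr_prog[reg],
                               death_prob = q_d)
      } else {
        s <- state[p1]
        q_d <- death_probability(age, state_hr[s], life, FALSE, 0,
                                 cfg$flags$hr_composition,
                                 cfg$flags$mortality_rrr_basis)
        row <- progression_row(s, base, death_prob = q_d)
      }
      u <- stats::runif(length(members))
      nxt <- uacrcea::RISK_STATES[findInterval(u, cumsum(row)) + 1L]
      died <- nxt == "DEATH"
      alive[members[died]] <- FALSE
      moved <- !died & nxt != s
      eskd_entered[members[!died & nxt == "ESKD" & s != "ESKD"]] <- TRUE
      in_tunnel[members[moved]] <- FALSE
      state[members[!died]] <- nxt[!died]
    }
  }

  list(
    ly = mean(years_alive), ly_se = stats::sd(years_alive) / sqrt(n),
    eskd = mean(eskd_entered),
    eskd_se = stats::sd(eskd_entered) / sqrt(n),
    cv = mean(cv_count), cv_se = stats::sd(cv_count) / sqrt(n),
    n = n
  )
}

# matching expectations from a cohort trace (per person, undiscounted,
# start-of-year occupancy)
trace_expectations <- function(trace) {
  T <- length(trace$cycles) - 1
  list(
    ly = sum(trace$occupancy[1:T, uacrcea::LIVING_STATES]),
    eskd = sum(trace$incident_eskd),
    cv = sum(trace$cv_events)
  )
}
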