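## Decision tree: test strategy -> diagnosed albuminuria class ---------------

reclass_counts <- function(reclass, strategy, stratum) {
  rows <- reclass[reclass$stratum == stratum & reclass$strategy == strategy, ]
  if (nrow(rows) != 3) {
    stop("reclassification table has no ", strategy, " rows for stratum ", stratum)
  }
  stats::setNames(rows$count[match(A_CLASSES, rows$class)], A_CLASSES)
}

#' Diagnosed-class distribution of a testing strategy
#'
#' Builds, for each true albuminuria class (UACR is taken as the diagnostic
#' gold standard), the probability of each diagnosed class under a test
#' strategy:
#'
#' * `UACR` observes the true class (identity).
#' * `NONE` assigns every patient to the normoalbuminuria-like class `A1`:
#'   with no urine test, kidney damage is never identified and decisions are
#'   made as if albuminuria were normal.
#' * `UPCR` is reconstructed from the marginal re-test counts under a nested
#'   detection assumption: a patient cannot be classified more severely by
#'   the proteinuria test than by the gold standard, so the
#'   proteinuria-positive sets are subsets of the corresponding
#'   albuminuria-positive sets and a missed case is classified one class
#'   lower. Per-class sensitivity is then the ratio of detected to true
#'   counts.
#'
#' @param reclass Re-test classification table (data.frame with columns
#'   `stratum`, `strategy`, `class`, `proportion`, `count`), e.g.
#'   `default_config()$tables$reclassification`.
#' @param strategy `"UACR"`, `"UPCR"` or `"NONE"`.
#' @param stratum Dipstick stratum; `"UNSTRATIFIED"` (default) uses the whole
#'   re-test cohort.
#' @return A 3x3 matrix; rows are true classes, columns diagnosed classes,
#'   each row summing to one.
#' @examples
#' rc <- default_config()$tables$reclassification
#' detection_profile(rc, "UPCR")["A2", "A2"]  # 75/198
#' @export
detection_profile <- function(reclass, strategy, stratum = "UNSTRATIFIED") {
  strategy <- match.arg(strategy, TEST_STRATEGIES)
  D <- matrix(0, 3, 3, dimnames = list(true = A_CLASSES, diagnosed = A_CLASSES))
  if (strategy == "NONE") {
    D[, "A1"] <- 1
    return(D)
  }
  if (strategy == "UACR") {
    diag(D) <- 1
    return(D)
  }
  u <- reclass_counts(reclass, "UACR", stratum)
  p <- reclass_counts(reclass, "UPCR", stratum)
  if (p["A3"] > u["A3"]) {
    stop("nesting violated in stratum ", stratum,
         ": UPCR ~A3 count exceeds UACR A3 count")
  }
  s3 <- if (u["A3"] > 0) p["A3"] / u["A3"] else 1
  demoted3 <- u["A3"] - p["A3"]          # true A3 classified ~A2
  detected2 <- p["A2"] - demoted3
  if (detected2 < 0 || detected2 > u["A2"]) {
    stop("nesting violated in stratum ", stratum,
         ": UPCR ~A2 count inconsistent with nested detection")
  }
  s2 <- if (u["A2"] > 0) detected2 / u["A2"] else 1
  D["A1", "A1"] <- 1
  D["A2", ] <- c(1 - s2, s2, 0)
  D["A3", ] <- c(0, 1 - s3, s3)
  D
}

#' Joint distribution over true KDIGO cell and diagnosed class
#'
#' The true eGFR stage is observed in every arm (all arms receive regular
#' eGFR testing); the diagnosed albuminuria class attaches to the true class
#' through the strategy's detection profile, independently of the G stage.
#'
#' @param starting_cells Named probability vector over the 18 `"G:A"` cells
#'   (e.g. `starting_distribution(...)$cells`).
#' @param diag A [detection_profile()] matrix.
#' @return An 18x3 matrix of joint probabilities, rows the true cells,
#'   columns the diagnosed classes; total mass equals `sum(starting_cells)`.
#' @export
diagnosed_cell_distribution <- function(starting_cells, diag) {
  cells <- kdigo_cells()
  m <- starting_cells[cells$cell] * diag[cells$a, , drop = FALSE]
  dimnames(m) <- list(cell = cells$cell, diagnosed = A_CLASSES)
  m
}

#' Treatment assigned from a diagnosis
#'
#' Eligibility is keyed on the observed (diagnosed) albuminuria class and the
#' true eGFR stage. Under standard of care, ACEi/ARBs are prescribed for
#' G1--G4 patients diagnosed A2 or A3. Under the combination scenario,
#' SGLT2 inhibitors are added for G3a--G4 diagnosed A2, or G1--G4 diagnosed
#' A3.
#'
#' @param g True eGFR stage (vectorised).
#' @param diagnosed_class Diagnosed albuminuria class (vectorised).
#' @param scenario `"base"` (ACEi/ARBs) or `"combo"` (ACEi/ARBs + SGLT2is).
#' @return Character vector in `{"NONE", "ACEI_ARB", "ACEI_ARB_PLUS_SGLT2I"}`.
#' @examples
#' treatment_assignment("G2", "A2", "base")    # "ACEI_ARB"
#' treatment_assignment("G3a", "A2", "combo")  # "ACEI_ARB_PLUS_SGLT2I"
#' @export
treatment_assignment <- function(g, diagnosed_class, scenario = c("base", "combo")) {
  scenario <- match.arg(scenario)
  stopifnot(all(g %in% G_STAGES), all(diagnosed_class %in% A_CLASSES))
  n <- max(length(g), length(diagnosed_class))
  g <- rep_len(g, n); dc <- rep_len(diagnosed_class, n)
  acei <- g %in% c("G1", "G2", "G3a", "G3b", "G4") & dc %in% c("A2", "A3")
  out <- ifelse(acei, "ACEI_ARB", "NONE")
  if (scenario == "combo") {
    sglt <- (g %in% c("G3a", "G3b", "G4") & dc == "A2") |
            (g %in% c("G1", "G2", "G3a", "G3b", "G4") & dc == "A3")
    out[acei & sglt] <- "ACEI_ARB_PLUS_SGLT2I"
  }
  out
}

#' Fraction of the cohort starting treatment under a strategy
#'
#' @param cfg A `uacr_config`.
#' @param strategy Test strategy.
#' @param scenario Treatment scenario.
#' @param stratum Dipstick stratum (also conditions the starting albuminuria
#'   marginal when not `"UNSTRATIFIED"`).
#' @return Probability that a cohort member is assigned any treatment at
#'   cycle 0.
#' @export
treated_fraction <- function(cfg, strategy, scenario = "base",
                             stratum = "UNSTRATIFIED") {
  start <- starting_cells_for(cfg, stratum)
  D <- detection_profile(cfg$tables$reclassification, strategy, stratum)
  joint <- diagnosed_cell_distribution(start, D)
  cells <- kdigo_cells()
  tx <- outer(cells$g, A_CLASSES,
              function(g, a) treatment_assignment(g, a, scenario))
  sum(joint[tx != "NONE"])
}

# Starting cell occupancy, optionally conditioning the albuminuria marginal
# on a dipstick stratum's gold-standard class mix.
starting_cells_for <- function(cfg, stratum = "UNSTRATIFIED") {
  acr <- cfg$starting$albuminuria
  if (stratum != "UNSTRATIFIED") {
    u <- reclass_counts(cfg$tables$reclassification, "UACR", stratum)
    if (sum(u) <= 0) stop("empty dipstick stratum: ", stratum)
    acr <- u / sum(u)
  }
  starting_distribution(cfg$starting$egfr, acr)$cells
}
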