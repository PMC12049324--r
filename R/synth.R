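## Synthetic inputs: parametric life table, re-test classification data ------

#' Generate a parametric (Gompertz-Makeham) life table
#'
#' Annual death probabilities follow
#' `q(age) = 1 - exp(-(A + B * exp(c * age)))`: a Makeham constant `A` for
#' age-independent background risk plus a Gompertz term for senescent
#' mortality. The defaults (`A = 3e-4`, `B = 8e-6`, `c = 0.105`) give a
#' remaining life expectancy at age 60 of about 26.6 years, in line with a
#' modern high-longevity population; this synthetic table stands in for a
#' national life table, which users can substitute via the `life_table`
#' config slot.
#'
#' @param makeham Age-independent hazard component (>= 0).
#' @param gompertz_level Gompertz level `B` (> 0).
#' @param gompertz_slope Gompertz slope `c` (> 0).
#' @param ages Integer ages to tabulate.
#' @return A data.frame with columns `age` and `qx`, `qx` strictly
#'   increasing in age and strictly inside (0, 1). Deterministic (no
#'   randomness).
#' @examples
#' lt <- synth_life_table()
#' life_expectancy(lt, 60)
#' @export
synth_life_table <- function(makeham = 3e-4, gompertz_level = 8e-6,
                             gompertz_slope = 0.105, ages = 0:104) {
  stopifnot(makeham >= 0, gompertz_level > 0, gompertz_slope > 0)
  hazard <- makeham + gompertz_level * exp(gompertz_slope * ages)
  qx <- 1 - exp(-hazard)
  if (any(qx >= 1)) stop("parameters produce q >= 1 within the age range")
  data.frame(age = as.integer(ages), qx = qx)
}

#' Remaining life expectancy from a life table
#'
#' Discrete survival sum with a half-year continuity correction:
#' `e(x) = sum_t S(t) + 0.5` where `S` is the survivor curve from `from_age`
#' to the end of the table.
#'
#' @param life_table A data.frame with `age` and `qx`.
#' @param from_age Starting age.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(life_table, from_age) {
  qx <- life_table$qx[life_table$age >= from_age]
  if (length(qx) == 0) stop("from_age beyond the life table")
  sum(cumprod(1 - qx)) + 0.5
}

#' Generate synthetic re-test classification counts
#'
#' Emulates the data-generating structure of a re-test study: `n` subjects
#' draw a true albuminuria class multinomially; the gold-standard (UACR)
#' test observes the truth; the proteinuria (UPCR) test detects a class-A2
#' or class-A3 subject with the class sensitivity and classifies misses one
#' class lower (nested detection). Optionally stratifies subjects by a prior
#' dipstick result.
#'
#' @param n Cohort size.
#' @param true_dist Named probabilities of the true classes `A1, A2, A3`.
#'   Defaults to the packaged re-test cohort mix (1027/198/13 of 1238).
#' @param sensitivity Named UPCR detection sensitivities for `A2` and `A3`.
#'   Defaults to the values implied by the packaged table (75/198 and 1).
#' @param dipstick_probs Optional 3 x k matrix of `P(stratum | true class)`
#'   (rows `A1, A2, A3` summing to 1, columns named after dipstick strata);
#'   when given, per-stratum rows are emitted in addition to the
#'   unstratified totals.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return A data.frame in the `reclassification.csv` dialect (columns
#'   `stratum`, `strategy`, `class`, `proportion`, `count`), directly usable
#'   as `cfg$tables$reclassification`.
#' @examples
#' synth_retest_counts(n = 1238, seed = 7)
#' @export
synth_retest_counts <- function(n = 1238,
                                true_dist = c(A1 = 1027, A2 = 198, A3 = 13) / 1238,
                                sensitivity = c(A2 = 75 / 198, A3 = 1),
                                dipstick_probs = NULL, seed = NULL) {
  stopifnot(n > 0, all(true_dist >= 0), abs(sum(true_dist) - 1) < 1e-6,
            all(sensitivity >= 0), all(sensitivity <= 1))
  if (!is.null(seed)) set.seed(seed)

  truth <- sample(A_CLASSES, n, replace = TRUE, prob = true_dist[A_CLASSES])
  upcr <- truth
  a2 <- truth == "A2"
  upcr[a2] <- ifelse(stats::runif(sum(a2)) < sensitivity[["A2"]], "A2", "A1")
  a3 <- truth == "A3"
  upcr[a3] <- ifelse(stats::runif(sum(a3)) < sensitivity[["A3"]], "A3", "A2")

  stratum <- rep("UNSTRATIFIED", n)
  strata <- "UNSTRATIFIED"
  if (!is.null(dipstick_probs)) {
    stopifnot(nrow(dipstick_probs) == 3)
    strata <- colnames(dipstick_probs)
    stratum <- vapply(truth, function(cl) {
      sample(strata, 1, prob = dipstick_probs[match(cl, A_CLASSES), ])
    }, character(1))
  }

  rows <- list()
  emit <- function(st, keep) {
    m <- sum(keep)
    for (strategy in c("UACR", "UPCR")) {
      obs <- if (strategy == "UACR") truth[keep] else upcr[keep]
      cnt <- table(factor(obs, levels = A_CLASSES))
      rows[[length(rows) + 1]] <<- data.frame(
        stratum = st, strategy = strategy, class = A_CLASSES,
        proportion = if (m > 0) as.numeric(cnt) / m else rep(0, 3),
        count = as.integer(cnt), stringsAsFactors = FALSE)
    }
  }
  emit("UNSTRATIFIED", rep(TRUE, n))
  if (!is.null(dipstick_probs)) {
    for (st in strata) emit(st, stratum == st)
  }
  do.call(rbind, rows)
}

#' Monte-Carlo check that sensitivities are recovered from synthetic data
#'
#' Repeatedly generates synthetic re-test tables and re-estimates the
#' per-class UPCR sensitivities through the nested-detection reconstruction
#' used by [detection_profile()], reporting bias and the fraction of
#' replicate estimates within two per-replicate binomial standard errors of
#' the generating value.
#'
#' @param n_reps Number of replicates (>= 100).
#' @param n Cohort size per replicate.
#' @param true_dist,sensitivity As in [synth_retest_counts()].
#' @param seed RNG seed.
#' @return A list: `report` (data.frame per class: generating sensitivity,
#'   mean and SD of the estimates, bias, Monte-Carlo SE of the mean,
#'   coverage) and `pass` (`TRUE` iff every mean estimate is within 3
#'   Monte-Carlo SEs of its generating value).
#' @export
parameter_recovery_check <- function(n_reps = 200, n = 10000,
                                     true_dist = c(A1 = 1027, A2 = 198, A3 = 13) / 1238,
                                     sensitivity = c(A2 = 0.5, A3 = 0.9),
                                     seed = 1) {
  stopifnot(n_reps >= 100)
  set.seed(seed)
  est <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, c("A2", "A3")))
  for (i in seq_len(n_reps)) {
    tab <- synth_retest_counts(n, true_dist, sensitivity)
    D <- detection_profile(tab, "UPCR", "UNSTRATIFIED")
    est[i, ] <- c(D["A2", "A2"], D["A3", "A3"])
  }
  report <- do.call(rbind, lapply(c("A2", "A3"), function(cl) {
    s <- sensitivity[[cl]]
    m <- mean(est[, cl]); sdev <- stats::sd(est[, cl])
    n_class <- n * true_dist[[cl]]
    se_rep <- sqrt(s * (1 - s) / n_class)          # per-replicate binomial SE
    cover <- if (se_rep > 0) mean(abs(est[, cl] - s) <= 2 * se_rep) else
      mean(est[, cl] == s)
    data.frame(class = cl, sensitivity = s, mean_estimate = m, sd = sdev,
               bias = m - s, mc_se = sdev / sqrt(n_reps), coverage = cover,
               stringsAsFactors = FALSE)
  }))
  pass <- all(abs(report$bias) <= pmax(3 * report$mc_se, 1e-12))
  list(report = report, pass = pass)
}
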