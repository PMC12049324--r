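## Model configuration: reading, writing, validation, packaged defaults ------

TABLE_KEYS <- c("transitions", "adjustment_factors", "mortality_hr", "cv",
                "costs", "resource_use", "utilities", "reclassification",
                "life_table")

default_model_dir <- function() {
  system.file("extdata", "default_model", package = "uacrcea", mustWork = TRUE)
}

read_model_table <- function(path, key) {
  if (!file.exists(path)) {
    stop("config incomplete: table '", key, "' not found at ", path)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) stop("failed to parse table '", key, "' (", path, "): ",
                             conditionMessage(e))
  )
  num_cols <- setdiff(names(df), c("from_state", "to_state", "g", "a", "state",
                                   "category", "item", "stratum", "strategy",
                                   "class", "sex"))
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))) & !is.na(df[[cl]]))
      stop("malformed number in table '", key, "', column '", cl, "', row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Load a model configuration
#'
#' Reads a YAML manifest plus the CSV parameter tables it references and
#' returns a validated `uacr_config`. Any field or table absent from the
#' manifest falls back to the packaged default parameter set (the published
#' Japanese inputs: re-test classification, starting distribution, transition
#' probabilities and KDIGO adjustment factors, mortality and cardiovascular
#' hazard ratios, treatment effects, unit costs, resource use and utilities,
#' plus a synthetic background-mortality life table).
#'
#' @param path Path to a `model.yaml` manifest, or to a directory containing
#'   one. `NULL` (default) loads the packaged defaults unchanged.
#' @param overrides Optional named list merged over the manifest (same nesting
#'   as the YAML, e.g. `list(run = list(discount_rate = 0))`). Tables may be
#'   overridden by passing data frames under `tables`.
#' @return A validated object of class `uacr_config`: a list with components
#'   `run`, `starting`, `treatment`, `flags` and `tables`.
#' @seealso [validate_config()], [write_config()], [default_config()]
#' @examples
#' cfg <- default_config()
#' cfg$run$discount_rate
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  def_dir <- default_model_dir()
  manifest <- yaml::read_yaml(file.path(def_dir, "model.yaml"))

  user_dir <- NULL
  user_tables <- character(0)
  if (!is.null(path)) {
    if (dir.exists(path)) path <- file.path(path, "model.yaml")
    if (!file.exists(path)) stop("config manifest not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    user_dir <- dirname(normalizePath(path))
    user_tables <- names(user$tables %||% list())
    manifest <- modifyList(manifest, user)
  }
  if (!is.null(overrides)) {
    tab_over <- overrides$tables
    overrides$tables <- NULL
    manifest <- modifyList(manifest, overrides)
  } else {
    tab_over <- NULL
  }

  tables <- list()
  for (key in TABLE_KEYS) {
    if (!is.null(tab_over[[key]])) {
      tables[[key]] <- as.data.frame(tab_over[[key]])
    } else {
      dir <- if (key %in% user_tables) user_dir else def_dir
      tables[[key]] <- read_model_table(file.path(dir, manifest$tables[[key]]), key)
    }
  }

  cfg <- structure(list(
    run       = manifest$run,
    starting  = list(
      egfr        = unlist(manifest$starting_distribution$egfr)[G_STAGES],
      albuminuria = unlist(manifest$starting_distribution$albuminuria)[A_CLASSES]
    ),
    treatment = manifest$treatment,
    flags     = manifest$flags,
    tables    = tables
  ), class = "uacr_config")

  report <- validate_config(cfg)
  if (nrow(report) > 0) {
    stop("invalid model configuration:\n  ",
         paste(paste0("[", report$field, "] ", report$message), collapse = "\n  "))
  }
  cfg
}

#' @rdname load_config
#' @export
default_config <- function() load_config(NULL)

`%||%` <- function(a, b) if (is.null(a)) b else a

violation <- function(field, message) {
  data.frame(field = field, message = message, stringsAsFactors = FALSE)
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the parameter set (probability
#' bounds, row sums, hazard ratios and adjustment factors positive, utilities
#' in (0,1], costs non-negative, classification proportions summing to one,
#' life-table coverage of the modelled age range) and reports all violations
#' rather than stopping at the first.
#'
#' @param cfg A `uacr_config` (possibly hand-edited).
#' @return A data.frame with columns `field` and `message`, one row per
#'   violated invariant; zero rows when the configuration is valid.
#' @export
validate_config <- function(cfg) {
  rep <- list()
  add <- function(v) rep[[length(rep) + 1]] <<- v

  run <- cfg$run
  if (run$max_age <= run$starting_age)
    add(violation("run", "max_age must exceed starting_age"))
  if (run$discount_rate < 0)
    add(violation("run", "discount_rate must be >= 0"))
  if (run$cohort_scale <= 0)
    add(violation("run", "cohort_scale must be > 0"))

  for (m in c("egfr", "albuminuria")) {
    v <- cfg$starting[[m]]
    if (anyNA(v)) add(violation(paste0("starting.", m), "missing classes"))
    else {
      if (any(v < 0)) add(violation(paste0("starting.", m), "negative proportion"))
      if (abs(sum(v) - 1) > 0.01)
        add(violation(paste0("starting.", m),
                      sprintf("marginal sums to %.4f (must be 1 +/- 0.01)", sum(v))))
    }
  }

  for (sc in c("base", "combo")) {
    tr <- cfg$treatment[[sc]]
    for (f in c("rrr_progression", "rrr_mortality")) {
      if (is.null(tr[[f]]) || tr[[f]] < 0 || tr[[f]] >= 1)
        add(violation(paste0("treatment.", sc), paste0(f, " must be in [0, 1)")))
    }
  }

  tp <- cfg$tables$transitions
  if (any(tp$probability < 0 | tp$probability > 1))
    add(violation("transitions", "probabilities must be in [0, 1]"))
  for (s in LIVING_STATES) {
    rs <- sum(tp$probability[tp$from_state == s])
    if (s != "ESKD" && rs >= 1)
      add(violation("transitions",
                    sprintf("row %s sums to %.3f before residual (must be < 1)", s, rs)))
  }
  if (any(tp$to_state %in% LIVING_STATES[1:4] & tp$from_state == "ESKD" &
          tp$probability > 0))
    add(violation("transitions", "ESKD must not transition back to CKD states"))

  af <- cfg$tables$adjustment_factors
  if (any(af$factor <= 0))
    add(violation("adjustment_factors", "factors must be > 0"))

  hr <- cfg$tables$mortality_hr
  if (nrow(hr) != 18 || anyDuplicated(paste(hr$g, hr$a)))
    add(violation("mortality_hr", "must list exactly the 18 KDIGO cells"))
  if (any(hr$hr <= 0))
    add(violation("mortality_hr", "hazard ratios must be > 0"))

  cv <- cfg$tables$cv
  mix <- cv$value[cv$item == "event_proportion"]
  if (abs(sum(mix) - 1) > 0.005)
    add(violation("cv", sprintf("event mix sums to %.4f (must be 1 +/- 0.005)", sum(mix))))
  if (any(cv$value[cv$item == "hazard_ratio"] <= 0))
    add(violation("cv", "hazard ratios must be > 0"))

  if (any(cfg$tables$costs$yen < 0))
    add(violation("costs", "costs must be >= 0"))
  if (any(cfg$tables$resource_use$annual_count < 0))
    add(violation("resource_use", "annual counts must be >= 0"))

  ut <- cfg$tables$utilities
  for (s in LIVING_STATES) {
    u <- ut$utility[ut$state == s]
    if (length(u) != 1 || u <= 0 || u > 1)
      add(violation("utilities", paste0("utility for ", s, " out of (0, 1]")))
  }
  if (!isTRUE(all(ut$utility[ut$state == "DEATH"] == 0)))
    add(violation("utilities", "DEATH utility must be 0"))

  rc <- cfg$tables$reclassification
  for (st in unique(rc$stratum)) for (sg in unique(rc$strategy)) {
    rows <- rc[rc$stratum == st & rc$strategy == sg, ]
    if (nrow(rows) == 0) next
    if (abs(sum(rows$proportion) - 1) > 0.005)
      add(violation("reclassification",
                    sprintf("%s/%s proportions sum to %.4f", st, sg, sum(rows$proportion))))
  }

  lt <- cfg$tables$life_table
  ages_needed <- run$starting_age:(run$max_age - 1)
  if (!all(ages_needed %in% lt$age))
    add(violation("life_table",
                  sprintf("must cover every integer age in [%d, %d)",
                          run$starting_age, run$max_age)))
  qx <- lt$qx[lt$age %in% ages_needed]
  if (any(qx <= 0 | qx >= 1))
    add(violation("life_table", "qx must be strictly in (0, 1) over the model ages"))

  if (length(rep) == 0) {
    data.frame(field = character(0), message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rep)
  }
}

#' Write a model configuration to disk
#'
#' Writes `model.yaml` plus all parameter tables as CSV into `dir`, in the
#' same dialect [load_config()] reads, so that
#' `load_config(write_config(cfg, dir))` round-trips field-by-field.
#'
#' @param cfg A `uacr_config`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- stats::setNames(paste0(TABLE_KEYS, ".csv"), TABLE_KEYS)
  files["life_table"] <- "life_table_synthetic.csv"
  manifest <- list(
    run = cfg$run,
    starting_distribution = list(
      egfr        = as.list(cfg$starting$egfr),
      albuminuria = as.list(cfg$starting$albuminuria)
    ),
    treatment = cfg$treatment,
    flags = cfg$flags,
    tables = as.list(files)
  )
  yaml::write_yaml(manifest, file.path(dir, "model.yaml"), precision = 15)
  for (key in TABLE_KEYS) {
    utils::write.csv(cfg$tables[[key]], file.path(dir, files[[key]]),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @export
print.uacr_config <- function(x, ...) {
  cat("<uacr_config> CKD urine-testing cost-effectiveness model\n")
  cat(sprintf("  cohort: start age %d, horizon to age %d, %d-person scale\n",
              x$run$starting_age, x$run$max_age, x$run$cohort_scale))
  cat(sprintf("  discount rate: %.3f per annum\n", x$run$discount_rate))
  cat(sprintf("  flags: treatment_scope=%s, cv_rate_basis=%s, hr_composition=%s\n",
              x$flags$treatment_scope, x$flags$cv_rate_basis, x$flags$hr_composition))
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

## Starting distribution -----------------------------------------------------

#' Joint starting distribution over KDIGO cells and health states
#'
#' Forms the cycle-0 cohort occupancy as the outer product of the eGFR-stage
#' and albuminuria-class marginals (independence assumption: the source
#' aggregate data report only marginals). Both marginals are renormalised to
#' sum exactly to one before the product is taken; the joint cell mass is then
#' collapsed onto the six health states via [kdigo_risk_map()].
#'
#' @param egfr_props Named proportions over `G1 ... G5` (sum within 0.01 of 1).
#' @param acr_props Named proportions over `A1, A2, A3` (sum within 0.01 of 1).
#' @return A list with `cells` (named length-18 probability vector over
#'   `"G:A"` cells) and `states` (named length-6 probability vector over the
#'   health states; DEATH mass 0).
#' @examples
#' cfg <- default_config()
#' sd <- starting_distribution(cfg$starting$egfr, cfg$starting$albuminuria)
#' round(sd$states, 4)
#' @export
starting_distribution <- function(egfr_props, acr_props) {
  g <- egfr_props[G_STAGES]
  a <- acr_props[A_CLASSES]
  if (anyNA(g) || anyNA(a)) stop("marginals must be named over all stages/classes")
  if (any(g < 0) || any(a < 0)) stop("negative proportion in starting marginals")
  if (abs(sum(g) - 1) > 0.01 || abs(sum(a) - 1) > 0.01)
    stop("starting marginals must sum to 1 within 0.01 (printed rounding)")
  g <- g / sum(g)
  a <- a / sum(a)

  cells_df <- kdigo_cells()
  cells <- stats::setNames(g[cells_df$g] * a[cells_df$a], cells_df$cell)
  states <- stats::setNames(numeric(length(RISK_STATES)), RISK_STATES)
  agg <- tapply(cells, kdigo_risk_map(names(cells)), sum)
  states[names(agg)] <- agg
  list(cells = cells, states = states)
}

## Internal table accessors --------------------------------------------------

cfg_cost <- function(cfg, category) {
  tab <- cfg$tables$costs
  hit <- tab$yen[tab$category == category]
  if (length(hit) != 1) stop("unknown cost category: ", category)
  hit
}

cfg_utilities <- function(cfg) {
  ut <- cfg$tables$utilities
  stats::setNames(ut$utility, ut$state)[RISK_STATES]
}

cfg_hr_cells <- function(cfg) {
  hr <- cfg$tables$mortality_hr
  stats::setNames(hr$hr, paste(hr$g, hr$a, sep = ":"))
}

cfg_adjustment_factors <- function(cfg) {
  af <- cfg$tables$adjustment_factors
  out <- stats::setNames(rep(1, 18), kdigo_cells()$cell)  # G5 cells default to 1
  out[paste(af$g, af$a, sep = ":")] <- af$factor
  out
}

# 5x5 base transition matrix over living states (diagonal = residual "remain",
# before mortality thinning)
cfg_base_transitions <- function(cfg) {
  tp <- cfg$tables$transitions
  m <- matrix(0, 5, 5, dimnames = list(LIVING_STATES, LIVING_STATES))
  for (i in seq_len(nrow(tp))) m[tp$from_state[i], tp$to_state[i]] <- tp$probability[i]
  diag(m) <- 1 - rowSums(m)
  m
}

cfg_cv <- function(cfg) {
  cv <- cfg$tables$cv
  list(
    reference_risk_10yr = cv$value[cv$item == "reference_risk_10yr"],
    hr  = stats::setNames(cv$value[cv$item == "hazard_ratio"],
                          cv$category[cv$item == "hazard_ratio"])[LIVING_STATES],
    mix = stats::setNames(cv$value[cv$item == "event_proportion"],
                          cv$category[cv$item == "event_proportion"])
  )
}

cfg_life_table <- function(cfg) {
  lt <- cfg$tables$life_table
  stats::setNames(lt$qx, lt$age)
}

cfg_resource_use <- function(cfg) {
  ru <- cfg$tables$resource_use
  cats <- unique(ru$category)
  m <- matrix(0, length(LIVING_STATES), length(cats),
              dimnames = list(LIVING_STATES, cats))
  for (i in seq_len(nrow(ru))) m[ru$state[i], ru$category[i]] <- ru$annual_count[i]
  m
}
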