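#' @keywords internal
"_PACKAGE"

## State-space constants -----------------------------------------------------

#' eGFR stages, albuminuria classes and model health states
#'
#' The model classifies kidney function by eGFR stage (G1--G5) and kidney
#' damage by albuminuria class (A1 normo-, A2 micro-, A3 macroalbuminuria).
#' The 18 (G, A) cells of the KDIGO prognosis heatmap collapse onto six
#' mutually exclusive health states: four CKD prognosis bands, end-stage
#' kidney disease (ESKD, the dialysis-requiring state) and death.
#'
#' @format Character vectors of level names, in model order.
#' @name state-space
NULL

#' @rdname state-space
#' @export
G_STAGES <- c("G1", "G2", "G3a", "G3b", "G4", "G5")

#' @rdname state-space
#' @export
A_CLASSES <- c("A1", "A2", "A3")

#' @rdname state-space
#' @export
RISK_STATES <- c("LOW", "MODERATE", "HIGH", "VERY_HIGH", "ESKD", "DEATH")

#' @rdname state-space
#' @export
LIVING_STATES <- RISK_STATES[1:5]

#' @rdname state-space
#' @export
CKD_STATES <- RISK_STATES[1:4]

#' @rdname state-space
#' @export
TEST_STRATEGIES <- c("UACR", "UPCR", "NONE")

#' @rdname state-space
#' @export
DIPSTICK_STRATA <- c("UNSTRATIFIED", "DIPSTICK_NEGATIVE", "DIPSTICK_TRACE",
                     "DIPSTICK_POSITIVE")

#' All 18 KDIGO heatmap cells
#'
#' @return A data.frame with columns `g`, `a` and `cell` (e.g. `"G1:A1"`),
#'   one row per (eGFR stage, albuminuria class) combination.
#' @examples
#' kdigo_cells()
#' @export
kdigo_cells <- function() {
  grid <- expand.grid(a = A_CLASSES, g = G_STAGES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(g = grid$g, a = grid$a,
             cell = paste(grid$g, grid$a, sep = ":"),
             stringsAsFactors = FALSE)
}

# Standard KDIGO 2012 prognosis bands; G5 is kidney failure (ESKD) at any A.
.KDIGO_HEATMAP <- c(
  "G1:A1"  = "LOW",       "G1:A2"  = "MODERATE",  "G1:A3"  = "HIGH",
  "G2:A1"  = "LOW",       "G2:A2"  = "MODERATE",  "G2:A3"  = "HIGH",
  "G3a:A1" = "MODERATE",  "G3a:A2" = "HIGH",      "G3a:A3" = "VERY_HIGH",
  "G3b:A1" = "HIGH",      "G3b:A2" = "VERY_HIGH", "G3b:A3" = "VERY_HIGH",
  "G4:A1"  = "VERY_HIGH", "G4:A2"  = "VERY_HIGH", "G4:A3"  = "VERY_HIGH",
  "G5:A1"  = "ESKD",      "G5:A2"  = "ESKD",      "G5:A3"  = "ESKD"
)

#' Map a KDIGO heatmap cell to its model health state
#'
#' Deterministic lookup of the KDIGO 2012 prognosis heatmap: each
#' (eGFR stage, albuminuria class) cell belongs to exactly one prognosis band
#' (low / moderate / high / very high CKD risk); all G5 cells map to ESKD.
#'
#' @param g eGFR stage (`"G1"` ... `"G5"`), or a `"G:A"` cell string when `a`
#'   is missing. Vectorised.
#' @param a Albuminuria class (`"A1"`, `"A2"`, `"A3"`).
#' @return Character vector of health states.
#' @examples
#' kdigo_risk_map("G1", "A1")    # "LOW"
#' kdigo_risk_map("G3a", "A2")   # "HIGH"
#' kdigo_risk_map("G5:A1")      # "ESKD"
#' @export
kdigo_risk_map <- function(g, a) {
  cell <- if (missing(a)) g else paste(g, a, sep = ":")
  out <- unname(.KDIGO_HEATMAP[cell])
  if (anyNA(out)) {
    stop("unknown KDIGO cell(s): ",
         paste(unique(cell[is.na(out)]), collapse = ", "))
  }
  out
}
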