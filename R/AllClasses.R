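#' @import methods
NULL

#' CombinationMatrix: one drug pair on one cell line
#'
#' A k x k grid of normalized growth-inhibition values for a drug combination
#' screened as a full dose matrix, with rows indexed by ascending doses of
#' drug A and columns by ascending doses of drug B.
#'
#' @slot drugA,drugB Drug identifiers.
#' @slot cellLine Cell line identifier.
#' @slot plate Assay plate identifier.
#' @slot concA,concB Strictly increasing concentration vectors (arbitrary
#'   units), lengths matching the grid dimensions.
#' @slot grid Numeric matrix of inhibition values (not clipped; values
#'   slightly outside `[0, 1]` are legal after normalization of noisy wells).
#' @export
setClass("CombinationMatrix",
  representation(
    drugA = "character", drugB = "character",
    cellLine = "character", plate = "character",
    concA = "numeric", concB = "numeric",
    grid = "matrix"
  ),
  prototype(drugA = "A", drugB = "B", cellLine = NA_character_,
            plate = NA_character_)
)

setValidity("CombinationMatrix", function(object) {
  msg <- character()
  if (nrow(object@grid) != length(object@concA))
    msg <- c(msg, "grid rows must match length(concA)")
  if (ncol(object@grid) != length(object@concB))
    msg <- c(msg, "grid columns must match length(concB)")
  if (any(diff(object@concA) <= 0) || any(diff(object@concB) <= 0))
    msg <- c(msg, "concentrations must be strictly increasing")
  if (any(object@concA <= 0) || any(object@concB <= 0))
    msg <- c(msg, "concentrations must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a CombinationMatrix
#'
#' @param grid Numeric k x k matrix of inhibition values, rows = drug A doses
#'   ascending, columns = drug B doses ascending.
#' @param concA,concB Strictly increasing positive concentration vectors.
#' @param drugA,drugB,cellLine,plate Identifiers.
#' @return A [CombinationMatrix-class] object.
#' @examples
#' cm <- CombinationMatrix(matrix(0.5, 7, 7), doseGrid(7), doseGrid(7))
#' dim(inhibitionGrid(cm))
#' @export
CombinationMatrix <- function(grid, concA, concB, drugA = "A", drugB = "B",
                              cellLine = NA_character_,
                              plate = NA_character_) {
  new("CombinationMatrix", grid = as.matrix(grid),
      concA = as.numeric(concA), concB = as.numeric(concB),
      drugA = drugA, drugB = drugB, cellLine = cellLine, plate = plate)
}

#' CurveFit: a fitted two-parameter logistic dose-response curve
#'
#' @slot ic50 Fitted half-maximal dose (same units as the dose axis).
#' @slot slope Fitted shape parameter.
#' @slot emax Fitted inhibition at the highest screened dose.
#' @slot rmse Residual root-mean-square error of the fit.
#' @slot converged Whether the least-squares optimizer converged; when it did
#'   not, `emax` falls back to the observed inhibition at the top dose.
#' @slot censoring `"none"`, `"right"` (fitted IC50 above the top tested
#'   dose) or `"left"` (below the lowest); censored IC50s are extrapolations
#'   and should not be interpreted as measured potencies.
#' @export
setClass("CurveFit",
  representation(ic50 = "numeric", slope = "numeric", emax = "numeric",
                 rmse = "numeric", converged = "logical",
                 censoring = "character")
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!is.na(object@ic50) && object@ic50 <= 0)
    msg <- c(msg, "ic50 must be positive")
  if (!object@censoring %in% c("none", "right", "left"))
    msg <- c(msg, "censoring must be one of none/right/left")
  if (length(msg)) msg else TRUE
})

#' SynergyResult: matrix- and window-level synergy scores for one pair
#'
#' @slot blissMatrix,hsaMatrix Matrix-level scores (mean per-well excess by
#'   default; see [matrixScore()]).
#' @slot blissWindow,hsaWindow Best sliding-window scores (max over windows
#'   of the within-window mean excess).
#' @slot blissWindowLoc,hsaWindowLoc Integer `(row, col)` of the top-left
#'   corner of the winning window, 1-based.
#' @slot comboEmax Second-highest inhibition value in the combination grid.
#' @export
setClass("SynergyResult",
  representation(blissMatrix = "numeric", blissWindow = "numeric",
                 hsaMatrix = "numeric", hsaWindow = "numeric",
                 blissWindowLoc = "integer", hsaWindowLoc = "integer",
                 comboEmax = "numeric")
)

#' QCReport: plate-level quality-control verdict
#'
#' @slot plate Plate identifier.
#' @slot cv Coefficient of variation of the DMSO negative controls.
#' @slot ncRatio Mean untreated / mean DMSO negative-control ratio.
#' @slot zFactors Named Z-factor per positive-control class.
#' @slot zApplicable Named logical: whether the Z check applied (the cell
#'   line is sensitive enough to that positive control).
#' @slot pass Overall verdict.
#' @slot reasons Failed checks (empty iff `pass`).
#' @export
setClass("QCReport",
  representation(plate = "character", cv = "numeric", ncRatio = "numeric",
                 zFactors = "numeric", zApplicable = "logical",
                 pass = "logical", reasons = "character")
)

setValidity("QCReport", function(object) {
  if (object@pass != (length(object@reasons) == 0))
    "pass must be TRUE iff reasons is empty" else TRUE
})

#' SyntheticScreen: a simulated combination screen with ground truth
#'
#' Container returned by [simulateScreen()]: long-format well-level records
#' (combination, single-agent and control wells), cell line annotations, the
#' combination design, a binary feature matrix and the planted ground truth
#' used by recovery tests.
#'
#' @slot wells Long-format well table (see [readScreen()] for the schema).
#' @slot cellLines Cell line annotation: `cell_line`, `cancer_type`,
#'   `group` (`heme`/`solid`), `plate`.
#' @slot combinations Combination design: `combo_id`, `drug_A`, `drug_B`,
#'   pathway classes and mechanism category.
#' @slot features Binary cell line x feature matrix.
#' @slot groundTruth List with elements `curves`, `windows`, `effects`.
#' @slot config The [screenConfig()] list that produced the screen.
#' @export
setClass("SyntheticScreen",
  representation(wells = "data.frame", cellLines = "data.frame",
                 combinations = "data.frame", features = "matrix",
                 groundTruth = "list", config = "list")
)
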