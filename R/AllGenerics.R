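#' @rdname CombinationMatrix
#' @param object,x A [CombinationMatrix-class] object.
#' @export
setGeneric("inhibitionGrid", function(x) standardGeneric("inhibitionGrid"))

#' @rdname CombinationMatrix
#' @export
setGeneric("doseA", function(x) standardGeneric("doseA"))

#' @rdname CombinationMatrix
#' @export
setGeneric("doseB", function(x) standardGeneric("doseB"))

#' @rdname trimMatrix
#' @export
setGeneric("trimMatrix", function(x, nRemove = 2L) standardGeneric("trimMatrix"))

setMethod("inhibitionGrid", "CombinationMatrix", function(x) x@grid)
setMethod("doseA", "CombinationMatrix", function(x) x@concA)
setMethod("doseB", "CombinationMatrix", function(x) x@concB)

setMethod("show", "CombinationMatrix", function(object) {
  cat(sprintf("CombinationMatrix: %s x %s [%s]\n", object@drugA, object@drugB,
              ifelse(is.na(object@cellLine), "-", object@cellLine)))
  cat(sprintf("  %d x %d doses, range %.3g-%.3g / %.3g-%.3g\n",
              length(object@concA), length(object@concB),
              min(object@concA), max(object@concA),
              min(object@concB), max(object@concB)))
  cat(sprintf("  inhibition range [%.3f, %.3f]\n",
              min(object@grid), max(object@grid)))
})

setMethod("show", "CurveFit", function(object) {
  cat(sprintf(
    "CurveFit: IC50 = %.4g (%s), slope = %.3g, Emax = %.3f, RMSE = %.3g%s\n",
    object@ic50, object@censoring, object@slope, object@emax, object@rmse,
    if (object@converged) "" else " [not converged]"))
})

setMethod("show", "SynergyResult", function(object) {
  cat("SynergyResult\n")
  cat(sprintf("  Bliss matrix %+.4f | window %+.4f at (%d,%d)\n",
              object@blissMatrix, object@blissWindow,
              object@blissWindowLoc[1], object@blissWindowLoc[2]))
  cat(sprintf("  HSA   matrix %+.4f | window %+.4f at (%d,%d)\n",
              object@hsaMatrix, object@hsaWindow,
              object@hsaWindowLoc[1], object@hsaWindowLoc[2]))
  cat(sprintf("  combo Emax %.3f\n", object@comboEmax))
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport plate %s: %s\n", object@plate,
              if (object@pass) "PASS" else
                paste("FAIL:", paste(object@reasons, collapse = ", "))))
  cat(sprintf("  CV = %.4f, NC-0/NC-1 = %.3f\n", object@cv, object@ncRatio))
  for (nm in names(object@zFactors))
    cat(sprintf("  Z[%s] = %.3f%s\n", nm, object@zFactors[[nm]],
                if (object@zApplicable[[nm]]) "" else " (not applicable)"))
})

setMethod("show", "SyntheticScreen", function(object) {
  cat(sprintf(
    "SyntheticScreen: %d cell lines, %d combinations, %d wells, %d features\n",
    nrow(object@cellLines), nrow(object@combinations), nrow(object@wells),
    ncol(object@features)))
})

#' Convert a SynergyResult to a one-row data.frame
#'
#' @param x A [SynergyResult-class] object.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @return One-row data.frame with columns `bliss_matrix`, `bliss_window`,
#'   `hsa_matrix`, `hsa_window`, `window_row`, `window_col`, `combo_emax`.
#'   `window_row`/`window_col` refer to the winning Bliss window.
#' @export
as.data.frame.SynergyResult <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    bliss_matrix = x@blissMatrix, bliss_window = x@blissWindow,
    hsa_matrix = x@hsaMatrix, hsa_window = x@hsaWindow,
    window_row = x@blissWindowLoc[1], window_col = x@blissWindowLoc[2],
    combo_emax = x@comboEmax
  )
}
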