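# Normalization of raw viability signal to a growth-inhibition scale,
# two-parameter logistic single-agent fits, combination Emax extraction and
# dose-matrix trimming.

#' Normalize raw signal to the growth-inhibition scale
#'
#' Maps instrument signal to inhibition anchored at 0 = mean of the DMSO
#' negative-control wells (cells fully growing) and 1 = mean of the cell-free
#' blank wells (complete growth inhibition):
#' `inhibition = (mean_nc1 - raw) / (mean_nc1 - mean_blank)`.
#' Values are deliberately not clipped here, so noisy wells may fall slightly
#' outside `[0, 1]`; clipping happens only where a probability reading is
#' required (curve fitting, Bliss/HSA).
#'
#' @param raw Raw well signal(s).
#' @param meanNc1 Mean DMSO negative-control signal of the same plate.
#' @param meanBlank Mean blank-well signal of the same plate.
#' @return Inhibition value(s) on the 0-1 anchored scale.
#' @examples
#' normalizeInhibition(c(1000, 505, 10), meanNc1 = 1000, meanBlank = 10)
#' @export
normalizeInhibition <- function(raw, meanNc1, meanBlank) {
  if (meanNc1 == meanBlank)
    inputError("degenerate normalization: control means are equal")
  (meanNc1 - raw) / (meanNc1 - meanBlank)
}

#' Fit a two-parameter logistic dose-response curve
#'
#' Least-squares fit of `inhibition = 1 / (1 + (IC50/d)^slope)` (asymptotes
#' fixed at 0 and 1) on inhibition values clipped to `[0, 1]`. The optimizer
#' is restarted from a log-spaced grid of IC50 starting values to avoid local
#' minima; the best sum of squares wins. The fitted response at the highest
#' screened dose is reported as the single-agent Emax. IC50 estimates landing
#' outside the tested dose range are flagged as censored extrapolations. On
#' optimizer failure the fit is reported non-converged with Emax falling back
#' to the observed inhibition at the top dose.
#'
#' @param doses Strictly increasing positive dose vector (>= 4 points).
#' @param inhibition Observed inhibition at each dose.
#' @return A [CurveFit-class] object.
#' @examples
#' d <- doseGrid(7)
#' fitLogistic2p(d, logistic2p(d, ic50 = d[4], slope = 2))
#' @export
fitLogistic2p <- function(doses, inhibition) {
  if (length(doses) < 4)
    inputError("fitLogistic2p needs >= 4 dose points")
  if (length(doses) != length(inhibition))
    inputError("doses and inhibition lengths differ")
  if (any(doses <= 0) || any(diff(doses) <= 0))
    inputError("doses must be positive and strictly increasing")
  y <- clip01(inhibition)
  ld <- log(doses)

  lower <- c(logIc50 = log(min(doses)) - log(1000), logSlope = log(0.05))
  upper <- c(logIc50 = log(max(doses)) + log(1000), logSlope = log(20))
  starts <- expand.grid(
    logIc50 = seq(log(min(doses)) - log(10), log(max(doses)) + log(10),
                  length.out = 7),
    logSlope = log(c(0.5, 1, 2))
  )

  best <- NULL; bestSse <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ 1 / (1 + exp(exp(logSlope) * (logIc50 - ld))),
        start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (sse < bestSse) { bestSse <- sse; best <- fit }
    }
  }

  topObs <- clip01(inhibition[which.max(doses)])
  if (is.null(best)) {
    return(new("CurveFit", ic50 = NA_real_, slope = NA_real_, emax = topObs,
               rmse = NA_real_, converged = FALSE, censoring = "right"))
  }
  p <- stats::coef(best)
  ic50 <- exp(p[["logIc50"]]); slope <- exp(p[["logSlope"]])
  emax <- logistic2p(max(doses), ic50, slope)
  censoring <- if (ic50 > max(doses)) "right"
               else if (ic50 < min(doses)) "left" else "none"
  new("CurveFit", ic50 = ic50, slope = slope, emax = emax,
      rmse = sqrt(bestSse / length(y)), converged = TRUE,
      censoring = censoring)
}

#' Combination Emax: second-highest inhibition in the dose matrix
#'
#' As a precaution against single outlying wells, the maximal effect of a
#' combination is reported as the second-highest inhibition value across all
#' wells of the dose matrix (duplicated values count separately).
#'
#' @param x A [CombinationMatrix-class] object or a numeric matrix/vector of
#'   well inhibition values (>= 2 wells).
#' @return The second-largest well value.
#' @examples
#' comboEmax(c(0.95, 0.90, 0.1, 0.2))  # 0.90
#' @export
comboEmax <- function(x) {
  v <- if (is(x, "CombinationMatrix")) as.vector(x@grid) else as.vector(x)
  if (length(v) < 2) inputError("comboEmax needs >= 2 wells")
  sort(v, decreasing = TRUE)[2]
}

#' Trim the highest doses off a combination matrix
#'
#' Removes the `nRemove` highest doses of both drugs (e.g. cutting a 7x7
#' matrix to 5x5 where the top two concentrations are beyond the
#' biologically relevant range), keeping dose axes and grid consistent.
#'
#' @param x A [CombinationMatrix-class] object or a numeric matrix.
#' @param nRemove Number of top doses to drop from each axis (default 2;
#'   must be smaller than the matrix dimension).
#' @return Object of the same class as `x`, trimmed.
#' @examples
#' cm <- CombinationMatrix(matrix(runif(49), 7, 7), doseGrid(7), doseGrid(7))
#' trimMatrix(cm, 2)  # 5x5
#' @name trimMatrix
NULL

#' @rdname trimMatrix
setMethod("trimMatrix", "CombinationMatrix", function(x, nRemove = 2L) {
  k <- min(length(x@concA), length(x@concB))
  if (nRemove >= k) inputError("nRemove must be smaller than matrix dimension")
  if (nRemove == 0) return(x)
  keepA <- seq_len(length(x@concA) - nRemove)
  keepB <- seq_len(length(x@concB) - nRemove)
  CombinationMatrix(x@grid[keepA, keepB, drop = FALSE],
                    x@concA[keepA], x@concB[keepB],
                    drugA = x@drugA, drugB = x@drugB,
                    cellLine = x@cellLine, plate = x@plate)
})

#' @rdname trimMatrix
setMethod("trimMatrix", "matrix", function(x, nRemove = 2L) {
  k <- min(dim(x))
  if (nRemove >= k) inputError("nRemove must be smaller than matrix dimension")
  if (nRemove == 0) return(x)
  x[seq_len(nrow(x) - nRemove), seq_len(ncol(x) - nRemove), drop = FALSE]
})

#' Log-equispaced dose grid
#'
#' Standard screening dose ladder: `n` points log-equispaced across a
#' `foldRange`-fold concentration range ending at `top`.
#'
#' @param n Number of doses (default 7).
#' @param foldRange Ratio between highest and lowest dose (default 1000).
#' @param top Highest dose (default 10, arbitrary units).
#' @return Strictly increasing dose vector of length `n`.
#' @examples
#' doseGrid(7)
#' @export
doseGrid <- function(n = 7, foldRange = 1000, top = 10) {
  stopifnot(n >= 2, foldRange > 1, top > 0)
  top * foldRange^(seq(-1, 0, length.out = n))
}
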