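# Bliss-independence and Highest-Single-Agent excess, matrix-level and
# sliding-window synergy scores.

#' Expected combination effect under Bliss independence
#'
#' For single-agent effects expressed as probabilities, the Bliss-additive
#' expectation is `eA + eB - eA * eB`. Inputs are clipped to `[0, 1]` first
#' (probability semantics); the operation is symmetric in its arguments.
#'
#' @param eA,eB Single-agent inhibition values (vectors recycle as usual).
#' @return Expected combined inhibition under independence.
#' @examples
#' blissExpected(0.5, 0.5)  # 0.75
#' @export
blissExpected <- function(eA, eB) {
  eA <- clip01(eA); eB <- clip01(eB)
  eA + eB - eA * eB
}

#' Per-well synergy excess over a null-combination model
#'
#' Computes, for every well of a combination dose matrix, the observed
#' inhibition minus the model expectation built from the single-agent
#' marginals: Bliss independence (`eA + eB - eA*eB`) or Highest Single Agent
#' (`max(eA, eB)`). Marginals and combination wells are clipped to `[0, 1]`
#' before the excess is computed. Positive excess indicates synergy.
#'
#' @param matrix Numeric k x k matrix of combination inhibition values
#'   (rows = drug A doses ascending, columns = drug B doses) or a
#'   [CombinationMatrix-class].
#' @param marginalsA,marginalsB Single-agent inhibition vectors of drug A
#'   (length = rows) and drug B (length = columns).
#' @param model `"bliss"` or `"hsa"`.
#' @return k x k matrix of per-well excess values.
#' @examples
#' eA <- c(0.2, 0.5); eB <- c(0.1, 0.3)
#' m <- outer(eA, eB, blissExpected)
#' perWellExcess(m, eA, eB, "bliss")  # all zero
#' @export
perWellExcess <- function(matrix, marginalsA, marginalsB,
                          model = c("bliss", "hsa")) {
  model <- match.arg(model)
  if (is(matrix, "CombinationMatrix")) matrix <- inhibitionGrid(matrix)
  if (nrow(matrix) != length(marginalsA) ||
      ncol(matrix) != length(marginalsB))
    inputError("matrix dimensions must match marginal lengths")
  eA <- clip01(marginalsA); eB <- clip01(marginalsB)
  expected <- switch(model,
    bliss = outer(eA, eB, function(a, b) a + b - a * b),
    hsa = outer(eA, eB, pmax))
  clip01(matrix) - expected
}

#' Matrix-level synergy score
#'
#' Summarizes a per-well excess grid over the whole dose matrix. The primary
#' statistic is the arithmetic mean over all wells (so localized synergy in
#' a large matrix can average out to a negative matrix score while the
#' window score stays positive); the per-well maximum is available as an
#' alternative via `statistic = "max"`.
#'
#' @param excessGrid Numeric matrix of per-well excess values (non-empty).
#' @param statistic `"mean"` (default) or `"max"`.
#' @return The matrix-level score.
#' @examples
#' g <- matrix(0, 7, 7); g[1, 1] <- 0.49
#' matrixScore(g)  # 0.01
#' @export
matrixScore <- function(excessGrid, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  if (length(excessGrid) == 0) inputError("empty excess grid")
  if (statistic == "mean") mean(excessGrid) else max(excessGrid)
}

#' Sliding-window synergy score
#'
#' Enumerates every contiguous `w x w` sub-matrix of the excess grid (25 for
#' a 3x3 window on a 7x7 grid) and returns the largest within-window mean
#' together with the 1-based top-left corner of the winning window. Ties are
#' broken row-major: smallest row first, then smallest column. The window
#' score detects dose-localized synergy that the full-matrix average can
#' cancel out.
#'
#' @param excessGrid Numeric matrix of per-well excess values.
#' @param windowSize Window edge length `w` (default 3; must not exceed
#'   either grid dimension).
#' @return List with elements `score`, `row`, `col`.
#' @examples
#' g <- matrix(0, 7, 7); g[4, 4] <- 0.9
#' windowScore(g)$score  # 0.1
#' @export
windowScore <- function(excessGrid, windowSize = 3L) {
  nr <- nrow(excessGrid); nc <- ncol(excessGrid)
  if (windowSize > nr || windowSize > nc)
    inputError("window larger than grid")
  w <- as.integer(windowSize)
  best <- -Inf; bestRow <- 1L; bestCol <- 1L
  for (i in seq_len(nr - w + 1L)) {
    for (j in seq_len(nc - w + 1L)) {
      s <- mean(excessGrid[i:(i + w - 1L), j:(j + w - 1L)])
      if (s > best) { best <- s; bestRow <- i; bestCol <- j }
    }
  }
  list(score = best, row = bestRow, col = bestCol)
}

#' Full synergy summary for one combination-cell line pair
#'
#' Composes the four synergy scores (Bliss and HSA, each at matrix and
#' window level), the winning window locations and the combination Emax into
#' one [SynergyResult-class] record.
#'
#' @param matrix Combination inhibition matrix (numeric or
#'   [CombinationMatrix-class]).
#' @param marginalsA,marginalsB Single-agent inhibition vectors.
#' @param windowSize Sliding-window edge length (default 3).
#' @param statistic Matrix-score statistic, `"mean"` or `"max"`.
#' @return A [SynergyResult-class] object.
#' @examples
#' eA <- logistic2p(doseGrid(7), 0.5, 1.5); eB <- logistic2p(doseGrid(7), 2, 1)
#' m <- outer(eA, eB, blissExpected)
#' synergySummary(m, eA, eB)  # all scores ~0
#' @export
synergySummary <- function(matrix, marginalsA, marginalsB, windowSize = 3L,
                           statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  grid <- if (is(matrix, "CombinationMatrix")) inhibitionGrid(matrix)
          else matrix
  bliss <- perWellExcess(grid, marginalsA, marginalsB, "bliss")
  hsa <- perWellExcess(grid, marginalsA, marginalsB, "hsa")
  bw <- windowScore(bliss, windowSize)
  hw <- windowScore(hsa, windowSize)
  new("SynergyResult",
      blissMatrix = matrixScore(bliss, statistic),
      blissWindow = bw$score,
      hsaMatrix = matrixScore(hsa, statistic),
      hsaWindow = hw$score,
      blissWindowLoc = c(bw$row, bw$col),
      hsaWindowLoc = c(hw$row, hw$col),
      comboEmax = comboEmax(grid))
}
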