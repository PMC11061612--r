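# Plate-level quality control: CV, Z-factor, negative-control ratio and
# replicate-consistency checks for matrix screens run in 1536-well plates
# with dedicated control populations (untreated NC0, DMSO NC1, cytotoxic
# positive controls PC1/PC2, cell-free blanks B).

#' Coefficient of variation of control wells
#'
#' `cv = sd / mean`, with the sample (n-1) standard deviation. Screens gate
#' plates on the CV of the DMSO-treated negative controls (default threshold
#' 0.18).
#'
#' @param values Numeric vector of control-well signals (>= 2 values).
#' @return The coefficient of variation (dimensionless).
#' @examples
#' coefficientOfVariation(c(90, 100, 110))
#' @export
coefficientOfVariation <- function(values) {
  if (length(values) < 2) inputError("coefficientOfVariation needs >= 2 values")
  m <- mean(values)
  if (m == 0) inputError("CV undefined: mean of values is zero")
  stats::sd(values) / m
}

#' Z-factor assay-quality statistic
#'
#' `Z = 1 - 3 * (sd(pos) + sd(neg)) / (mean(neg) - mean(pos))`, measuring
#' the separation between negative (high signal) and positive (low signal)
#' control populations. Z = 1 for perfectly separated, noiseless controls;
#' plates are typically required to exceed 0.3.
#'
#' @param negValues,posValues Numeric vectors of negative / positive control
#'   signals (each >= 2 values, distinct means).
#' @return The Z-factor (dimensionless, <= 1).
#' @examples
#' zFactor(rnorm(50, 1000, 50), rnorm(32, 100, 30))
#' @export
zFactor <- function(negValues, posValues) {
  if (length(negValues) < 2 || length(posValues) < 2)
    inputError("zFactor needs >= 2 values in each control group")
  muN <- mean(negValues); muP <- mean(posValues)
  if (muN == muP)
    inputError("zFactor degenerate: control means are equal")
  1 - 3 * (stats::sd(posValues) + stats::sd(negValues)) / (muN - muP)
}

#' Quality-control thresholds
#'
#' Named defaults for [qcPlate()]: CV of DMSO controls below `cvMax`;
#' untreated/DMSO mean ratio inside `[ncRatioMin, ncRatioMax]`; Z-factor at
#' least `zMin` for every positive control to which the line is sensitive
#' (negative/positive mean-signal ratio at least `pcSensitivityRatio`).
#' Lines flagged as weakly separating may use the relaxed bound `zMinRelaxed`.
#'
#' @param cvMax CV upper bound (default 0.18).
#' @param ncRatioMin,ncRatioMax NC-0/NC-1 ratio band (default 0.8-1.2).
#' @param zMin Z-factor lower bound (default 0.3).
#' @param zMinRelaxed Relaxed Z bound for flagged lines (default 0.2).
#' @param pcSensitivityRatio NC-1/PC mean ratio above which the Z check
#'   applies (default 4).
#' @return Named list of thresholds.
#' @export
qcThresholds <- function(cvMax = 0.18, ncRatioMin = 0.8, ncRatioMax = 1.2,
                         zMin = 0.3, zMinRelaxed = 0.2,
                         pcSensitivityRatio = 4) {
  list(cvMax = cvMax, ncRatioMin = ncRatioMin, ncRatioMax = ncRatioMax,
       zMin = zMin, zMinRelaxed = zMinRelaxed,
       pcSensitivityRatio = pcSensitivityRatio)
}

#' Quality-control verdict for one assay plate
#'
#' Applies the plate gates: CV of the DMSO negative controls (NC1) below the
#' threshold; mean untreated / mean DMSO ratio (NC-0/NC-1) within the band;
#' and, for each positive-control class (PC1, PC2 and the blanks B) to which
#' the cell line is sensitive (NC-1/PC mean ratio >= 4), Z-factor at least
#' the bound. Insensitive positive controls are skipped, not failed.
#'
#' @param plateWells Data frame with at least `well_class` and `raw_signal`
#'   columns, containing classes `NC0`, `NC1`, `PC1`, `PC2`, `B`.
#' @param thresholds A [qcThresholds()] list.
#' @param relaxedZ Use the relaxed Z bound (for the small fraction of lines
#'   with intrinsically weak positive-control separation).
#' @return A [QCReport-class] object.
#' @export
qcPlate <- function(plateWells, thresholds = qcThresholds(),
                    relaxedZ = FALSE) {
  needed <- c("NC0", "NC1", "PC1", "PC2", "B")
  missing <- setdiff(needed, unique(plateWells$well_class))
  if (length(missing))
    inputError("plate is missing control class(es): ",
               paste(missing, collapse = ", "))
  sig <- function(cls) plateWells$raw_signal[plateWells$well_class == cls]
  plate <- if ("plate" %in% names(plateWells))
    as.character(plateWells$plate[1]) else NA_character_

  cv <- coefficientOfVariation(sig("NC1"))
  ncRatio <- mean(sig("NC0")) / mean(sig("NC1"))
  zBound <- if (relaxedZ) thresholds$zMinRelaxed else thresholds$zMin

  reasons <- character()
  if (!(cv < thresholds$cvMax)) reasons <- c(reasons, "cv")
  if (ncRatio < thresholds$ncRatioMin || ncRatio > thresholds$ncRatioMax)
    reasons <- c(reasons, "nc_ratio")

  zs <- c(PC1 = NA_real_, PC2 = NA_real_, B = NA_real_)
  applicable <- c(PC1 = FALSE, PC2 = FALSE, B = FALSE)
  for (pc in names(zs)) {
    pcSig <- sig(pc)
    zs[[pc]] <- zFactor(sig("NC1"), pcSig)
    applicable[[pc]] <-
      mean(sig("NC1")) / mean(pcSig) >= thresholds$pcSensitivityRatio
    if (applicable[[pc]] && !(zs[[pc]] >= zBound))
      reasons <- c(reasons, paste0("z_factor:", pc))
  }

  new("QCReport", plate = plate, cv = cv, ncRatio = ncRatio, zFactors = zs,
      zApplicable = applicable, pass = length(reasons) == 0,
      reasons = reasons)
}

#' Quality control across all plates of a screen
#'
#' @param wells Long-format well table (see [readScreen()]).
#' @param thresholds A [qcThresholds()] list.
#' @return Data frame with one row per plate: `plate`, `cv`, `nc_ratio`,
#'   `z_pc1`, `z_pc2`, `z_b`, `pass`, `reasons` (semicolon-separated).
#' @export
qcScreen <- function(wells, thresholds = qcThresholds()) {
  ctl <- wells[wells$well_class %in% c("NC0", "NC1", "PC1", "PC2", "B"), ]
  plates <- sort(unique(as.character(ctl$plate)))
  rows <- lapply(plates, function(p) {
    rep <- qcPlate(ctl[ctl$plate == p, ], thresholds)
    data.frame(plate = p, cv = rep@cv, nc_ratio = rep@ncRatio,
               z_pc1 = rep@zFactors[["PC1"]], z_pc2 = rep@zFactors[["PC2"]],
               z_b = rep@zFactors[["B"]], pass = rep@pass,
               reasons = paste(rep@reasons, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Replicate-consistency screen for drug failures
#'
#' Cell lines screened in replicate expose systematic dosing errors: a dose
#' point is flagged when the replicate range (max - min response) exceeds a
#' tolerance, and a drug fails QC when flagged at two or more dose points in
#' one cell line, or flagged in two or more replicate cell lines. The
#' numeric rule behind "significant inconsistency" is a tolerance on the
#' replicate range; the tolerance is configurable.
#'
#' @param replicates Data frame with columns `drug`, `cell_line`,
#'   `dose_index`, `response`, one row per replicate measurement; every
#'   (drug, cell line, dose) group needs >= 2 replicates.
#' @param tolerance Maximum allowed replicate range on the inhibition scale
#'   (default 0.3).
#' @return Data frame with one row per drug: counts of flagged dose points
#'   and flagged lines, the overall `fail` verdict, and `replicate_cor`, the
#'   mean pairwise Pearson correlation between replicate response profiles.
#' @export
replicateConsistency <- function(replicates, tolerance = 0.3) {
  req <- c("drug", "cell_line", "dose_index", "response")
  if (!all(req %in% names(replicates)))
    inputError("replicates must have columns ",
               paste(req, collapse = ", "))
  grp <- interaction(replicates$drug, replicates$cell_line,
                     replicates$dose_index, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes < 2))
    inputError("every (drug, cell_line, dose) group needs >= 2 replicates")

  agg <- stats::aggregate(response ~ drug + cell_line + dose_index,
                          data = replicates,
                          FUN = function(x) max(x) - min(x))
  agg$flag <- agg$response > tolerance

  drugs <- sort(unique(as.character(replicates$drug)))
  rows <- lapply(drugs, function(d) {
    a <- agg[agg$drug == d, ]
    perLine <- tapply(a$flag, as.character(a$cell_line), sum)
    nFlaggedLines <- sum(perLine >= 1)
    fail <- any(perLine >= 2) || nFlaggedLines >= 2

    # mean pairwise correlation across replicate profiles
    r <- replicates[replicates$drug == d, ]
    r$rep <- stats::ave(seq_len(nrow(r)),
                        interaction(r$cell_line, r$dose_index, drop = TRUE),
                        FUN = seq_along)
    wide <- stats::reshape(
      r[, c("cell_line", "dose_index", "rep", "response")],
      idvar = c("cell_line", "dose_index"), timevar = "rep",
      direction = "wide")
    mat <- as.matrix(wide[, grep("^response\\.", names(wide)), drop = FALSE])
    cors <- c()
    if (ncol(mat) >= 2) {
      for (i in seq_len(ncol(mat) - 1)) for (j in seq((i + 1), ncol(mat))) {
        ok <- stats::complete.cases(mat[, c(i, j)])
        if (sum(ok) >= 3) {
          v1 <- mat[ok, i]; v2 <- mat[ok, j]
          cors <- c(cors, if (stats::sd(v1) == 0 && stats::sd(v2) == 0 &&
                              all(v1 == v2)) 1
                    else suppressWarnings(stats::cor(v1, v2)))
        }
      }
    }
    data.frame(drug = d, n_flagged_doses = sum(a$flag),
               n_flagged_lines = nFlaggedLines, fail = fail,
               replicate_cor = if (length(cors)) mean(cors, na.rm = TRUE)
                               else NA_real_)
  })
  do.call(rbind, rows)
}
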