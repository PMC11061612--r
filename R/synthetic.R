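# Synthetic combination-screen generator: dose matrices with Bliss-additive
# baselines and planted localized synergy windows, per-plate control
# populations, binary multi-omics features with planted single-agent-driven
# and emergent response associations, and the ground truth needed for
# recovery testing.

#' Configuration of a synthetic combination screen
#'
#' Collects the generator parameters: panel and design sizes, the dose grid
#' (7 log-spaced doses over a 1,000-fold range by default), well-level
#' Gaussian noise, the synergy-window planting scheme, the binary feature
#' matrix, and the planted biomarker effects. One global seed expands to
#' per-entity substreams via a counter-based hash, so adding cell lines or
#' combinations never perturbs entities already generated.
#'
#' @param nCellLines Number of cell lines (default 120; 12 per cancer type, so the 10-cell-line prioritization minimum is meaningful).
#' @param nCancerTypes Number of cancer types, assigned round-robin
#'   (default 10; the first ~30 percent are labelled hematological).
#' @param nCombinations Number of drug combinations (default 12, cycling
#'   through the nine mechanism categories).
#' @param nDoses Doses per drug (default 7).
#' @param doseFoldRange Ratio of highest to lowest dose (default 1000).
#' @param topDose Highest dose, arbitrary units (default 10).
#' @param noiseSd Gaussian well noise on the inhibition scale (default
#'   0.05). Production screens do not publish their well-level noise; this
#'   is a free parameter.
#' @param synergyFraction Fraction of combination-cell line pairs given a
#'   planted synergy window, within sensitive cancer types (default 0.25).
#' @param typeSelectivity Fraction of cancer types in which a combination's
#'   synergy mechanism is operative (default 0.4): windows are planted only
#'   in pairs whose cancer type is drawn sensitive for that combination,
#'   giving combinations the cancer-type-selective activity a screen's
#'   prioritization stage is built to detect. Set to 1 to plant windows
#'   irrespective of cancer type.
#' @param drugSensitiveFraction Fraction of cell lines in which a drug is
#'   potent (default 0.3), emulating the genotype-restricted response of
#'   targeted agents: in sensitive lines the IC50 falls inside the tested
#'   dose range, elsewhere well above it (weak residual activity). Set to 1
#'   to make every drug potent everywhere.
#' @param synergyBoost Added inhibition inside a planted window (default
#'   0.3; the noiseless truth is clipped at 1).
#' @param windowSize Planted window edge length (default 3).
#' @param nFeatures Number of binary features (default 40).
#' @param featurePrevalence Range of per-feature positive prevalence
#'   (default `c(0.1, 0.4)`).
#' @param plantedSingleAgentEffects List of `list(feature=, drug=, effect=)`
#'   entries; `effect` is in units of the affected metric's noise SD.
#' @param plantedEmergentEffects List of `list(feature=, combo=, effect=)`
#'   entries shifting only combination metrics, never single-agent Emax.
#' @param controls Control-well counts, means and SDs per plate; defaults
#'   mimic a 1536-well screen (155 untreated + 155 DMSO negatives, 32
#'   positive-control wells split over two cytotoxic agents, 28 blanks,
#'   negative-control CV ~0.123 and Z-factor ~0.5).
#' @param seed Global seed (default 1).
#' @return Validated config list of class `screenConfig`.
#' @export
screenConfig <- function(nCellLines = 120, nCancerTypes = 10,
                         nCombinations = 12, nDoses = 7,
                         doseFoldRange = 1000, topDose = 10,
                         noiseSd = 0.05, synergyFraction = 0.25,
                         typeSelectivity = 0.4,
                         drugSensitiveFraction = 0.3,
                         synergyBoost = 0.3, windowSize = 3,
                         nFeatures = 40, featurePrevalence = c(0.1, 0.4),
                         plantedSingleAgentEffects = list(),
                         plantedEmergentEffects = list(),
                         controls = list(
                           nNc0 = 155, nNc1 = 155, nPc = 32, nBlank = 28,
                           means = c(NC0 = 1000, NC1 = 1000, PC1 = 100,
                                     PC2 = 120, B = 10),
                           sds = c(NC0 = 122.8, NC1 = 122.8, PC1 = 27.8,
                                   PC2 = 27.8, B = 5)),
                         seed = 1) {
  if (nDoses < 2) inputError("nDoses must be >= 2")
  if (doseFoldRange <= 1) inputError("doseFoldRange must be > 1")
  if (noiseSd < 0) inputError("noiseSd must be >= 0")
  if (synergyFraction < 0 || synergyFraction > 1)
    inputError("synergyFraction must lie in [0, 1]")
  if (typeSelectivity < 0 || typeSelectivity > 1)
    inputError("typeSelectivity must lie in [0, 1]")
  if (drugSensitiveFraction < 0 || drugSensitiveFraction > 1)
    inputError("drugSensitiveFraction must lie in [0, 1]")
  if (windowSize > nDoses) inputError("windowSize must not exceed nDoses")
  cfg <- list(nCellLines = nCellLines, nCancerTypes = nCancerTypes,
              nCombinations = nCombinations, nDoses = nDoses,
              doseFoldRange = doseFoldRange, topDose = topDose,
              noiseSd = noiseSd, synergyFraction = synergyFraction,
              typeSelectivity = typeSelectivity,
              drugSensitiveFraction = drugSensitiveFraction,
              synergyBoost = synergyBoost, windowSize = windowSize,
              nFeatures = nFeatures, featurePrevalence = featurePrevalence,
              plantedSingleAgentEffects = plantedSingleAgentEffects,
              plantedEmergentEffects = plantedEmergentEffects,
              controls = controls, seed = seed)
  class(cfg) <- "screenConfig"
  cfg
}

# Pathway classes and the nine mechanism categories (chemo+chemo pairs are
# not screened, matching combination-portfolio practice).
.pathwayClasses <- c("CD", "DDR", "CS", "chemo")
.categoryPairs <- list(
  c("CD", "CD"), c("CD", "DDR"), c("CD", "CS"), c("CD", "chemo"),
  c("DDR", "DDR"), c("DDR", "CS"), c("DDR", "chemo"),
  c("CS", "CS"), c("CS", "chemo"))

#' Deterministic screen design: drugs, combinations, cell lines
#'
#' Builds the drug library (three drugs per pathway class), the combination
#' list (cycling through the nine mechanism categories), and the annotated
#' cell line panel for a [screenConfig()].
#'
#' @param config A [screenConfig()] list.
#' @return List with data frames `drugs` (`drug`, `pathway`), `combos`
#'   (`combo_id`, `drug_A`, `drug_B`, `class_A`, `class_B`, `category`) and
#'   `cellLines` (`cell_line`, `cancer_type`, `group`, `plate`).
#' @export
screenDesign <- function(config) {
  drugs <- data.frame(
    drug = sprintf("D%02d", seq_len(3 * length(.pathwayClasses))),
    pathway = rep(.pathwayClasses, each = 3))
  byClass <- split(drugs$drug, drugs$pathway)
  counters <- stats::setNames(rep(0L, length(.pathwayClasses)),
                              .pathwayClasses)
  pick <- function(cls, avoid = NULL) {
    pool <- setdiff(byClass[[cls]], avoid)
    counters[[cls]] <<- counters[[cls]] + 1L
    pool[(counters[[cls]] - 1L) %% length(pool) + 1L]
  }
  rows <- lapply(seq_len(config$nCombinations), function(i) {
    cat <- .categoryPairs[[(i - 1L) %% length(.categoryPairs) + 1L]]
    a <- pick(cat[1])
    b <- pick(cat[2], avoid = a)
    data.frame(combo_id = sprintf("C%02d", i), drug_A = a, drug_B = b,
               class_A = cat[1], class_B = cat[2],
               category = paste(sort(cat), collapse = "+"))
  })
  combos <- do.call(rbind, rows)

  nT <- config$nCancerTypes
  types <- sprintf("T%02d", seq_len(nT))
  heme <- types[seq_len(max(1L, round(0.3 * nT)))]
  i <- seq_len(config$nCellLines)
  cellLines <- data.frame(
    cell_line = sprintf("CL%03d", i),
    cancer_type = types[(i - 1L) %% nT + 1L],
    plate = sprintf("P%03d", i))
  cellLines$group <- ifelse(cellLines$cancer_type %in% heme, "heme", "solid")
  list(drugs = drugs, combos = combos, cellLines = cellLines)
}

#' Simulate one single-agent dose-response curve
#'
#' The noiseless truth is the two-parameter logistic with asymptotes 0 and 1
#' evaluated at each dose; i.i.d. Gaussian noise is added on the inhibition
#' scale (not clipped, so downstream normalization and fitting see realistic
#' out-of-range values).
#'
#' @param trueIc50 True half-maximal dose (positive).
#' @param trueSlope True shape parameter (positive).
#' @param doses Strictly increasing positive dose vector.
#' @param noiseSd Gaussian noise SD (default 0).
#' @param seed Optional seed making the draw reproducible.
#' @return List with `doses`, `trueIc50`, `trueSlope`, `truth` (noiseless
#'   inhibition) and `inhibition` (noisy).
#' @export
simulateSingleAgentCurve <- function(trueIc50, trueSlope, doses,
                                     noiseSd = 0, seed = NULL) {
  if (any(doses <= 0)) inputError("doses must be positive")
  if (any(diff(doses) <= 0)) inputError("doses must be strictly increasing")
  truth <- logistic2p(doses, trueIc50, trueSlope)
  noise <- if (noiseSd > 0) {
    if (!is.null(seed)) withSeed(seed, stats::rnorm(length(doses), 0, noiseSd))
    else stats::rnorm(length(doses), 0, noiseSd)
  } else rep(0, length(doses))
  list(doses = doses, trueIc50 = trueIc50, trueSlope = trueSlope,
       truth = truth, inhibition = truth + noise)
}

#' Simulate one combination dose matrix
#'
#' The noiseless well `(i, j)` is the Bliss-additive expectation of the two
#' curves' noiseless truths, `EA(i) + EB(j) - EA(i)*EB(j)`, plus
#' `window$boost` inside the planted window (truth clipped at 1), plus
#' i.i.d. Gaussian well noise.
#'
#' @param curveA,curveB Curves from [simulateSingleAgentCurve()] (or any
#'   list with `doses` and `truth`); must share the number of doses.
#' @param window Optional `list(row=, col=, size=, boost=)`, `row`/`col` the
#'   1-based top-left corner; must fit inside the matrix.
#' @param noiseSd Gaussian well-noise SD (default 0).
#' @param seed Optional seed.
#' @param ... Identifiers passed to [CombinationMatrix()] (`drugA`, `drugB`,
#'   `cellLine`, `plate`).
#' @return A [CombinationMatrix-class] with the (noisy) inhibition grid.
#' @export
simulateCombinationMatrix <- function(curveA, curveB, window = NULL,
                                      noiseSd = 0, seed = NULL, ...) {
  tA <- if (!is.null(curveA$truth)) curveA$truth else curveA$inhibition
  tB <- if (!is.null(curveB$truth)) curveB$truth else curveB$inhibition
  if (length(tA) != length(tB))
    inputError("curves must share the number of doses")
  k <- length(tA)
  truth <- outer(tA, tB, function(a, b) a + b - a * b)
  if (!is.null(window)) {
    w <- window$size
    if (window$row < 1 || window$col < 1 ||
        window$row + w - 1 > k || window$col + w - 1 > k)
      inputError("planted window falls outside the matrix")
    ri <- window$row:(window$row + w - 1)
    ci <- window$col:(window$col + w - 1)
    truth[ri, ci] <- truth[ri, ci] + window$boost
  }
  truth <- pmin(truth, 1)
  noise <- if (noiseSd > 0) {
    draw <- function() matrix(stats::rnorm(k * k, 0, noiseSd), k, k)
    if (!is.null(seed)) withSeed(seed, draw()) else draw()
  } else 0
  CombinationMatrix(truth + noise, curveA$doses, curveB$doses, ...)
}

#' Simulate one plate's control-well populations
#'
#' Draws Gaussian signals for the untreated (NC0) and DMSO (NC1) negative
#' controls, the two positive-control classes (PC1/PC2, the positive-control
#' count split evenly), and the cell-free blanks (B).
#'
#' @param nNc0,nNc1,nPc,nBlank Well counts per class (positive; defaults
#'   155 / 155 / 32 / 28).
#' @param means,sds Named vectors (`NC0`, `NC1`, `PC1`, `PC2`, `B`) of class
#'   means and SDs; SDs must be non-negative.
#' @param seed Optional seed.
#' @param plate Plate identifier attached to the rows.
#' @return Data frame `plate`, `well_class`, `raw_signal`.
#' @export
generatePlateControls <- function(nNc0 = 155, nNc1 = 155, nPc = 32,
                                  nBlank = 28,
                                  means = c(NC0 = 1000, NC1 = 1000,
                                            PC1 = 100, PC2 = 120, B = 10),
                                  sds = c(NC0 = 122.8, NC1 = 122.8,
                                          PC1 = 27.8, PC2 = 27.8, B = 5),
                                  seed = NULL, plate = NA_character_) {
  counts <- c(NC0 = nNc0, NC1 = nNc1, PC1 = ceiling(nPc / 2),
              PC2 = floor(nPc / 2), B = nBlank)
  if (any(counts <= 0)) inputError("control-well counts must be positive")
  if (any(sds < 0)) inputError("control SDs must be non-negative")
  draw <- function() {
    cls <- rep(names(counts), counts)
    data.frame(plate = plate, well_class = cls,
               raw_signal = stats::rnorm(length(cls), means[cls], sds[cls]))
  }
  if (!is.null(seed)) withSeed(seed, draw()) else draw()
}

#' Generate the binary feature matrix and biomarker ground truth
#'
#' Draws independent Bernoulli features per cell line (per-feature
#' prevalence uniform over the configured range) and validates the planted
#' single-agent and emergent effects against the screen design. The planted
#' effects are returned as ground truth; they are applied to responses by
#' [simulateResponseTable()] (metric level) or [simulateScreen()] (well
#' level).
#'
#' @param config A [screenConfig()] list.
#' @param design Optional [screenDesign()] (recomputed when absent).
#' @return List with `features` (binary cell line x feature matrix) and
#'   `effects` (data frame `feature`, `type`, `target`, `effect`).
#' @export
generateFeatureMatrix <- function(config, design = screenDesign(config)) {
  lines <- design$cellLines$cell_line
  featNames <- sprintf("F%03d", seq_len(config$nFeatures))
  cols <- lapply(seq_len(config$nFeatures), function(j) {
    withSeed(substreamSeed(config$seed, "feature", featNames[j]), {
      prev <- stats::runif(1, config$featurePrevalence[1],
                           config$featurePrevalence[2])
      stats::rbinom(length(lines), 1, prev)
    })
  })
  features <- do.call(cbind, cols)
  dimnames(features) <- list(lines, featNames)

  effects <- data.frame(feature = character(), type = character(),
                        target = character(), effect = numeric())
  addEffect <- function(e, type, targetField, validTargets) {
    if (!e$feature %in% featNames)
      inputError("planted effect references unknown feature: ", e$feature)
    if (!e[[targetField]] %in% validTargets)
      inputError("planted effect references unknown ", targetField, ": ",
                 e[[targetField]])
    data.frame(feature = e$feature, type = type, target = e[[targetField]],
               effect = e$effect)
  }
  for (e in config$plantedSingleAgentEffects)
    effects <- rbind(effects,
                     addEffect(e, "single_agent", "drug", design$drugs$drug))
  for (e in config$plantedEmergentEffects)
    effects <- rbind(effects,
                     addEffect(e, "emergent", "combo",
                               design$combos$combo_id))
  if (nrow(effects) > config$nFeatures)
    inputError("more planted effects than features")
  list(features = features, effects = effects)
}

# Sample a planted-window location. Synergy on the inhibition scale can
# only be expressed where the additive baseline has headroom: if any well
# of the window saturates, the clipped boost shifts the noiseless excess
# argmax off the planted corner and the location is no longer recoverable
# even in principle. Locations are therefore drawn uniformly among corners
# where every well leaves room for the full boost (fallback: the corner
# with the lowest window-mean baseline).
.sampleWindowLocation <- function(baseline, w, boost) {
  k <- nrow(baseline)
  corners <- expand.grid(row = seq_len(k - w + 1), col = seq_len(k - w + 1))
  wstat <- mapply(function(i, j) {
    win <- baseline[i:(i + w - 1), j:(j + w - 1)]
    c(max = max(win), mean = mean(win))
  }, corners$row, corners$col)
  feasible <- which(wstat["max", ] <= 1 - boost)
  pick <- if (length(feasible)) feasible[sample.int(length(feasible), 1)]
          else which.min(wstat["mean", ])
  c(row = corners$row[pick], col = corners$col[pick])
}

#' Simulate a full well-level combination screen
#'
#' Generates, per cell line (one assay plate each): the plate's control
#' populations; single-agent dose-response wells for every drug (random
#' IC50 log-uniform over the central dose range, slope uniform on
#' `[0.8, 2.5]`, shifted upward for cell lines positive for a planted
#' single-agent biomarker); and every combination's dose matrix, built as
#' the Bliss-additive baseline of the two single-agent truths plus a planted
#' synergy window for a `synergyFraction` of pairs and a whole-matrix shift
#' for planted emergent biomarkers, with Gaussian well noise throughout.
#' Raw signals are obtained by inverting the growth-inhibition
#' normalization against the configured control means.
#'
#' @param config A [screenConfig()] list.
#' @return A [SyntheticScreen-class] object.
#' @export
simulateScreen <- function(config) {
  stopifnot(inherits(config, "screenConfig"))
  design <- screenDesign(config)
  fm <- generateFeatureMatrix(config, design)
  doses <- doseGrid(config$nDoses, config$doseFoldRange, config$topDose)
  k <- config$nDoses
  muN <- config$controls$means[["NC1"]]
  muB <- config$controls$means[["B"]]
  toRaw <- function(inh) muN - inh * (muN - muB)

  saEffects <- fm$effects[fm$effects$type == "single_agent", , drop = FALSE]
  emEffects <- fm$effects[fm$effects$type == "emergent", , drop = FALSE]

  lineBlocks <- vector("list", config$nCellLines)
  curveRows <- vector("list", config$nCellLines)
  windowRows <- vector("list", config$nCellLines)

  for (li in seq_len(config$nCellLines)) {
    cl <- design$cellLines$cell_line[li]
    plate <- design$cellLines$plate[li]

    ctl <- generatePlateControls(
      nNc0 = config$controls$nNc0, nNc1 = config$controls$nNc1,
      nPc = config$controls$nPc, nBlank = config$controls$nBlank,
      means = config$controls$means, sds = config$controls$sds,
      seed = substreamSeed(config$seed, "controls", plate), plate = plate)
    ctl$cell_line <- cl
    ctl$drug_A <- NA_character_; ctl$drug_B <- NA_character_
    ctl$dose_index_A <- NA_integer_; ctl$dose_index_B <- NA_integer_
    ctl$conc_A <- NA_real_; ctl$conc_B <- NA_real_

    # single-agent truth curves per drug (with planted biomarker shifts)
    truths <- list(); noisy <- list(); crows <- list()
    for (di in seq_len(nrow(design$drugs))) {
      drug <- design$drugs$drug[di]
      # each drug is potent in a sensitive minority of lines (IC50 inside
      # the tested range) and weak elsewhere (IC50 1-2 decades above the
      # top dose), giving the wide spread of maximal effects and the
      # line-restricted activity of targeted agents
      s <- substreamSeed(config$seed, "curve", cl, drug)
      par <- withSeed(s, {
        sensitive <- stats::runif(1) < config$drugSensitiveFraction
        ic50 <- if (sensitive)
          10^stats::runif(1, log10(doses[2]), log10(doses[k - 1]))
        else
          10^stats::runif(1, log10(doses[k] * 10), log10(doses[k] * 100))
        c(ic50 = ic50, slope = stats::runif(1, 0.8, 2.5))
      })
      truth <- logistic2p(doses, par[["ic50"]], par[["slope"]])
      shift <- saEffects[saEffects$target == drug &
                           fm$features[cl, saEffects$feature] == 1, ,
                         drop = FALSE]
      if (nrow(shift))
        truth <- pmin(1, truth + sum(shift$effect) * config$noiseSd)
      noise <- withSeed(substreamSeed(config$seed, "sawell", cl, drug),
                        stats::rnorm(k, 0, config$noiseSd))
      truths[[drug]] <- truth
      noisy[[drug]] <- truth + noise
      crows[[di]] <- data.frame(cell_line = cl, drug = drug,
                                ic50 = par[["ic50"]], slope = par[["slope"]])
    }
    curveRows[[li]] <- do.call(rbind, crows)

    sa <- data.frame(
      plate = plate, well_class = "SA_A",
      cell_line = cl,
      drug_A = rep(design$drugs$drug, each = k),
      drug_B = NA_character_,
      dose_index_A = rep(seq_len(k), nrow(design$drugs)),
      dose_index_B = NA_integer_,
      conc_A = rep(doses, nrow(design$drugs)),
      conc_B = NA_real_,
      raw_signal = toRaw(unlist(noisy[design$drugs$drug])))

    # combination matrices
    cblocks <- vector("list", nrow(design$combos))
    wrows <- vector("list", nrow(design$combos))
    for (ci in seq_len(nrow(design$combos))) {
      combo <- design$combos$combo_id[ci]
      dA <- design$combos$drug_A[ci]; dB <- design$combos$drug_B[ci]
      tA <- truths[[dA]]; tB <- truths[[dB]]
      baseline <- outer(tA, tB, function(a, b) a + b - a * b)

      # a combination is only synergy-capable in cancer types drawn
      # sensitive for it (keyed by combo x type, so panel growth does not
      # reshuffle sensitivity)
      ctype <- design$cellLines$cancer_type[li]
      typeSensitive <- withSeed(
        substreamSeed(config$seed, "typegate", combo, ctype),
        stats::runif(1) < config$typeSelectivity)
      ws <- substreamSeed(config$seed, "window", cl, combo)
      window <- withSeed(ws, {
        if (typeSensitive && stats::runif(1) < config$synergyFraction) {
          loc <- .sampleWindowLocation(baseline, config$windowSize,
                                       config$synergyBoost)
          list(row = loc[["row"]], col = loc[["col"]],
               size = config$windowSize, boost = config$synergyBoost)
        } else NULL
      })
      truth <- baseline
      if (!is.null(window)) {
        ri <- window$row:(window$row + window$size - 1)
        cj <- window$col:(window$col + window$size - 1)
        truth[ri, cj] <- truth[ri, cj] + window$boost
      }
      eshift <- emEffects[emEffects$target == combo &
                            fm$features[cl, emEffects$feature] == 1, ,
                          drop = FALSE]
      if (nrow(eshift))
        truth <- truth + sum(eshift$effect) * config$noiseSd
      truth <- pmin(truth, 1)
      noise <- withSeed(substreamSeed(config$seed, "matrix", cl, combo),
                        matrix(stats::rnorm(k * k, 0, config$noiseSd), k, k))
      grid <- truth + noise

      cblocks[[ci]] <- data.frame(
        plate = plate, well_class = "COMBO", cell_line = cl,
        drug_A = dA, drug_B = dB,
        dose_index_A = rep(seq_len(k), k),
        dose_index_B = rep(seq_len(k), each = k),
        conc_A = rep(doses, k),
        conc_B = rep(doses, each = k),
        raw_signal = toRaw(as.vector(grid)))
      wrows[[ci]] <- data.frame(
        cell_line = cl, combo_id = combo,
        has_window = !is.null(window),
        row = if (is.null(window)) NA_integer_ else window$row,
        col = if (is.null(window)) NA_integer_ else window$col,
        size = if (is.null(window)) NA_integer_ else window$size,
        boost = if (is.null(window)) NA_real_ else window$boost)
    }
    windowRows[[li]] <- do.call(rbind, wrows)

    block <- rbind(ctl[, names(sa)], sa, do.call(rbind, cblocks))
    block$well <- sprintf("W%04d", seq_len(nrow(block)))
    lineBlocks[[li]] <- block
  }

  wells <- do.call(rbind, lineBlocks)
  rownames(wells) <- NULL
  wells <- wells[, c("plate", "well", "well_class", "cell_line", "drug_A",
                     "drug_B", "dose_index_A", "dose_index_B", "conc_A",
                     "conc_B", "raw_signal")]

  new("SyntheticScreen", wells = wells, cellLines = design$cellLines,
      combinations = design$combos, features = fm$features,
      groundTruth = list(curves = do.call(rbind, curveRows),
                         windows = do.call(rbind, windowRows),
                         effects = fm$effects),
      config = unclass(config))
}

#' Simulate a response-metric table directly
#'
#' Distributional shortcut past the well level: draws the per
#' (combination, cell line) response metrics from Gaussian baselines and
#' applies the planted biomarker effects, in units of each metric's own
#' noise SD (single-agent effects shift the drug's Emax and, as
#' monotherapy-driven combination response, the combination Emax; emergent
#' effects shift only the combination metrics). This is the path used for
#' biomarker calibration and recovery studies, where the well-level detail
#' is irrelevant and thousands of ANOVA tests must run quickly.
#'
#' @param config A [screenConfig()] list.
#' @param sds Named noise SDs of the metric baselines: `emax` (single-agent
#'   Emax, default 0.15), `combo` (combination Emax, 0.08), `synergy`
#'   (Bliss/HSA scores, 0.05).
#' @return List with `responses` (data frame `combo_id`, `cell_line`,
#'   `emax_A`, `emax_B`, `combo_emax`, `bliss_matrix`, `bliss_window`,
#'   `hsa_matrix`, `hsa_window`), `features`, `annotations`, `design` and
#'   `groundTruth`.
#' @export
simulateResponseTable <- function(config,
                                  sds = c(emax = 0.15, combo = 0.08,
                                          synergy = 0.05)) {
  stopifnot(inherits(config, "screenConfig"))
  design <- screenDesign(config)
  fm <- generateFeatureMatrix(config, design)
  lines <- design$cellLines$cell_line

  blocks <- vector("list", nrow(design$combos))
  saEffects <- fm$effects[fm$effects$type == "single_agent", , drop = FALSE]
  emEffects <- fm$effects[fm$effects$type == "emergent", , drop = FALSE]

  for (ci in seq_len(nrow(design$combos))) {
    combo <- design$combos$combo_id[ci]
    dA <- design$combos$drug_A[ci]; dB <- design$combos$drug_B[ci]
    n <- length(lines)
    base <- withSeed(substreamSeed(config$seed, "resp", combo), {
      eA <- stats::rnorm(n, 0.45, sds[["emax"]])
      eB <- stats::rnorm(n, 0.45, sds[["emax"]])
      data.frame(
        combo_id = combo, cell_line = lines,
        emax_A = eA, emax_B = eB,
        combo_emax = pmax(eA, eB) + stats::rnorm(n, 0.05, sds[["combo"]]),
        bliss_matrix = stats::rnorm(n, 0, sds[["synergy"]]),
        bliss_window = stats::rnorm(n, 0.05, sds[["synergy"]]),
        hsa_matrix = stats::rnorm(n, 0.02, sds[["synergy"]]),
        hsa_window = stats::rnorm(n, 0.06, sds[["synergy"]]))
    })
    for (ei in seq_len(nrow(saEffects))) {
      e <- saEffects[ei, ]
      if (!e$target %in% c(dA, dB)) next
      pos <- fm$features[lines, e$feature] == 1
      col <- if (e$target == dA) "emax_A" else "emax_B"
      base[[col]][pos] <- base[[col]][pos] + e$effect * sds[["emax"]]
      base$combo_emax[pos] <- base$combo_emax[pos] + e$effect * sds[["combo"]]
    }
    for (ei in seq_len(nrow(emEffects))) {
      e <- emEffects[ei, ]
      if (e$target != combo) next
      pos <- fm$features[lines, e$feature] == 1
      d <- e$effect
      base$combo_emax[pos] <- base$combo_emax[pos] + d * sds[["combo"]]
      base$bliss_matrix[pos] <- base$bliss_matrix[pos] + d * sds[["synergy"]]
      base$bliss_window[pos] <- base$bliss_window[pos] + d * sds[["synergy"]]
      base$hsa_matrix[pos] <- base$hsa_matrix[pos] + d * sds[["synergy"]]
      base$hsa_window[pos] <- base$hsa_window[pos] + d * sds[["synergy"]]
    }
    blocks[[ci]] <- base
  }
  responses <- do.call(rbind, blocks)
  rownames(responses) <- NULL
  list(responses = responses, features = fm$features,
       annotations = design$cellLines, design = design,
       groundTruth = list(effects = fm$effects))
}
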