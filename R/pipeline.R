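# Pipeline driver: normalization, per-pair response/synergy scoring, and
# the end-to-end run (simulate -> qc -> fit -> synergy -> prioritize ->
# biomarkers -> enrich) with file artifacts and a run manifest.

#' Normalize a well table to the inhibition scale
#'
#' Adds an `inhibition` column to every treatment well using each plate's
#' own control means: 0 at the mean DMSO (NC1) signal, 1 at the mean blank
#' (B) signal. Values are not clipped.
#'
#' @param wells Well data frame (see [readScreen()]).
#' @return The well table with an `inhibition` column (NA for control
#'   wells).
#' @export
normalizeScreen <- function(wells) {
  nc1 <- tapply(wells$raw_signal[wells$well_class == "NC1"],
                wells$plate[wells$well_class == "NC1"], mean)
  blank <- tapply(wells$raw_signal[wells$well_class == "B"],
                  wells$plate[wells$well_class == "B"], mean)
  missing <- setdiff(unique(wells$plate), intersect(names(nc1), names(blank)))
  if (length(missing))
    inputError("plate(s) lack NC1 or B control wells: ",
               paste(missing, collapse = ", "))
  treated <- wells$well_class %in% c("COMBO", "SA_A", "SA_B")
  wells$inhibition <- NA_real_
  p <- wells$plate[treated]
  wells$inhibition[treated] <-
    (nc1[p] - wells$raw_signal[treated]) / (nc1[p] - blank[p])
  wells
}

#' Per-pair response and synergy metrics from a well table
#'
#' For every cell line passing QC: fits each drug's single-agent dose
#' response ([fitLogistic2p()]) to obtain IC50 and Emax, and scores every
#' combination matrix ([synergySummary()]) using the observed (normalized,
#' unfitted) single-agent inhibition as Bliss/HSA marginals, plus the
#' combination Emax.
#'
#' @param wells Well data frame.
#' @param combos Data frame `combo_id`, `drug_A`, `drug_B` mapping matrices
#'   to combination identifiers.
#' @param excludePlates Plates to drop (e.g. QC failures).
#' @param windowSize Sliding-window edge length (default 3).
#' @param statistic Matrix-score statistic (`"mean"` or `"max"`).
#' @return Data frame with one row per (combination, cell line):
#'   `ic50_A`, `ic50_B`, `emax_A`, `emax_B`, `combo_emax`, the four synergy
#'   scores and the Bliss window location.
#' @export
screenResponses <- function(wells, combos, excludePlates = character(),
                            windowSize = 3L,
                            statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  wells <- wells[!(wells$plate %in% excludePlates), ]
  if (!"inhibition" %in% names(wells)) wells <- normalizeScreen(wells)

  out <- list()
  for (cl in sort(unique(wells$cell_line[wells$well_class == "COMBO"]))) {
    w <- wells[wells$cell_line == cl, ]

    # observed single-agent inhibition per drug, ordered by dose index
    saA <- w[w$well_class == "SA_A", ]
    saB <- w[w$well_class == "SA_B", ]
    marginals <- list(); fits <- list(); dosesOf <- list()
    for (d in unique(c(saA$drug_A, saB$drug_B))) {
      rows <- rbind(
        data.frame(idx = saA$dose_index_A[saA$drug_A %in% d],
                   conc = saA$conc_A[saA$drug_A %in% d],
                   inh = saA$inhibition[saA$drug_A %in% d]),
        data.frame(idx = saB$dose_index_B[saB$drug_B %in% d],
                   conc = saB$conc_B[saB$drug_B %in% d],
                   inh = saB$inhibition[saB$drug_B %in% d]))
      rows <- rows[order(rows$idx), ]
      marginals[[d]] <- rows$inh
      dosesOf[[d]] <- rows$conc
      fits[[d]] <- fitLogistic2p(rows$conc, rows$inh)
    }

    cw <- w[w$well_class == "COMBO", ]
    for (ci in seq_len(nrow(combos))) {
      dA <- combos$drug_A[ci]; dB <- combos$drug_B[ci]
      m <- cw[cw$drug_A == dA & cw$drug_B == dB, ]
      if (nrow(m) == 0) next
      k <- max(m$dose_index_A)
      grid <- matrix(NA_real_, k, k)
      grid[cbind(m$dose_index_A, m$dose_index_B)] <- m$inhibition
      syn <- synergySummary(grid, marginals[[dA]], marginals[[dB]],
                            windowSize = windowSize, statistic = statistic)
      out[[length(out) + 1L]] <- cbind(
        data.frame(combo_id = combos$combo_id[ci], cell_line = cl,
                   ic50_A = fits[[dA]]@ic50, ic50_B = fits[[dB]]@ic50,
                   emax_A = fits[[dA]]@emax, emax_B = fits[[dB]]@emax),
        as.data.frame(syn))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default pipeline configuration
#'
#' Every decision threshold of the analysis is a named key: activity calls
#' (`emax_threshold` 0.5, `hsa_threshold` 0.1, `hsa_variant` "window" --
#' the activity call reads the localized HSA benefit because a 0.1
#' threshold on the whole-matrix mean excess is unattainable for
#' dose-localized synergy; set `"matrix"` for the mean-score reading),
#' prioritization (`responder_threshold` 10 percent, `breadth_cap` 0.5,
#' `min_cell_lines` 10), plate QC (`cv_max` 0.18, `z_min` 0.3,
#' `z_min_relaxed` 0.2, `nc_ratio_min` 0.8, `nc_ratio_max` 1.2), biomarkers
#' (`p_threshold` 0.001, `fdr_threshold` 0.1, `glass_threshold` 1,
#' `z_expression` 2, `min_type_size` 20), synergy (`window_size` 3,
#' `matrix_statistic` "mean"), enrichment (`n_boot` 10) and the generator
#' block (`simulate`).
#'
#' @param ... Overrides merged over the defaults (named).
#' @return Config list.
#' @export
defaultConfig <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(nCellLines = 120, nCancerTypes = 10, nCombinations = 12,
                    nDoses = 7, doseFoldRange = 1000, noiseSd = 0.05,
                    synergyFraction = 0.25, synergyBoost = 0.3,
                    windowSize = 3, nFeatures = 40),
    emax_threshold = 0.5, hsa_threshold = 0.1, hsa_variant = "window",
    responder_threshold = 10, breadth_cap = 0.5, min_cell_lines = 10,
    cv_max = 0.18, z_min = 0.3, z_min_relaxed = 0.2,
    nc_ratio_min = 0.8, nc_ratio_max = 1.2,
    p_threshold = 0.001, fdr_threshold = 0.1, glass_threshold = 1,
    z_expression = 2, min_type_size = 20, baskets = character(),
    window_size = 3, matrix_statistic = "mean", n_boot = 10)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full screen-analysis pipeline
#'
#' Executes simulate (optional) -> plate QC -> normalization and curve
#' fitting -> synergy scoring -> activity calls and prioritization ->
#' biomarker ANOVA with emergent flagging -> pathway-pair enrichment, and
#' writes every intermediate table plus a machine-readable run manifest
#' (seed, config hash, package version, per-stage row counts) to `outDir`.
#'
#' @param config A config list from [defaultConfig()], or the path of a YAML
#'   file holding one.
#' @param outDir Output directory (created if needed).
#' @param screen Optional pre-built [SyntheticScreen-class]; otherwise one
#'   is simulated from the config's `simulate` block.
#' @return Invisible list with all intermediate results (`screen`, `qc`,
#'   `responses`, `activity`, `rates`, `ranked`, `biomarkers`, `emergent`,
#'   `enrichment`, `manifest`).
#' @export
runPipeline <- function(config = defaultConfig(), outDir = tempfile("run"),
                        screen = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- defaultConfig()
  base[names(config)] <- config
  config <- base
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outFile <- function(name) file.path(outDir, name)
  writeCsv <- function(x, name) {
    utils::write.csv(x, outFile(name), row.names = FALSE, quote = FALSE)
    counts[[name]] <<- nrow(x)
  }

  # -- simulate ------------------------------------------------------------
  if (is.null(screen)) {
    sim <- config$simulate
    sim$seed <- config$seed
    screen <- do.call(screenConfig, sim)
    screen <- simulateScreen(screen)
  }
  writeScreen(screen, outFile("wells.csv"))
  counts[["wells.csv"]] <- nrow(screen@wells)
  writeMobem(screen@features, outFile("features.tsv"))
  jsonlite::write_json(screen@groundTruth, outFile("ground_truth.json"),
                       dataframe = "columns", na = "null")

  # -- qc ------------------------------------------------------------------
  thr <- qcThresholds(cvMax = config$cv_max, ncRatioMin = config$nc_ratio_min,
                      ncRatioMax = config$nc_ratio_max, zMin = config$z_min,
                      zMinRelaxed = config$z_min_relaxed)
  qc <- qcScreen(screen@wells, thr)
  writeCsv(qc, "qc.csv")
  jsonlite::write_json(
    list(n_plates = nrow(qc), n_pass = sum(qc$pass),
         n_fail = sum(!qc$pass),
         failed_plates = qc$plate[!qc$pass]),
    outFile("qc_summary.json"), auto_unbox = TRUE)

  # -- fit + synergy -------------------------------------------------------
  responses <- screenResponses(
    screen@wells, screen@combinations,
    excludePlates = qc$plate[!qc$pass],
    windowSize = config$window_size,
    statistic = config$matrix_statistic)
  writeCsv(responses, "responses.csv")

  # -- prioritize ----------------------------------------------------------
  hsaCol <- paste0("hsa_", config$hsa_variant)
  activity <- data.frame(
    combo_id = responses$combo_id, cell_line = responses$cell_line,
    combo_emax = responses$combo_emax, hsa = responses[[hsaCol]],
    active = classifyActivity(responses$combo_emax, responses[[hsaCol]],
                              config$emax_threshold, config$hsa_threshold))
  writeCsv(activity, "activity.csv")
  rates <- responderRate(activity, screen@cellLines)
  writeCsv(rates, "responder_rates.csv")
  typeGroups <- unique(screen@cellLines[, c("cancer_type", "group")])
  ranked <- rankHits(rates, typeGroups,
                     comboCategories = screen@combinations,
                     minCellLines = config$min_cell_lines,
                     responderThreshold = config$responder_threshold,
                     breadthCap = config$breadth_cap)
  writeCsv(ranked$heme, "ranked_heme.csv")
  writeCsv(ranked$solid, "ranked_solid.csv")
  jsonlite::write_json(ranked$funnel, outFile("funnel.json"),
                       dataframe = "rows")

  # -- biomarkers ----------------------------------------------------------
  subgroups <- makeSubgroups(screen@cellLines, screen@features,
                             minTypeSize = config$min_type_size,
                             baskets = config$baskets)
  biomarkers <- runAnovaSuite(
    responses, screen@features, screen@cellLines, subgroups = subgroups,
    pThreshold = config$p_threshold, fdrThreshold = config$fdr_threshold,
    glassThreshold = config$glass_threshold)
  emergent <- flagEmergent(biomarkers)
  writeCsv(emergent$associations, "biomarkers.csv")
  writeCsv(emergent$partition, "emergent_partition.csv")

  # -- enrichment ----------------------------------------------------------
  activity$category <- screen@combinations$category[
    match(activity$combo_id, screen@combinations$combo_id)]
  enrichment <- enrichmentOverRandom(activity, nBoot = config$n_boot,
                                     seed = config$seed)
  writeCsv(enrichment, "enrichment.csv")

  # -- manifest ------------------------------------------------------------
  cfgPath <- outFile("config.yaml")
  yaml::write_yaml(config, cfgPath)
  manifest <- list(
    package = "comboscreen",
    version = as.character(utils::packageVersion("comboscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfgPath)),
    row_counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, outFile("manifest.json"),
                       auto_unbox = TRUE)

  invisible(list(screen = screen, qc = qc, responses = responses,
                 activity = activity, rates = rates, ranked = ranked,
                 biomarkers = emergent$associations,
                 emergent = emergent, enrichment = enrichment,
                 manifest = manifest, outDir = outDir))
}
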