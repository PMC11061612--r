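# ANOVA biomarker discovery: binary multi-omics features against response
# metrics across pan-cancer, per-cancer-type and molecular-basket subgroups,
# with Benjamini-Hochberg FDR, Glass-delta effect sizes and emergent
# combination-biomarker flagging.

#' Binarize expression into up/down event features
#'
#' Z-scores each gene across the cell lines of the relevant panel subset and
#' emits two binary features per gene: `GENE_up` (Z at or above the
#' threshold) and `GENE_down` (Z at or below minus the threshold). Because
#' the Z-score is computed within the subset, a line can be "up" inside a
#' molecular basket without being up pan-cancer. Zero-variance genes yield
#' all-zero features.
#'
#' @param expression Numeric matrix, cell lines in rows (rownames), genes in
#'   columns.
#' @param zThreshold Z-score magnitude defining an event (default 2).
#' @return Integer 0/1 matrix, cell lines x (2 x genes).
#' @export
binarizeExpression <- function(expression, zThreshold = 2) {
  expression <- as.matrix(expression)
  mu <- colMeans(expression)
  sd <- apply(expression, 2, stats::sd)
  z <- sweep(sweep(expression, 2, mu, "-"), 2, ifelse(sd == 0, 1, sd), "/")
  z[, sd == 0] <- 0
  up <- (z >= zThreshold) + 0L
  down <- (z <= -zThreshold) + 0L
  colnames(up) <- paste0(colnames(expression), "_up")
  colnames(down) <- paste0(colnames(expression), "_down")
  out <- cbind(up, down)
  out[, order(rep(seq_len(ncol(expression)), 2)), drop = FALSE]
}

#' One feature-response ANOVA association
#'
#' F-test of a response metric on a binary feature, optionally adjusting for
#' covariates (a tissue factor in pan-cancer runs): without covariates the
#' classical one-way ANOVA F (equal to the squared pooled-variance t
#' statistic) is computed in closed form; with covariates the feature term
#' is tested after the covariates in a sequential linear model. Effect sizes
#' are the two Glass deltas, `|mean_pos - mean_neg|` divided by each group's
#' own standard deviation.
#'
#' @param response Numeric response vector.
#' @param feature Binary (0/1 or logical) feature vector, same length.
#' @param covariates Optional data.frame of covariates (same length).
#' @param minGroupSize Minimum cell lines per arm (default 3); smaller arms
#'   are reported as skipped rather than tested.
#' @return One-row data.frame: `n_pos`, `n_neg`, `delta_mean`,
#'   `glass_delta_pos`, `glass_delta_neg`, `p_value`, `skipped`, `reason`.
#' @export
anovaAssociation <- function(response, feature, covariates = NULL,
                             minGroupSize = 3) {
  f <- as.logical(feature)
  if (length(response) != length(f))
    inputError("response and feature lengths differ")
  ok <- !is.na(response) & !is.na(f)
  response <- response[ok]; f <- f[ok]
  if (!is.null(covariates)) covariates <- covariates[ok, , drop = FALSE]

  out <- data.frame(n_pos = sum(f), n_neg = sum(!f), delta_mean = NA_real_,
                    glass_delta_pos = NA_real_, glass_delta_neg = NA_real_,
                    p_value = NA_real_, skipped = FALSE, reason = "")
  if (out$n_pos < minGroupSize || out$n_neg < minGroupSize) {
    out$skipped <- TRUE
    out$reason <- sprintf("group below minimum size (%d pos, %d neg)",
                          out$n_pos, out$n_neg)
    return(out)
  }

  mPos <- mean(response[f]); mNeg <- mean(response[!f])
  sPos <- stats::sd(response[f]); sNeg <- stats::sd(response[!f])
  delta <- mPos - mNeg
  glass <- function(s) if (s == 0) { if (delta == 0) 0 else Inf }
                       else abs(delta) / s
  out$delta_mean <- delta
  out$glass_delta_pos <- glass(sPos)
  out$glass_delta_neg <- glass(sNeg)

  if (is.null(covariates)) {
    n1 <- out$n_pos; n2 <- out$n_neg; n <- n1 + n2
    m <- mean(response)
    ssb <- n1 * (mPos - m)^2 + n2 * (mNeg - m)^2
    ssw <- (n1 - 1) * sPos^2 + (n2 - 1) * sNeg^2
    out$p_value <- if (ssw == 0) {
      if (ssb == 0) NA_real_ else 0
    } else {
      stats::pf(ssb / (ssw / (n - 2)), 1, n - 2, lower.tail = FALSE)
    }
  } else {
    dat <- data.frame(.y = response, covariates, .f = f)
    # drop constant covariates (single-level factors break lm)
    keep <- vapply(covariates, function(x) length(unique(x)) > 1, logical(1))
    form <- if (any(keep))
      stats::as.formula(paste(".y ~", paste(names(covariates)[keep],
                                            collapse = " + "), "+ .f"))
    else stats::as.formula(".y ~ .f")
    at <- tryCatch(stats::anova(stats::lm(form, data = dat)),
                   error = function(e) NULL)
    out$p_value <- if (is.null(at)) NA_real_ else at[".f", "Pr(>F)"]
  }
  out
}

#' Build analysis subgroups
#'
#' Assembles the cell-line subgroups for the biomarker suite: the pan-cancer
#' panel, one subgroup per sufficiently common cancer type, and one
#' molecular basket per requested binary feature (all feature-positive
#' lines, cancer-type agnostic).
#'
#' @param annotations Data frame `cell_line`, `cancer_type`.
#' @param features Binary feature matrix (rownames = cell lines); required
#'   when `baskets` are requested.
#' @param minTypeSize Minimum lines for a cancer-type subgroup; types with
#'   strictly more than `minTypeSize - 1` lines qualify (default 20, i.e.
#'   more than 19 lines).
#' @param baskets Character vector of feature names defining baskets (e.g.
#'   mutation events such as `"TP53_mut"`).
#' @return Named list of subgroups, each `list(id, kind, cellLines)`.
#' @export
makeSubgroups <- function(annotations, features = NULL, minTypeSize = 20,
                          baskets = character()) {
  subs <- list(list(id = "pan-cancer", kind = "pan-cancer",
                    cellLines = as.character(annotations$cell_line)))
  counts <- table(annotations$cancer_type)
  for (ct in names(counts)[counts >= minTypeSize]) {
    subs[[length(subs) + 1L]] <- list(
      id = ct, kind = "cancer-type",
      cellLines = as.character(
        annotations$cell_line[annotations$cancer_type == ct]))
  }
  for (b in baskets) {
    if (is.null(features) || !b %in% colnames(features))
      inputError("basket feature not in feature matrix: ", b)
    subs[[length(subs) + 1L]] <- list(
      id = b, kind = "basket",
      cellLines = rownames(features)[features[, b] == 1])
  }
  names(subs) <- vapply(subs, `[[`, "", "id")
  subs
}

#' Run the full ANOVA biomarker suite
#'
#' Tests every (feature x response metric x combination x subgroup)
#' association, computes Benjamini-Hochberg FDR within each
#' (subgroup x metric) family, and applies the three-part significance rule:
#' p at most `pThreshold`, FDR at most `fdrThreshold`, and both Glass deltas
#' at least `glassThreshold`. Pan-cancer runs adjust for cancer type as a
#' categorical covariate by default; subgroup runs do not.
#'
#' @param responses Data frame with `combo_id`, `cell_line` and the metric
#'   columns.
#' @param features Binary feature matrix, rownames = cell lines.
#' @param annotations Data frame `cell_line`, `cancer_type`.
#' @param subgroups Subgroup list from [makeSubgroups()]; defaults to
#'   pan-cancer only.
#' @param metrics Response metrics to test (default the five: each single
#'   agent Emax, combination Emax, Bliss matrix, Bliss window).
#' @param pThreshold,fdrThreshold,glassThreshold Significance cut-offs
#'   (defaults 0.001, 0.10, 1).
#' @param tissueCovariate Adjust pan-cancer runs for cancer type
#'   (default TRUE).
#' @param minGroupSize Minimum arm size per test (default 3).
#' @return Data frame of associations, one row per test, with `p_value`,
#'   `fdr`, `significant`, `skipped` and the Glass deltas.
#' @export
runAnovaSuite <- function(responses, features, annotations,
                          subgroups = NULL,
                          metrics = c("emax_A", "emax_B", "combo_emax",
                                      "bliss_matrix", "bliss_window"),
                          pThreshold = 0.001, fdrThreshold = 0.1,
                          glassThreshold = 1, tissueCovariate = TRUE,
                          minGroupSize = 3) {
  if (is.null(subgroups)) subgroups <- makeSubgroups(annotations)
  missingMetrics <- setdiff(metrics, names(responses))
  if (length(missingMetrics))
    inputError("responses lack metric column(s): ",
               paste(missingMetrics, collapse = ", "))
  combos <- sort(unique(as.character(responses$combo_id)))
  featNames <- colnames(features)
  ctype <- stats::setNames(as.character(annotations$cancer_type),
                           annotations$cell_line)

  rows <- vector("list", 0L)
  for (sg in subgroups) {
    lines <- intersect(sg$cellLines, rownames(features))
    fsub <- features[lines, , drop = FALSE]
    rsub <- responses[responses$cell_line %in% lines, , drop = FALSE]
    useCov <- tissueCovariate && sg$kind == "pan-cancer"
    for (metric in metrics) {
      block <- vector("list", length(combos) * length(featNames))
      bi <- 0L
      for (combo in combos) {
        rc <- rsub[rsub$combo_id == combo, , drop = FALSE]
        idx <- match(rc$cell_line, lines)
        y <- rc[[metric]]
        cov <- if (useCov)
          data.frame(tissue = factor(ctype[rc$cell_line])) else NULL
        for (feat in featNames) {
          a <- anovaAssociation(y, fsub[idx, feat], covariates = cov,
                                minGroupSize = minGroupSize)
          bi <- bi + 1L
          block[[bi]] <- cbind(
            data.frame(feature = feat, metric = metric, combo_id = combo,
                       subgroup = sg$id, kind = sg$kind), a)
        }
      }
      fam <- do.call(rbind, block[seq_len(bi)])
      fam$fdr <- NA_real_
      testable <- !fam$skipped & !is.na(fam$p_value)
      fam$fdr[testable] <- stats::p.adjust(fam$p_value[testable],
                                           method = "BH")
      fam$significant <- testable &
        fam$p_value <= pThreshold &
        !is.na(fam$fdr) & fam$fdr <= fdrThreshold &
        !is.na(fam$glass_delta_pos) & fam$glass_delta_pos >= glassThreshold &
        !is.na(fam$glass_delta_neg) & fam$glass_delta_neg >= glassThreshold
      fam$significant[is.na(fam$significant)] <- FALSE
      rows[[length(rows) + 1L]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag emergent combination biomarkers
#'
#' An association between a feature and a combination response metric
#' (combination Emax, Bliss matrix or Bliss window) is emergent when the
#' same feature, in the same subgroup, is not significantly associated with
#' either constituent drug's single-agent Emax for that combination:
#' monotherapy-driven markers are excluded. Emergent biomarker units
#' (feature, combination, subgroup) are partitioned three ways by which
#' combination metrics carry the signal: Bliss only, both Bliss and
#' combination Emax, or combination Emax only.
#'
#' @param associations Output of [runAnovaSuite()]; must contain single-agent
#'   Emax rows (`emax_A`, `emax_B`) alongside the combination metrics.
#' @return List with `associations` (input plus an `emergent` column) and
#'   `partition`, a data frame of emergent-unit counts per class
#'   (`bliss_only`, `both`, `combo_emax_only`) whose `n` sums to the total
#'   number of emergent units.
#' @export
flagEmergent <- function(associations) {
  saMetrics <- c("emax_A", "emax_B")
  comboMetrics <- c("combo_emax", "bliss_matrix", "bliss_window")
  if (!any(associations$metric %in% saMetrics))
    inputError("association table lacks single-agent Emax rows")

  key <- function(d) paste(d$feature, d$combo_id, d$subgroup, sep = "\r")
  saSig <- unique(key(associations[
    associations$metric %in% saMetrics & associations$significant, ,
    drop = FALSE]))

  isCombo <- associations$metric %in% comboMetrics
  associations$emergent <- isCombo & associations$significant &
    !(key(associations) %in% saSig)

  em <- associations[associations$emergent, , drop = FALSE]
  units <- unique(key(em))
  blissAny <- unique(key(em[em$metric %in% c("bliss_matrix", "bliss_window"),
                            , drop = FALSE]))
  emaxAny <- unique(key(em[em$metric == "combo_emax", , drop = FALSE]))
  partition <- data.frame(
    class = c("bliss_only", "both", "combo_emax_only"),
    n = c(sum(units %in% blissAny & !(units %in% emaxAny)),
          sum(units %in% blissAny & units %in% emaxAny),
          sum(!(units %in% blissAny) & units %in% emaxAny)))
  list(associations = associations, partition = partition,
       n_emergent_units = length(units))
}
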