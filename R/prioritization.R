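# Activity classification and combination:cancer-type prioritization:
# responder rates, cancer-type specificity and the filter-and-rank cascade.

#' Classify a combination-cell line pair as active
#'
#' A pair is active when the combination shows both high activity
#' (combination Emax strictly above the Emax threshold) and benefit beyond
#' the better single agent (HSA score strictly above the HSA threshold).
#'
#' @param comboEmax Combination Emax value(s).
#' @param hsa HSA synergy score(s); the matrix-level HSA score by default
#'   feeds this call (see [rankHits()] and the pipeline config).
#' @param emaxThreshold Emax cut-off (default 0.5, strict `>`).
#' @param hsaThreshold HSA cut-off (default 0.1, strict `>`).
#' @return Logical vector of activity calls.
#' @examples
#' classifyActivity(c(0.6, 0.5, 0.6), c(0.2, 0.2, 0.1))  # TRUE FALSE FALSE
#' @export
classifyActivity <- function(comboEmax, hsa, emaxThreshold = 0.5,
                             hsaThreshold = 0.1) {
  comboEmax > emaxThreshold & hsa > hsaThreshold
}

#' Responder rates per combination and cancer type
#'
#' Aggregates activity calls into per (combination, cancer type) counts and
#' responder percentages. Percentages are reported to one decimal, rounding
#' half away from zero (3 of 7 -> 42.9).
#'
#' @param calls Data frame with columns `combo_id`, `cell_line`, `active`
#'   (logical) and either a `cancer_type` column or one joined from
#'   `annotations`.
#' @param annotations Optional data frame `cell_line`, `cancer_type` used to
#'   label calls lacking a `cancer_type` column.
#' @return Data frame: `combo_id`, `cancer_type`, `n_tested`,
#'   `n_responders`, `responder_pct`.
#' @examples
#' calls <- data.frame(combo_id = "C1", cell_line = paste0("L", 1:7),
#'                     cancer_type = "HL", active = c(rep(TRUE, 3), rep(FALSE, 4)))
#' responderRate(calls)$responder_pct  # 42.9
#' @export
responderRate <- function(calls, annotations = NULL) {
  if (!"cancer_type" %in% names(calls)) {
    if (is.null(annotations))
      inputError("calls lack cancer_type and no annotations were given")
    idx <- match(calls$cell_line, annotations$cell_line)
    calls$cancer_type <- annotations$cancer_type[idx]
  }
  if (anyNA(calls$cancer_type))
    inputError("unknown cancer type for cell line(s): ",
               paste(unique(calls$cell_line[is.na(calls$cancer_type)]),
                     collapse = ", "))
  agg <- stats::aggregate(active ~ combo_id + cancer_type, data = calls,
                          FUN = function(x) c(n = length(x), r = sum(x)))
  out <- data.frame(combo_id = agg$combo_id, cancer_type = agg$cancer_type,
                    n_tested = agg$active[, "n"],
                    n_responders = agg$active[, "r"])
  out$responder_pct <- roundHalfUp(100 * out$n_responders / out$n_tested, 1)
  out <- out[order(out$combo_id, out$cancer_type), ]
  rownames(out) <- NULL
  out
}

#' Count cancer types sensitive to each combination
#'
#' A cancer type counts as sensitive to a combination when at least
#' `responderThreshold` percent of its tested cell lines are responders
#' (inclusive `>=`, "at least").
#'
#' @param rateTable Output of [responderRate()].
#' @param responderThreshold Responder percentage cut-off (default 10).
#' @return Data frame `combo_id`, `n_sensitive_types`.
#' @export
sensitiveCancerTypes <- function(rateTable, responderThreshold = 10) {
  sens <- tapply(rateTable$responder_pct >= responderThreshold,
                 as.character(rateTable$combo_id), sum)
  data.frame(combo_id = names(sens), n_sensitive_types = as.integer(sens),
             row.names = NULL)
}

#' Cancer-type specificity score
#'
#' Total number of cancer types tested minus the number showing sensitivity;
#' a higher score means a more selective combination.
#'
#' @param nTotalTypes Number of cancer types in which the combination was
#'   tested.
#' @param nSensitiveTypes Number of sensitive cancer types (must lie in
#'   `[0, nTotalTypes]`).
#' @return The specificity score.
#' @examples
#' specificityScore(41, 15)  # 26
#' @export
specificityScore <- function(nTotalTypes, nSensitiveTypes) {
  if (any(nSensitiveTypes < 0) || any(nSensitiveTypes > nTotalTypes))
    inputError("nSensitiveTypes must lie in [0, nTotalTypes]")
  nTotalTypes - nSensitiveTypes
}

#' Filter and rank combination:cancer-type hits
#'
#' Applies the prioritization cascade to a responder-rate table:
#' \enumerate{
#'   \item drop pairs below the responder threshold (default 10 percent);
#'   \item drop combinations sensitive in half or more of their tested
#'     cancer types (broadly active combinations are less likely to be
#'     clinically tolerable);
#'   \item drop pairs tested in fewer than `minCellLines` cell lines
#'     (small samples bias percentages);
#'   \item score the survivors as `responder_pct + specificity_score`
#'     (equal weighting of activity and selectivity) and sort descending,
#'     ties broken by responder percentage then combination id.
#' }
#' The specificity score uses each combination's own number of tested cancer
#' types as the total. Results are split into hematological and solid-tumor
#' lists.
#'
#' @param rateTable Output of [responderRate()].
#' @param typeGroups Data frame `cancer_type`, `group` with group values
#'   `heme` or `solid`.
#' @param comboCategories Optional data frame `combo_id`, `category`
#'   (mechanism-pair label, see [categorizeCombination()]); joined onto the
#'   ranked output when present.
#' @param minCellLines Minimum cell lines tested per pair (default 10).
#' @param responderThreshold Responder percentage threshold (default 10).
#' @param breadthCap Drop combinations sensitive in at least this fraction
#'   of their tested cancer types (default 0.5).
#' @return List with elements `heme` and `solid` (ranked data frames with
#'   `rank_score`, `specificity_score`, `n_sensitive_types`) and `funnel`, a
#'   data frame of pair counts after each cascade step.
#' @export
rankHits <- function(rateTable, typeGroups, comboCategories = NULL,
                     minCellLines = 10, responderThreshold = 10,
                     breadthCap = 0.5) {
  if (!all(c("cancer_type", "group") %in% names(typeGroups)))
    inputError("typeGroups needs columns cancer_type, group")
  tab <- rateTable
  funnel <- data.frame(step = "tested", n_pairs = nrow(tab))

  # per-combo totals and sensitivity counts from the full tested table
  nTotal <- tapply(rep(1, nrow(tab)), as.character(tab$combo_id), sum)
  sens <- sensitiveCancerTypes(tab, responderThreshold)
  sens$n_total_types <- as.integer(nTotal[sens$combo_id])
  sens$specificity_score <-
    specificityScore(sens$n_total_types, sens$n_sensitive_types)

  # (1) responder threshold on pairs
  tab <- tab[tab$responder_pct >= responderThreshold, ]
  funnel <- rbind(funnel,
                  data.frame(step = "responders", n_pairs = nrow(tab)))

  # (2) breadth cap on combinations
  broad <- sens$combo_id[sens$n_sensitive_types >=
                           breadthCap * sens$n_total_types]
  tab <- tab[!(tab$combo_id %in% broad), ]
  funnel <- rbind(funnel,
                  data.frame(step = "breadth", n_pairs = nrow(tab)))

  # (3) minimum cell lines per pair
  tab <- tab[tab$n_tested >= minCellLines, ]
  funnel <- rbind(funnel,
                  data.frame(step = "min_cell_lines", n_pairs = nrow(tab)))

  # (4) score and rank
  idx <- match(tab$combo_id, sens$combo_id)
  tab$n_sensitive_types <- sens$n_sensitive_types[idx]
  tab$n_total_types <- sens$n_total_types[idx]
  tab$specificity_score <- sens$specificity_score[idx]
  tab$rank_score <- tab$responder_pct + tab$specificity_score

  gidx <- match(tab$cancer_type, typeGroups$cancer_type)
  if (anyNA(gidx))
    inputError("missing heme/solid annotation for cancer type(s): ",
               paste(unique(tab$cancer_type[is.na(gidx)]), collapse = ", "))
  tab$group <- typeGroups$group[gidx]
  if (!is.null(comboCategories))
    tab$category <-
      comboCategories$category[match(tab$combo_id, comboCategories$combo_id)]

  ord <- order(-tab$rank_score, -tab$responder_pct, tab$combo_id)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  list(heme = tab[tab$group == "heme", ],
       solid = tab[tab$group == "solid", ],
       funnel = funnel)
}

#' Mechanism category of a combination
#'
#' Labels a combination by the unordered pair of pathway classes of its two
#' drugs (e.g. a cell-death agent plus a DDR agent gives `"CD+DDR"`); the
#' label is symmetric in drug order.
#'
#' @param drugA,drugB Drug identifiers.
#' @param pathwayMap Named character vector or data frame (`drug`,
#'   `pathway`) mapping every drug to exactly one pathway class.
#' @return Character category label.
#' @examples
#' pm <- c(venetoclax = "CD", AZD5991 = "CD", selumetinib = "CS")
#' categorizeCombination("selumetinib", "venetoclax", pm)  # "CD+CS"
#' @export
categorizeCombination <- function(drugA, drugB, pathwayMap) {
  if (is.data.frame(pathwayMap))
    pathwayMap <- stats::setNames(as.character(pathwayMap$pathway),
                                  pathwayMap$drug)
  lookup <- function(d) {
    if (!d %in% names(pathwayMap))
      inputError("drug not in pathway map: ", d)
    pathwayMap[[d]]
  }
  mapply(function(a, b) paste(sort(c(lookup(a), lookup(b))), collapse = "+"),
         drugA, drugB, USE.NAMES = FALSE)
}
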