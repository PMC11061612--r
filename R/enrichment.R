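# Enrichment of efficacious combinations in pathway-pair categories
# relative to a random-assignment baseline.

#' Enrichment of active combinations over random assignment
#'
#' For each pathway-pair category, compares the observed fraction of active
#' (efficacious) combination-cell line pairs, `Es = nc / Nc`, with the
#' fraction expected if the `n` active labels were redistributed uniformly
#' at random across all pairs: the redistribution is repeated `nBoot` times
#' (10-fold by default), the per-category active counts are averaged into
#' `nb`, and `Er = nb / Nc`. A category is enriched for synergy over random
#' when `Es > Er`. An empirical p-value (fraction of replicates whose random
#' count reaches the observed `nc`) is reported alongside the binary
#' verdict.
#'
#' @param calls Data frame of combination-cell line pairs with logical
#'   `active` and character `category` columns (no missing categories).
#' @param nBoot Number of random redistributions (default 10).
#' @param seed Seed for the redistribution (default 1).
#' @return Data frame, one row per category: `category`, `Nc`, `nc`, `Es`,
#'   `nb`, `Er`, `enriched`, `p_empirical`.
#' @export
enrichmentOverRandom <- function(calls, nBoot = 10, seed = 1) {
  if (!all(c("active", "category") %in% names(calls)))
    inputError("calls need `active` and `category` columns")
  if (anyNA(calls$category))
    inputError("pair(s) without a category label")
  cats <- sort(unique(as.character(calls$category)))
  category <- factor(as.character(calls$category), levels = cats)
  nTotal <- nrow(calls)
  n <- sum(calls$active)
  Nc <- as.integer(table(category))
  nc <- as.integer(table(category[calls$active]))

  randomCounts <- withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(nTotal, n)
      as.integer(table(category[idx]))
    }, integer(length(cats)))
  })
  randomCounts <- matrix(randomCounts, nrow = length(cats))
  nb <- rowMeans(randomCounts)
  pEmp <- rowMeans(randomCounts >= nc)

  data.frame(category = cats, Nc = Nc, nc = nc,
             Es = nc / Nc, nb = nb, Er = nb / Nc,
             enriched = nc / Nc > nb / Nc, p_empirical = pEmp,
             row.names = NULL)
}
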