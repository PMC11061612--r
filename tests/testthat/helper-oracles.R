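# Independent oracles and fixture builders shared across tests.

# Sliding-window maximum-mean oracle via a summed-area (integral image)
# table: an independent computation of the best w x w window mean and its
# 1-based top-left corner, ties broken by smallest row then column.
windowOracle <- function(g, w = 3) {
  nr <- nrow(g); nc <- ncol(g)
  C <- t(apply(apply(g, 2, cumsum), 1, cumsum))  # C[i,j] = sum g[1:i,1:j]
  Cp <- matrix(0, nr + 1, nc + 1)
  Cp[2:(nr + 1), 2:(nc + 1)] <- C
  scores <- matrix(NA_real_, nr - w + 1, nc - w + 1)
  for (i in seq_len(nr - w + 1)) for (j in seq_len(nc - w + 1)) {
    scores[i, j] <- (Cp[i + w, j + w] - Cp[i, j + w] -
                       Cp[i + w, j] + Cp[i, j]) / (w * w)
  }
  best <- max(scores)
  hits <- which(scores == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(score = best, row = unname(hits[1, 1]), col = unname(hits[1, 2]),
       n_windows = length(scores))
}

# Benjamini-Hochberg step-up, written from the definition.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Expand per-group responder counts into a long activity-call table.
makeCalls <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    data.frame(
      combo_id = r$combo_id,
      cell_line = sprintf("%s_%s_L%02d", r$combo_id, r$cancer_type,
                          seq_len(r$n_tested)),
      cancer_type = r$cancer_type,
      active = seq_len(r$n_tested) <= r$n_responders)
  })
  do.call(rbind, rows)
}

# Deterministic control-well plate mimicking the generator defaults.
makePlate <- function(seed = 1, plate = "P1", ncMean = 1000, ncSd = 122.8,
                      pcMean = 100, pcSd = 27.8) {
  generatePlateControls(
    means = c(NC0 = ncMean, NC1 = ncMean, PC1 = pcMean, PC2 = pcMean * 1.2,
              B = 10),
    sds = c(NC0 = ncSd, NC1 = ncSd, PC1 = pcSd, PC2 = pcSd, B = 5),
    seed = seed, plate = plate)
}
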