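# Synthetic screen generator: curve and matrix construction, controls,
# determinism and ground-truth consistency.

test_that("single-agent curves follow the two-parameter logistic truth", {
  d <- doseGrid(7)
  # IC50 at the middle dose: half-maximal inhibition there
  cur <- simulateSingleAgentCurve(d[4], 2, d)
  expect_equal(cur$inhibition[4], 0.5)
  expect_true(all(diff(cur$truth) > 0))      # monotone in dose
  expect_true(all(cur$truth >= 0 & cur$truth <= 1))

  # IC50 far above the top dose with a steep slope: inactive
  flat <- simulateSingleAgentCurve(1e6 * max(d), 4, d)
  expect_true(all(flat$inhibition < 1e-6))

  # seed determinism of the noisy draw
  a <- simulateSingleAgentCurve(d[4], 2, d, noiseSd = 0.05, seed = 9)
  b <- simulateSingleAgentCurve(d[4], 2, d, noiseSd = 0.05, seed = 9)
  expect_identical(a$inhibition, b$inhibition)
  expect_false(identical(
    a$inhibition,
    simulateSingleAgentCurve(d[4], 2, d, noiseSd = 0.05, seed = 10)$inhibition))

  expect_error(simulateSingleAgentCurve(1, 1, c(-1, 1, 2, 3)), "positive")
})

test_that("combination matrices are Bliss-additive with optional planted windows", {
  d <- doseGrid(7)
  cA <- simulateSingleAgentCurve(d[3], 1.5, d)
  cB <- simulateSingleAgentCurve(d[5], 1, d)

  # additive construction: per-well Bliss excess is exactly zero
  m <- simulateCombinationMatrix(cA, cB)
  ex <- perWellExcess(inhibitionGrid(m), cA$truth, cB$truth, "bliss")
  expect_true(all(abs(ex) < 1e-12))

  # an inactive partner: every column equals drug A's own curve
  zero <- list(doses = d, truth = rep(0, 7))
  m2 <- inhibitionGrid(simulateCombinationMatrix(cA, zero))
  for (j in 1:7) expect_equal(m2[, j], cA$truth)

  # a corner window with boost 0.2 on an inactive-inactive background is
  # recovered exactly by the window score
  zeroA <- list(doses = d, truth = rep(0, 7))
  m3 <- simulateCombinationMatrix(
    zeroA, zero, window = list(row = 1, col = 1, size = 3, boost = 0.2))
  syn <- synergySummary(inhibitionGrid(m3), zeroA$truth, zero$truth)
  expect_equal(syn@blissWindow, 0.2)
  expect_equal(syn@blissWindowLoc, c(1L, 1L))

  expect_error(
    simulateCombinationMatrix(cA, cB,
                              window = list(row = 6, col = 1, size = 3,
                                            boost = 0.2)),
    "outside")
})

test_that("noiseless generated pairs have zero Bliss scores and truth in [0,1]", {
  d <- doseGrid(7)
  withr::with_seed(51, {
    for (i in 1:20) {
      cA <- simulateSingleAgentCurve(10^runif(1, -2, 1), runif(1, 0.8, 2.5), d)
      cB <- simulateSingleAgentCurve(10^runif(1, -2, 1), runif(1, 0.8, 2.5), d)
      g <- inhibitionGrid(simulateCombinationMatrix(cA, cB))
      expect_true(all(g >= 0 & g <= 1))
      syn <- synergySummary(g, cA$truth, cB$truth)
      expect_lt(abs(syn@blissMatrix), 1e-12)
      expect_lt(abs(syn@blissWindow), 1e-12)
    }
  })
})

test_that("plate controls honor counts, parameters and determinism", {
  ctl <- generatePlateControls(seed = 1)
  expect_equal(sum(ctl$well_class == "NC1"), 155)
  expect_equal(sum(ctl$well_class == "NC0"), 155)
  expect_equal(sum(ctl$well_class %in% c("PC1", "PC2")), 32)
  expect_equal(sum(ctl$well_class == "B"), 28)

  # zero SD collapses each class onto its mean
  exact <- generatePlateControls(sds = c(NC0 = 0, NC1 = 0, PC1 = 0,
                                         PC2 = 0, B = 0), seed = 1)
  expect_equal(unique(exact$raw_signal[exact$well_class == "NC1"]), 1000)
  expect_equal(unique(exact$raw_signal[exact$well_class == "B"]), 10)

  expect_identical(generatePlateControls(seed = 2),
                   generatePlateControls(seed = 2))
  expect_error(generatePlateControls(sds = c(NC0 = -1, NC1 = 1, PC1 = 1,
                                             PC2 = 1, B = 1)),
               "non-negative")
})

test_that("screens are deterministic and stable under panel extension", {
  cfg <- screenConfig(nCellLines = 6, nCombinations = 4, nFeatures = 8,
                      seed = 13)
  s1 <- simulateScreen(cfg)
  s2 <- simulateScreen(cfg)
  expect_identical(s1@wells, s2@wells)
  expect_identical(s1@features, s2@features)

  # counter-based substreams: adding cell lines never perturbs earlier ones
  bigger <- simulateScreen(screenConfig(nCellLines = 9, nCombinations = 4,
                                        nFeatures = 8, seed = 13))
  keep <- bigger@wells$cell_line %in% s1@cellLines$cell_line
  expect_identical(bigger@wells[keep, ], s1@wells)
  expect_identical(bigger@features[rownames(s1@features), ], s1@features)
})

test_that("planted ground truth is internally consistent", {
  cfg <- screenConfig(nCellLines = 10, nCombinations = 5, nFeatures = 8,
                      synergyFraction = 0.5, seed = 17)
  scr <- simulateScreen(cfg)
  gt <- scr@groundTruth
  # every planted window fits inside the matrix
  w <- gt$windows[gt$windows$has_window, ]
  expect_true(nrow(w) > 0)
  expect_true(all(w$row >= 1 & w$row + w$size - 1 <= cfg$nDoses))
  expect_true(all(w$col >= 1 & w$col + w$size - 1 <= cfg$nDoses))
  # every curve has positive parameters inside the sampled potency range
  # (in-range for sensitive lines, up to two decades above the top dose
  # for insensitive ones)
  d <- doseGrid(cfg$nDoses, cfg$doseFoldRange, cfg$topDose)
  expect_true(all(gt$curves$ic50 >= d[2] & gt$curves$ic50 <= 100 * max(d)))
  expect_true(all(gt$curves$slope > 0))

  # planted effects must reference existing features and targets
  bad <- screenConfig(nFeatures = 5, plantedSingleAgentEffects = list(
    list(feature = "F099", drug = "D01", effect = 3)))
  expect_error(generateFeatureMatrix(bad), "unknown feature")
  bad2 <- screenConfig(plantedEmergentEffects = list(
    list(feature = "F001", combo = "C99", effect = 3)))
  expect_error(generateFeatureMatrix(bad2), "unknown combo")
})

test_that("config invariants are enforced", {
  expect_error(screenConfig(nDoses = 1), "nDoses")
  expect_error(screenConfig(doseFoldRange = 1), "doseFoldRange")
  expect_error(screenConfig(noiseSd = -0.1), "noiseSd")
  expect_error(screenConfig(synergyFraction = 1.2), "synergyFraction")
})

test_that("the response-table shortcut plants effects in the stated metrics", {
  cfg <- screenConfig(
    nCellLines = 120, nCombinations = 4, nFeatures = 6, seed = 23,
    plantedSingleAgentEffects = list(
      list(feature = "F001", drug = "D01", effect = 3)),
    plantedEmergentEffects = list(
      list(feature = "F002", combo = "C03", effect = 3)))
  sim <- simulateResponseTable(cfg)
  r <- sim$responses
  f <- sim$features
  combosWithD01 <- sim$design$combos$combo_id[
    sim$design$combos$drug_A == "D01" | sim$design$combos$drug_B == "D01"]
  expect_true(length(combosWithD01) > 0)

  # the single-agent effect separates emax for feature-positive lines
  cid <- combosWithD01[1]
  sub <- r[r$combo_id == cid, ]
  pos <- f[sub$cell_line, "F001"] == 1
  col <- if (sim$design$combos$drug_A[sim$design$combos$combo_id == cid] ==
               "D01") "emax_A" else "emax_B"
  expect_gt(mean(sub[[col]][pos]) - mean(sub[[col]][!pos]), 0.2)

  # the emergent effect moves combination metrics but not single-agent Emax
  sub3 <- r[r$combo_id == "C03", ]
  pos3 <- f[sub3$cell_line, "F002"] == 1
  expect_gt(mean(sub3$bliss_matrix[pos3]) - mean(sub3$bliss_matrix[!pos3]),
            0.05)
  expect_lt(abs(mean(sub3$emax_A[pos3]) - mean(sub3$emax_A[!pos3])), 0.1)
})
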