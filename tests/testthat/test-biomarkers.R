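# Expression binarization, ANOVA associations, the suite, FDR and
# emergent-biomarker flagging.

test_that("expression binarization flags z-score tails within the panel subset", {
  withr::with_seed(31, x <- matrix(rnorm(5000), 1000, 5,
                                   dimnames = list(NULL, paste0("G", 1:5))))
  bin <- binarizeExpression(x)
  expect_equal(colnames(bin)[1:2], c("G1_up", "G1_down"))
  # standard-normal tails beyond |Z|=2 hold ~2.3% of lines
  expect_equal(mean(bin[, "G1_up"]), 0.023, tolerance = 0.5)
  expect_true(all(bin %in% 0:1))

  # constant genes produce no events
  const <- binarizeExpression(matrix(5, 100, 1,
                                     dimnames = list(NULL, "G")))
  expect_true(all(const == 0))

  # z-scores are subset-relative: a line 3 SDs up within its subgroup is
  # unremarkable against a strongly bimodal pan-cancer panel
  withr::with_seed(37,
    expr <- matrix(c(rnorm(50, 0, 1), rnorm(50, 10, 1)), ncol = 1,
                   dimnames = list(NULL, "G")))
  sub <- expr[51:100, , drop = FALSE]
  sub[50, 1] <- 10 + 3  # 3 SDs above the subgroup mean
  panBin <- binarizeExpression(rbind(expr[1:50, , drop = FALSE], sub))
  subBin <- binarizeExpression(sub)
  expect_equal(unname(subBin[50, "G_up"]), 1L)
  expect_equal(unname(panBin[100, "G_up"]), 0L)  # pan-panel SD ~5, z ~1.6
})

test_that("the ANOVA F-test equals the squared pooled t-test without covariates", {
  withr::with_seed(32, {
    for (i in 1:25) {
      n <- sample(20:60, 1)
      f <- rbinom(n, 1, 0.4)
      if (sum(f) < 3 || sum(!f) < 3) next
      y <- rnorm(n) + 0.5 * f
      a <- anovaAssociation(y, f)
      tt <- t.test(y[f == 1], y[f == 0], var.equal = TRUE)
      expect_equal(a$p_value, tt$p.value, tolerance = 1e-12)
      expect_equal(a$delta_mean, unname(diff(rev(tt$estimate))),
                   tolerance = 1e-12)
    }
  })
})

test_that("degenerate and undersized associations are handled without failure", {
  # identical groups: zero deltas, no significance claim
  a <- anovaAssociation(rep(1, 20), rep(c(0, 1), 10))
  expect_equal(a$glass_delta_pos, 0)
  expect_equal(a$glass_delta_neg, 0)
  expect_true(is.na(a$p_value))

  # an arm below the minimum size is skipped with a reason, not tested
  a <- anovaAssociation(rnorm(20), c(rep(1, 2), rep(0, 18)))
  expect_true(a$skipped)
  expect_match(a$reason, "minimum size")
})

test_that("a planted 3-SD effect is overwhelming at n = 200, prevalence 0.3", {
  withr::with_seed(33, {
    f <- rbinom(200, 1, 0.3)
    y <- rnorm(200, 0, 1) + 3 * f
  })
  a <- anovaAssociation(y, f)
  expect_lt(a$p_value, 1e-10)
  expect_gte(a$glass_delta_pos, 1)
  expect_gte(a$glass_delta_neg, 1)
})

test_that("glass deltas are invariant to shifting and scaling the response", {
  withr::with_seed(34, {
    f <- rbinom(100, 1, 0.3)
    y <- rnorm(100) + f
  })
  a <- anovaAssociation(y, f)
  b <- anovaAssociation(5 + 3 * y, f)
  expect_equal(b$glass_delta_pos, a$glass_delta_pos)
  expect_equal(b$glass_delta_neg, a$glass_delta_neg)
})

test_that("BH adjustment in the suite matches a step-up oracle", {
  withr::with_seed(35, {
    for (i in 1:200) {
      p <- runif(sample(5:80, 1))
      expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
    }
  })
})

test_that("the suite recovers planted effects and respects subgroup scoping", {
  cfg <- screenConfig(
    nCellLines = 150, nCombinations = 6, nFeatures = 15, seed = 42,
    plantedSingleAgentEffects = list(
      list(feature = "F001", drug = "D01", effect = 3),
      list(feature = "F002", drug = "D04", effect = 3)),
    plantedEmergentEffects = list(
      list(feature = "F003", combo = "C02", effect = 3),
      list(feature = "F004", combo = "C05", effect = 3)))
  sim <- simulateResponseTable(cfg)
  res <- runAnovaSuite(sim$responses, sim$features, sim$annotations)

  # planted single-agent effects: significant on the drug's Emax metric
  sigSA <- res[res$significant & res$metric %in% c("emax_A", "emax_B"), ]
  expect_true(any(sigSA$feature == "F001"))
  expect_true(any(sigSA$feature == "F002"))

  em <- flagEmergent(res)
  emUnits <- unique(em$associations[em$associations$emergent,
                                    c("feature", "combo_id")])
  # planted emergent effects surface as emergent units on their combination
  expect_true(any(emUnits$feature == "F003" & emUnits$combo_id == "C02"))
  expect_true(any(emUnits$feature == "F004" & emUnits$combo_id == "C05"))
  # planted single-agent markers are never flagged emergent
  expect_false(any(emUnits$feature %in% c("F001", "F002")))
  # partition is disjoint and exhaustive over emergent units
  expect_equal(sum(em$partition$n), em$n_emergent_units)
  # emergent rows are a subset of significant combination-metric rows
  a <- em$associations
  expect_true(all(a$significant[a$emergent]))
  expect_true(all(a$metric[a$emergent] %in%
                    c("combo_emax", "bliss_matrix", "bliss_window")))
})

test_that("a basket-confined effect is found in the basket but not pan-cancer", {
  withr::with_seed(36, {
    n <- 300
    lines <- sprintf("L%03d", 1:n)
    basket <- rbinom(n, 1, 0.25)           # e.g. a mutation basket
    feat <- rbinom(n, 1, 0.4)
    y <- rnorm(n, 0.4, 0.1)
    y[basket == 1 & feat == 1] <- y[basket == 1 & feat == 1] + 0.3
  })
  features <- cbind(BASKET_mut = basket, F1 = feat)
  rownames(features) <- lines
  responses <- data.frame(combo_id = "C01", cell_line = lines, combo_emax = y)
  ann <- data.frame(cell_line = lines, cancer_type = "mixed")
  subs <- makeSubgroups(ann, features, baskets = "BASKET_mut")
  res <- runAnovaSuite(responses, features, ann, subgroups = subs,
                       metrics = "combo_emax")
  r1 <- res[res$feature == "F1", ]
  expect_true(r1$significant[r1$subgroup == "BASKET_mut"])
  # diluted pan-cancer signal fails the Glass-delta gate
  expect_false(r1$significant[r1$subgroup == "pan-cancer"])
  expect_lt(r1$glass_delta_neg[r1$subgroup == "pan-cancer"], 1)
})

test_that("emergent flagging applies the monotherapy-exclusion definition", {
  mk <- function(feature, metric, significant) {
    data.frame(feature = feature, metric = metric, combo_id = "C1",
               subgroup = "pan-cancer", significant = significant)
  }
  tab <- rbind(
    mk("f1", "bliss_matrix", TRUE), mk("f1", "emax_A", FALSE),
    mk("f1", "emax_B", FALSE),
    mk("f2", "bliss_matrix", TRUE), mk("f2", "emax_A", TRUE),
    mk("f2", "emax_B", FALSE),
    mk("f3", "combo_emax", TRUE), mk("f3", "bliss_window", TRUE),
    mk("f3", "emax_A", FALSE), mk("f3", "emax_B", FALSE))
  em <- flagEmergent(tab)
  a <- em$associations
  expect_true(a$emergent[a$feature == "f1" & a$metric == "bliss_matrix"])
  # monotherapy-driven marker: excluded despite combination significance
  expect_false(any(a$emergent[a$feature == "f2"]))
  expect_equal(em$n_emergent_units, 2)
  expect_equal(em$partition$n[em$partition$class == "bliss_only"], 1)
  expect_equal(em$partition$n[em$partition$class == "both"], 1)
  expect_equal(em$partition$n[em$partition$class == "combo_emax_only"], 0)
  expect_error(flagEmergent(tab[tab$metric == "bliss_matrix", ]),
               "single-agent")
})
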