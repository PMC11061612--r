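# Activity calls, responder rates and the prioritization cascade.

test_that("activity requires both thresholds strictly exceeded", {
  expect_true(classifyActivity(0.6, 0.2))
  expect_false(classifyActivity(0.5, 0.2))   # Emax boundary is strict
  expect_false(classifyActivity(0.6, 0.1))   # HSA boundary is strict
  expect_equal(classifyActivity(c(0.6, 0.4), c(0.2, 0.2)), c(TRUE, FALSE))
})

test_that("responder percentages reproduce worked examples to one decimal", {
  counts <- data.frame(
    combo_id = "CX",
    cancer_type = c("HL", "SCLC", "EWS", "NONE"),
    n_tested = c(7, 36, 20, 11),
    n_responders = c(3, 17, 9, 0))
  rates <- responderRate(makeCalls(counts))
  got <- setNames(rates$responder_pct, rates$cancer_type)
  expect_equal(got[["HL"]], 42.9)    # 3 of 7
  expect_equal(got[["SCLC"]], 47.2)  # 17 of 36
  expect_equal(got[["EWS"]], 45)     # 9 of 20
  expect_equal(got[["NONE"]], 0)
  expect_equal(rates$n_tested[rates$cancer_type == "SCLC"], 36)
})

test_that("responder rates join annotations and reject unknown cell lines", {
  calls <- data.frame(combo_id = "C1", cell_line = c("L1", "L2"),
                      active = c(TRUE, FALSE))
  ann <- data.frame(cell_line = "L1", cancer_type = "AML")
  expect_error(responderRate(calls, ann), "unknown cancer type.*L2")
  expect_error(responderRate(calls), "no annotations")
  ann2 <- rbind(ann, data.frame(cell_line = "L2", cancer_type = "AML"))
  expect_equal(responderRate(calls, ann2)$responder_pct, 50)
})

test_that("sensitivity counting is inclusive at the threshold and monotone", {
  rt <- data.frame(combo_id = "C1", cancer_type = c("A", "B", "C"),
                   n_tested = c(10, 10, 10), n_responders = c(1, 0, 5),
                   responder_pct = c(10, 0, 50))
  expect_equal(sensitiveCancerTypes(rt)$n_sensitive_types, 2)  # 10% counts
  # raising the threshold never increases the count
  for (thr in c(10, 25, 50, 75)) {
    lower <- sensitiveCancerTypes(rt, thr)$n_sensitive_types
    higher <- sensitiveCancerTypes(rt, thr + 10)$n_sensitive_types
    expect_lte(higher, lower)
  }
})

test_that("specificity score is the complement of sensitive-type count", {
  expect_equal(specificityScore(41, 41), 0)
  expect_equal(specificityScore(41, 0), 41)
  expect_equal(specificityScore(41, 15), 26)
  expect_error(specificityScore(41, 42), "lie in")
})

# Hand-computed cascade fixture:
#  CA broad:     HL 3/7 (42.9), AML 13/19 (68.4); sensitive 2/2 -> breadth-dropped
#  CB selective: HL 1/12 (8.3), AML 6/15 (40), LUSC 2/30 (6.7), EWS 1/20 (5),
#                GBM 2/9 (22.2); sensitive 2/5; GBM pair dropped (n=9 < 10)
#  CC selective: AML 0/9, LUSC 12/25 (48), EWS 1/20 (5), HL 0/11; sensitive 1/4
# Funnel: 11 tested -> 5 responders -> 3 after breadth -> 2 after min lines.
# Final: heme = CB:AML rank 40 + (5-2) = 43; solid = CC:LUSC rank 48 + (4-1) = 51.
prioritizationFixture <- function() {
  counts <- data.frame(
    combo_id = rep(c("CA", "CB", "CC"), c(2, 5, 4)),
    cancer_type = c("HL", "AML",
                    "HL", "AML", "LUSC", "EWS", "GBM",
                    "AML", "LUSC", "EWS", "HL"),
    n_tested = c(7, 19, 12, 15, 30, 20, 9, 9, 25, 20, 11),
    n_responders = c(3, 13, 1, 6, 2, 1, 2, 0, 12, 1, 0))
  list(rates = responderRate(makeCalls(counts)),
       groups = data.frame(
         cancer_type = c("HL", "AML", "LUSC", "EWS", "GBM"),
         group = c("heme", "heme", "solid", "solid", "solid")))
}

test_that("the filter cascade reproduces hand-computed funnel counts and ranking", {
  fx <- prioritizationFixture()
  ranked <- rankHits(fx$rates, fx$groups)

  expect_equal(ranked$funnel$n_pairs, c(11, 5, 3, 2))
  expect_equal(nrow(ranked$heme), 1)
  expect_equal(nrow(ranked$solid), 1)

  heme <- ranked$heme
  expect_equal(heme$combo_id, "CB")
  expect_equal(heme$cancer_type, "AML")
  expect_equal(heme$responder_pct, 40)
  expect_equal(heme$n_sensitive_types, 2)
  expect_equal(heme$specificity_score, 3)
  expect_equal(heme$rank_score, 43)

  solid <- ranked$solid
  expect_equal(solid$combo_id, "CC")
  expect_equal(solid$cancer_type, "LUSC")
  expect_equal(solid$rank_score, 51)

  # a surviving hit's cancer type lacking a heme/solid label is an error
  expect_error(rankHits(fx$rates,
                        fx$groups[fx$groups$cancer_type != "AML", ]),
               "heme/solid")
})

test_that("the cascade filters act as order-independent pure predicates", {
  fx <- prioritizationFixture()
  rt <- fx$rates
  # compute each predicate independently on the unfiltered table
  p1 <- rt$responder_pct >= 10
  sens <- sensitiveCancerTypes(rt)
  tot <- table(rt$combo_id)
  broad <- sens$combo_id[sens$n_sensitive_types >=
                           0.5 * as.integer(tot[sens$combo_id])]
  p2 <- !(rt$combo_id %in% broad)
  p3 <- rt$n_tested >= 10
  survivors <- rt[p1 & p2 & p3, ]
  ranked <- rankHits(rt, fx$groups)
  final <- rbind(ranked$heme, ranked$solid)
  expect_setequal(paste(final$combo_id, final$cancer_type),
                  paste(survivors$combo_id, survivors$cancer_type))
})

test_that("raising the responder threshold never increases surviving hits", {
  fx <- prioritizationFixture()
  nHits <- vapply(c(10, 25, 50, 75), function(thr) {
    r <- rankHits(fx$rates, fx$groups, responderThreshold = thr)
    nrow(r$heme) + nrow(r$solid)
  }, numeric(1))
  expect_true(all(diff(nHits) <= 0))
  # rank scores live in [0, 100 + n_total_types]
  r <- rankHits(fx$rates, fx$groups)
  all_ <- rbind(r$heme, r$solid)
  expect_true(all(all_$rank_score >= 0 &
                    all_$rank_score <= 100 + all_$n_total_types))
})

test_that("mechanism categories are symmetric unordered pathway pairs", {
  pm <- c(venetoclax = "CD", AZD5991 = "CD", selumetinib = "CS",
          olaparib = "DDR")
  expect_equal(categorizeCombination("venetoclax", "AZD5991", pm), "CD+CD")
  expect_equal(categorizeCombination("selumetinib", "venetoclax", pm),
               categorizeCombination("venetoclax", "selumetinib", pm))
  expect_equal(categorizeCombination("olaparib", "selumetinib", pm),
               "CS+DDR")
  expect_error(categorizeCombination("unknown", "olaparib", pm),
               "not in pathway map")

  # four pathway classes paired unordered, chemo+chemo never screened,
  # give the nine mechanism categories of the screen design
  design <- screenDesign(screenConfig(nCombinations = 18))
  expect_equal(length(unique(design$combos$category)), 9)
  expect_false("chemo+chemo" %in% design$combos$category)
})
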