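test_that("segregation tiers follow the LOD cut points and are monotone", {
  expect_identical(segregation_tier(3.4), "strong")
  expect_identical(segregation_tier(0.0), "none")
  expect_identical(segregation_tier(1.8), "moderate")
  expect_identical(segregation_tier(c(0.59, 0.6, 1.49, 1.5, 2.99, 3.0)),
                   c("none", "supporting", "supporting", "moderate",
                     "moderate", "strong"))

  lods <- seq(-1, 5, by = 0.05)
  ranks <- match(segregation_tier(lods),
                 c("none", "supporting", "moderate", "strong"))
  expect_true(all(diff(ranks) >= 0))

  expect_error(segregation_tier(NaN), class = "genevalid_input_error")
  expect_error(segregation_tier(Inf), class = "genevalid_input_error")
})

test_that("combine_criteria reproduces direct rows of the combining table", {
  expect_identical(combine_criteria(c("path_very_strong", "path_strong")),
                   "pathogenic")
  expect_identical(combine_criteria(character()), "VUS")
  expect_identical(combine_criteria(c("benign_strong", "path_strong",
                                      "path_moderate")), "VUS")
  expect_identical(combine_criteria("benign_standalone"), "benign")
  expect_identical(combine_criteria(c("benign_strong", "benign_strong")),
                   "benign")
  expect_identical(combine_criteria(c("benign_strong", "benign_supporting")),
                   "likely_benign")
  expect_identical(combine_criteria(c("path_strong", "path_moderate")),
                   "likely_pathogenic")
  expect_identical(combine_criteria(rep("path_moderate", 3)),
                   "likely_pathogenic")
  expect_identical(
    combine_criteria(c("path_very_strong", "path_moderate",
                       "path_supporting")),
    "pathogenic"
  )
  expect_identical(combine_criteria("path_supporting"), "VUS")
  expect_error(combine_criteria("definitely_pathogenic"),
               class = "genevalid_input_error")
})

test_that("combining engine agrees with the row-scan oracle (counts <= 3)", {
  grid <- all_count_grids(3)
  expect_identical(impl_verdicts(grid), oracle_verdicts(grid))
})

test_that("criterion assignment reproduces the flagship missense profile", {
  crit <- assign_criteria(wx_fixture$bundle, "MYH7_R403Q")
  expect_identical(crit$code[crit$criterion == "segregation"], "path_strong")
  expect_identical(crit$code[crit$criterion == "functional"], "path_strong")
  expect_identical(crit$code[crit$criterion == "absence_in_controls"],
                   "path_moderate")
})

test_that("functional evidence without mechanism concordance is capped", {
  crit <- assign_criteria(wx_fixture$bundle, "KCNQ1_V307L")
  fun <- crit[crit$criterion == "functional", ]
  expect_identical(fun$code, "path_supporting")
  expect_identical(fun$modulated_from, "path_strong")
})

test_that("case-count and consequence criteria are capped until links/gene are established", {
  b <- wx_fixture$bundle
  # conservative start: no status map, no link map
  crit <- assign_criteria(b, "KCNQ1_R518X")
  cc <- crit[startsWith(crit$criterion, "case_count"), ]
  expect_true(all(cc$code == "path_supporting"))
  expect_true(all(cc$modulated_from == "path_moderate"))
  cons <- crit[crit$criterion == "molecular_consequence", ]
  expect_identical(cons$code, "path_supporting")
  expect_identical(cons$modulated_from, "path_very_strong")

  # once the gene is proven and the links strong, nothing is modulated
  status <- tibble::tibble(gene = "KCNQ1", status = "proven")
  links <- tibble::tibble(gene = "KCNQ1", condition = c("LQTS", "JLNS"),
                          strength = "strong")
  crit2 <- assign_criteria(b, "KCNQ1_R518X", status, links)
  expect_identical(crit2$code[crit2$criterion == "molecular_consequence"],
                   "path_very_strong")
  expect_true(all(is.na(crit2$modulated_from)))
})

test_that("confirmed de novo in severe early-onset phenotype keeps full strength", {
  crit <- assign_criteria(wx_fixture$bundle, "KCNQ1_V141M")
  dn <- crit[crit$criterion == "de_novo", ]
  expect_identical(dn$code, "path_strong")
  expect_true(is.na(dn$modulated_from))
})

test_that("high population frequency triggers benign evidence regardless of link status", {
  crit <- assign_criteria(wx_fixture$bundle, "SCN10A_R14L")
  expect_identical(crit$code[crit$criterion == "population_frequency"],
                   "benign_strong")
})

test_that("a variant with no evidence records yields no criteria and VUS", {
  b <- evidence_bundle(
    genes = tibble::tibble(symbol = "G"),
    conditions = tibble::tibble(id = "C", inheritance = list("AD")),
    variants = tibble::tibble(id = "v", gene = "G", hgvs = "p.Ser2Leu",
                              consequence = "synonymous")
  )
  crit <- assign_criteria(b, "v")
  expect_identical(nrow(crit), 0L)
  expect_identical(classify_variant(b, "v")$verdict, "VUS")
})

test_that("unknown variant ids raise lookup errors", {
  expect_error(assign_criteria(wx_fixture$bundle, "NO_SUCH"),
               class = "genevalid_lookup_error")
  expect_error(classify_variant(wx_fixture$bundle, "NO_SUCH"),
               class = "genevalid_lookup_error")
})

test_that("modulation soundness: strong links and concordant assays emit no caps", {
  # a bundle whose every functional assay is mechanism-concordant
  b <- sweep_bundle(3)
  status <- tibble::tibble(gene = "GENE1", status = "proven")
  links <- tibble::tibble(gene = "GENE1", condition = c("C0", "C1"),
                          strength = "strong")
  crit <- genevalid:::assign_criteria_all(b, status, links)
  expect_true(all(is.na(crit$modulated_from)))
})

test_that("verdicts move monotonically with added criteria", {
  set.seed(404)
  n <- 1000
  base <- matrix(stats::rpois(n * 7, 0.8), ncol = 7)
  v0 <- verdict_rank(impl_verdicts(base))

  for (j in 1:4) {
    # adding a pathogenic-side criterion never enters or deepens the benign
    # side; the evidence-conflict rule may at most pull a verdict back to VUS
    pert <- base; pert[, j] <- pert[, j] + 1L
    expect_true(all(verdict_rank(impl_verdicts(pert)) >= pmin(v0, 3L)),
                info = paste("path tier", j))
  }
  for (j in 5:7) {
    # adding a benign-side criterion never enters or climbs the pathogenic
    # side; it may at most pull a benign-side verdict back to VUS via the
    # evidence-conflict rule
    pert <- base; pert[, j] <- pert[, j] + 1L
    expect_true(all(verdict_rank(impl_verdicts(pert)) <= pmax(v0, 3L)),
                info = paste("benign tier", j))
  }
})

test_that("classification is deterministic for identical inputs", {
  a <- classify_variants(wx_fixture$bundle)
  b <- classify_variants(wx_fixture$bundle)
  expect_identical(a, b)
})
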