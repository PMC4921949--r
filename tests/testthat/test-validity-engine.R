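# The worked-example assessment is deterministic; compute it once here.
wx_va <- assess_validity(wx_fixture$bundle)

test_that("unrelated probands are counted by distinct family ids", {
  b <- sweep_bundle(3)
  cls <- classify_variants(b, tibble::tibble(gene = "GENE1",
                                             status = "proven"))
  expect_identical(count_unrelated_probands(b, cls, "GENE1", "C0"), 3L)

  # two probands sharing a family collapse to one
  b2 <- sweep_bundle(2)
  b2$cases$family[b2$cases$condition == "C1"] <- "F_SHARED"
  cls2 <- classify_variants(b2)
  expect_identical(count_unrelated_probands(b2, cls2, "GENE1", "C1"), 1L)

  expect_error(count_unrelated_probands(b, cls, "NO_GENE", "C0"),
               class = "genevalid_lookup_error")
  expect_error(count_unrelated_probands(b, cls, "GENE1", "NO_COND"),
               class = "genevalid_lookup_error")
})

test_that("a gene with only VUS variants contributes no probands", {
  expect_identical(
    count_unrelated_probands(wx_fixture$bundle, wx_va$classifications,
                             "SCN10A", "BRUGADA"),
    0L
  )
})

test_that("gene status is proven exactly via pathogenic clinically observed variants", {
  st <- wx_va$gene_status
  expect_identical(st$status[st$gene == "MYH7"], "proven")
  expect_true("MYH7_R403Q" %in% st$proving_variants[[which(st$gene == "MYH7")]])
  expect_identical(st$status[st$gene == "SCN10A"], "uncertain")
  expect_identical(length(st$proving_variants[[which(st$gene == "SCN10A")]]),
                   0L)

  # pathogenic-classifiable evidence without any case observation
  # does not prove the gene
  b <- sweep_bundle(0)
  b$cases <- b$cases[0, ]
  va <- assess_validity(b)
  expect_identical(va$gene_status$status, "uncertain")
  cls <- va$classifications
  expect_identical(cls$verdict[cls$variant == "V1"], "pathogenic")
})

test_that("strength assignment follows the proband-count heuristic", {
  b <- sweep_bundle(3)
  va <- assess_validity(b)
  a <- va$assertions
  expect_identical(a$strength[a$condition == "C1"], "strong")

  # preliminary evidence without a pathogenic variant is 'suggested'
  gs <- generate_synthetic(synthetic_config(0, 2, seed = 3))
  va2 <- assess_validity(gs$bundle)
  expect_true(all(va2$assertions$strength == "suggested"))
  expect_true(all(va2$assertions$unrelated_proband_count == 0L))
})

test_that("the generic gene-anchored condition is strong exactly when proven", {
  b <- sweep_bundle(3)
  b$conditions <- dplyr::bind_rows(
    b$conditions,
    tibble::tibble(id = "GENE1_related", name = "GENE1-related conditions",
                   inheritance = list(character()), features = list(character()),
                   is_syndromic = FALSE, is_generic = TRUE)
  )
  va <- assess_validity(b)
  a <- va$assertions
  expect_identical(a$strength[a$condition == "GENE1_related"], "strong")

  # same gene with no pathogenic variant: generic assertion is none
  b$segregations <- b$segregations[0, ]
  b$functionals <- b$functionals[0, ]
  va2 <- assess_validity(b)
  expect_identical(
    va2$assertions$strength[va2$assertions$condition == "GENE1_related"],
    "none"
  )
})

test_that("proband-count sweep transitions none -> emerging at 1 and emerging -> strong at 3", {
  strengths <- vapply(0:10, function(k) {
    va <- assess_validity(sweep_bundle(k))
    a <- va$assertions
    s <- a$strength[a$condition == "C1"]
    if (length(s) == 0) "none" else s
  }, character(1))
  expect_identical(strengths,
                   c("none", "emerging", "emerging",
                     rep("strong", 8)))
  expect_true(all(diff(strength_rank(strengths)) >= 0))
})

test_that("adding an unrelated pathogenic-variant proband never decreases strength", {
  for (k in 0:5) {
    a1 <- assess_validity(sweep_bundle(k))$assertions
    a2 <- assess_validity(sweep_bundle(k + 1))$assertions
    for (cond in c("C0", "C1")) {
      s1 <- a1$strength[a1$condition == cond]
      s2 <- a2$strength[a2$condition == cond]
      if (length(s1) == 0) s1 <- "none"
      if (length(s2) == 0) s2 <- "none"
      expect_gte(strength_rank(s2), strength_rank(s1))
    }
  }
})

test_that("the fixed point resolves the evidence-modulation circularity", {
  # empty bundle: nothing to assess
  va0 <- assess_validity(evidence_bundle())
  expect_identical(nrow(va0$gene_status), 0L)
  expect_identical(nrow(va0$assertions), 0L)

  # the truncating founder variant needs the proven gene to escape its caps:
  # one sweep proves the gene via the de novo variant, the next one
  # reclassifies the truncation
  cls <- wx_va$classifications
  expect_identical(cls$verdict[cls$variant == "KCNQ1_R518X"], "pathogenic")
  expect_identical(cls$verdict[cls$variant == "KCNQ1_V141M"], "pathogenic")
  a <- wx_va$assertions
  expect_identical(a$strength[a$gene == "KCNQ1" & a$condition == "LQTS"],
                   "strong")
  expect_identical(a$strength[a$gene == "KCNQ1" & a$condition == "JLNS"],
                   "strong")
  expect_identical(a$strength[a$gene == "KCNQ1" & a$condition == "SQTS"],
                   "emerging")
})

test_that("fixed-point assessment converges within the gene-count bound", {
  expect_lte(wx_va$iterations, nrow(wx_fixture$bundle$genes) + 1L)
  for (seed in c(2, 12)) {
    gs <- generate_synthetic(synthetic_config(4, 4, seed = seed))
    va <- assess_validity(gs$bundle)
    expect_lte(va$iterations, nrow(gs$bundle$genes) + 1L)
  }
})

test_that("no strong or emerging assertion exists for an uncertain gene", {
  check <- function(va) {
    gus <- va$gene_status$gene[va$gene_status$status == "uncertain"]
    bad <- va$assertions$gene %in% gus &
      va$assertions$strength %in% c("strong", "emerging")
    expect_false(any(bad))
  }
  check(wx_va)
  for (seed in c(7, 17, 27)) {
    check(assess_validity(generate_synthetic(
      synthetic_config(3, 3, seed = seed))$bundle))
  }
})

test_that("compound heterozygotes count only when both alleles are pathogenic", {
  # the founder-truncation fixture: three homozygous recessive probands count;
  # the compound het whose partner allele stays VUS does not
  a <- wx_va$assertions
  expect_identical(a$unrelated_proband_count[a$gene == "KCNQ1" &
                                               a$condition == "JLNS"], 3L)
  cls <- wx_va$classifications
  expect_identical(cls$verdict[cls$variant == "KCNQ1_TRUNC2"], "VUS")
})

test_that("phenotype expansion distinguishes complex phenotypes from distinct conditions", {
  ex <- wx_va$expansion
  fhl1 <- ex[ex$gene == "FHL1", ]
  expect_identical(fhl1$flag, "complex_phenotype")

  kcnq1 <- ex[ex$gene == "KCNQ1" & ex$condition_a == "JLNS" &
                ex$condition_b == "LQTS", ]
  expect_identical(kcnq1$flag, "distinct_conditions")

  # a gene with a single condition yields no pair rows
  va1 <- assess_validity(sweep_bundle(0))
  expect_identical(nrow(va1$expansion), 0L)
})

test_that("tidy, glance and autoplot work on assessments", {
  td <- tidy(wx_va)
  expect_true(all(c("gene", "condition", "strength", "status") %in% names(td)))
  gl <- glance(wx_va)
  expect_identical(gl$n_genes, 6L)
  expect_identical(gl$n_proven, 5L)
  expect_identical(gl$n_gus, 1L)
  p <- autoplot(wx_va)
  expect_s3_class(p, "ggplot")
})

test_that("assertion matrices export in the genes-by-conditions shape", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assertion_matrix(wx_va, path)
  m <- utils::read.delim(path, check.names = FALSE)
  expect_identical(sort(m$gene), sort(wx_fixture$bundle$genes$symbol))
  expect_identical(m$HCM[m$gene == "MYH7"], "strong")
  expect_identical(m$BRUGADA[m$gene == "SCN10A"], "suggested")
  expect_identical(m$LQTS[m$gene == "MYH7"], "")
})
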