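overlap <- read_overlap_map(system.file("extdata", "cardiac_overlap.json",
                                        package = "genevalid"))
yield <- read_yield_table(system.file("extdata", "cardiac_yield.tsv",
                                      package = "genevalid"))
wx_assertions <- tidy(assess_validity(wx_fixture$bundle))

test_that("the differential includes mimicking and progressing conditions", {
  expect_setequal(differential("HCM", overlap),
                  c("HCM", "NOONAN_RASOPATHY", "FABRY"))
  expect_setequal(differential("DCM", overlap),
                  c("HCM", "DCM", "ARVD_C", "DMD_BECKER"))
  expect_error(differential("NO_SUCH", overlap),
               class = "genevalid_lookup_error")
})

test_that("panel gene classes follow strength and differential membership", {
  expect_identical(
    classify_panel_gene("MYBPC3", "HCM", wx_assertions, overlap),
    "proven_for_condition"
  )
  expect_identical(
    classify_panel_gene("SCN10A", "BRUGADA", wx_assertions, overlap),
    "suspected_for_condition"
  )
  # strong for HCM, which sits in the DCM differential
  expect_identical(
    classify_panel_gene("MYBPC3", "DCM", wx_assertions, overlap),
    "proven_for_differential"
  )
  # no relationship at all: excluded
  expect_identical(
    classify_panel_gene("SCN10A", "HCM", wx_assertions, overlap),
    NA_character_
  )
})

test_that("class precedence reports a gene once, in its strongest role", {
  a <- tibble::tibble(
    gene = c("G1", "G1"), condition = c("DCM", "HCM"),
    strength = c("strong", "strong")
  )
  expect_identical(classify_panel_gene("G1", "DCM", a, overlap),
                   "proven_for_condition")
  # suggested link to a differential condition only: excluded
  a2 <- tibble::tibble(gene = "G2", condition = "HCM",
                       strength = "suggested")
  expect_identical(classify_panel_gene("G2", "DCM", a2, overlap),
                   NA_character_)
})

test_that("panel design collects the right genes deterministically", {
  hcm <- design_panel("HCM", wx_assertions, overlap)
  expect_setequal(hcm$entries$gene, c("MYBPC3", "MYH7", "FHL1"))
  expect_true(all(hcm$entries$class == "proven_for_condition"))
  # DMD is strong only for DCM and the muscular dystrophy, neither of which
  # is in the HCM differential
  expect_false("DMD" %in% hcm$entries$gene)

  dcm <- design_panel("DCM", wx_assertions, overlap)
  expect_identical(
    dcm$entries$class[dcm$entries$gene == "DMD"],
    "proven_for_condition"
  )
  expect_identical(
    dcm$entries$class[dcm$entries$gene == "MYH7"],
    "proven_for_differential"
  )

  # idempotence and uniqueness
  dcm2 <- design_panel("DCM", wx_assertions, overlap)
  expect_identical(dcm$entries, dcm2$entries)
  expect_identical(anyDuplicated(dcm$entries$gene), 0L)

  # a target with no related genes yields an empty panel
  empty <- design_panel("UNSPECIFIED_ARRHYTHMIA",
                        tibble::tibble(gene = character(),
                                       condition = character(),
                                       strength = character()),
                        overlap)
  expect_identical(nrow(empty$entries), 0L)
})

test_that("panel validity hinges on substantial-yield genes", {
  hcm <- design_panel("HCM", wx_assertions, overlap)
  hcm <- validate_panel(hcm, yield)
  expect_identical(hcm$validity, "valid")

  # dropping the highest-yield gene invalidates the panel
  broken <- hcm
  broken$entries <- broken$entries[broken$entries$gene != "MYBPC3", ]
  broken <- validate_panel(broken, yield)
  expect_identical(broken$validity, "invalid")
  expect_identical(broken$missing_required, "MYBPC3")

  # removing every substantial gene, one at a time, flips validity
  required <- yield$gene[yield$condition == "HCM" & yield$substantial]
  for (g in required) {
    p <- hcm
    p$entries <- p$entries[p$entries$gene != g, ]
    expect_identical(validate_panel(p, yield)$validity, "invalid")
  }

  # extra suspected genes leave validity unchanged
  extra <- hcm
  extra$entries <- dplyr::bind_rows(
    extra$entries,
    tibble::tibble(gene = "SCN10A", class = "suspected_for_condition")
  )
  expect_identical(validate_panel(extra, yield)$validity, "valid")

  expect_error(validate_panel(design_panel("ARVD_C", wx_assertions, overlap),
                              yield),
               class = "genevalid_config_error")
})

test_that("finding interpretation maps class and verdict to clinical guidance", {
  expect_identical(interpret_result("proven_for_condition", "pathogenic"),
                   "diagnostic_actionable")
  expect_identical(interpret_result("proven_for_condition",
                                    "likely_pathogenic"),
                   "diagnostic_actionable")
  expect_identical(interpret_result("proven_for_condition", "VUS"),
                   "segregation_studies_suggested")
  expect_identical(interpret_result("proven_for_differential", "pathogenic"),
                   "expansion_or_incidental")
  expect_identical(interpret_result("proven_for_differential", "VUS"),
                   "clinical_rereview_suggested")
  expect_identical(interpret_result("suspected_for_condition", "pathogenic"),
                   "research_hold")
  expect_identical(interpret_result("suspected_for_condition", "VUS"),
                   "research_hold")
  expect_identical(interpret_result("proven_for_condition", "benign"),
                   "no_action")
})

test_that("panel round-trips through JSON and tidies", {
  hcm <- validate_panel(design_panel("HCM", wx_assertions, overlap), yield)
  path <- withr::local_tempfile(fileext = ".json")
  write_panel(hcm, path)
  raw <- jsonlite::read_json(path)
  expect_identical(raw$target, "HCM")
  expect_identical(raw$validity, "valid")

  td <- tidy(hcm)
  expect_identical(unique(td$target), "HCM")
  gl <- glance(hcm)
  expect_identical(gl$n_proven, 3L)
  expect_s3_class(autoplot(hcm), "ggplot")
})
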