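Package: genevalid
Title: Clinical Validity of Gene-Condition Relationships from Structured
    Variant Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic rules engine for clinical genetic test curation.
    Classifies clinically observed variants into the five-level pathogenicity
    scale from structured evidence (segregation, case observations, functional
    assays, population frequencies) using ACMG-style criterion combining rules
    with evidence modulation tied to gene-level status; derives gene-level
    clinical validity and gene-condition strength assertions (strong, emerging,
    suggested, or gene of uncertain significance) as the fixed point of the
    mutually dependent variant- and gene-level assessments; assesses phenotype
    expansion for genes asserted against multiple conditions; and designs and
    validates condition-targeted diagnostic gene panels over overlapping
    clinical presentations, with clinical-utility guidance per finding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
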