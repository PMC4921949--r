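# genevalid

A deterministic rules engine for establishing the **clinical validity of
gene–condition relationships** from structured variant-level evidence, with
diagnostic gene-panel design over overlapping clinical presentations. The
package is aimed at clinical-genetics curation teams (diagnostic labs,
panel designers) and at anyone who wants a reproducible, auditable
implementation of variant-centric gene curation.

## The method

The core insight is that gene-level validity reduces to variant-level
pathogenicity: *a gene causes human disease because at least one variant in
the gene causes human disease.* The package therefore implements three
coupled layers:

1. **Variant classification.** Structured evidence — segregation data,
   unrelated case observations, de novo occurrence, functional assays,
   population allele frequencies, molecular consequence — is mapped onto
   ACMG-style weighted criteria (pathogenic: very strong / strong /
   moderate / supporting; benign: stand-alone / strong / supporting) and
   combined by a fixed table into one of five verdicts
   (pathogenic / likely pathogenic / VUS / likely benign / benign).
   Segregation is tiered by LOD score (≥ 3.0 strong, ≥ 1.5 moderate,
   ≥ 0.6 supporting). Evidence of tangential relevance is *modulated*:
   case-count evidence is capped at supporting until the specific
   gene–condition relationship is strong, molecular-consequence evidence is
   capped until the gene itself is proven, and functional evidence is
   capped unless the assay demonstrates the disease-relevant mechanism.

2. **Gene–condition strength.** A gene is **proven** when at least one
   clinically observed variant classifies pathogenic; otherwise it is a
   **gene of uncertain significance (GUS)**. A specific gene–condition
   relationship is **strong** at ≥ 3 unrelated probands carrying a
   pathogenic variant and manifesting the condition, **emerging** at 1–2
   such probands in a proven gene, and **suggested** when only preliminary
   evidence links the pair. Because classification is modulated by gene
   status and link strength, and those derive from classifications, the
   joint assessment is computed as the **fixed point** of a monotone update
   from the maximally conservative start (`assess_validity()`).

3. **Panel design.** A panel targeted at a condition contains genes proven
   for the condition, genes suspected for it, and genes proven for a
   condition in its clinical differential (conditions that can mimic or
   progress to the target, e.g. Fabry disease presenting as HCM). A panel
   is *invalid* if it omits a gene accounting for a substantial share of
   the diagnostic yield. Each finding maps to clinical-utility guidance
   (`interpret_result()`).

## Worked example

The package ships a curated evidence bundle of six cardiac genes
(`worked_examples()`), plus a synthetic-bundle generator with known ground
truth (`generate_synthetic()`).

```r
library(genevalid)

wx <- worked_examples()
va <- assess_validity(wx$bundle)
va
#> <validity_assessment>
#>   6 genes (5 proven, 1 uncertain), 45 variants, 10 assertions; 2 sweep(s)
#> # A tibble: 10 × 5
#>    gene   condition  strength  unrelated_proband_count expansion_flag
#>  1 DMD    DCM        strong                          6 not_applicable
#>  2 DMD    DMD_BECKER emerging                        1 not_applicable
#>  3 FHL1   EDMD       strong                          3 complex_phenotype
#>  4 FHL1   HCM        strong                          6 complex_phenotype
#>  5 KCNQ1  JLNS       strong                          3 distinct_conditions
#>  6 KCNQ1  LQTS       strong                          4 distinct_conditions
#>  7 KCNQ1  SQTS       emerging                        1 distinct_conditions
#>  8 MYBPC3 HCM        strong                          3 not_applicable
#>  9 MYH7   HCM        strong                          5 not_applicable
#> 10 SCN10A BRUGADA    suggested                       0 not_applicable
```

Reading the table: MYH7–HCM is proven through the p.Arg403Gln variant
(four-family combined LOD 3.4, concordant functional and animal-model data,
absence from controls, five unrelated probands). KCNQ1 is proven for two
distinct conditions — the recessive deaf–arrhythmia syndrome (biallelic
probands) and long QT (heterozygous carriers) — while its short-QT link
rests on a single de novo case and stays *emerging*. SCN10A, with ~30
case-report missense variants that all remain VUS, stays a gene of
uncertain significance, its Brugada link *suggested*. The two syndromic
genes (DMD, FHL1) are proven for their isolated cardiomyopathies through
unrelated probands without muscular-dystrophy features.

Variant-level provenance is kept end to end:

```r
cls <- classify_variant(wx$bundle, "SCN10A_R14L",
                        gene_status = va$gene_status,
                        link_strength = va$assertions)
cls$verdict
#> [1] "VUS"
cls$criteria[[1]][, c("criterion", "code", "modulated_from")]
#> # A tibble: 3 × 3
#>   criterion            code            modulated_from
#> 1 case_count:BRUGADA   path_supporting path_moderate
#> 2 functional           path_supporting path_strong
#> 3 population_frequency benign_strong   <NA>
```

Four Brugada probands and an in-vitro effect, down-weighted because the
gene is unproven, cannot outweigh hundreds of reference-population alleles:
the variant stays VUS, and so the gene stays unproven — exactly the
conservative behaviour the modulation cautions are designed to enforce.

Panels are designed from the tidy assertion table:

```r
overlap <- read_overlap_map(system.file("extdata", "cardiac_overlap.json",
                                        package = "genevalid"))
yield <- read_yield_table(system.file("extdata", "cardiac_yield.tsv",
                                      package = "genevalid"))
hcm <- validate_panel(design_panel("HCM", tidy(va), overlap), yield)
glance(hcm)
#> # A tibble: 1 × 7
#>   target n_genes n_proven n_suspected n_differential validity n_missing_required
#> 1 HCM          3        3           0              0 valid                     0
```

`tidy()`, `glance()`, and `autoplot()` methods are provided for both
assessments and panels; a command-line front end
(`system.file("cli", "genevalid.R", package = "genevalid")`) exposes
`classify`, `assess`, `panel`, and `fixtures` subcommands over bundle JSON
files.

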