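#' Rule thresholds for classification and validity assessment
#'
#' All numeric cut points used by the rules engine live in one object so that
#' every judgement is auditable and overridable. Defaults follow standard
#' practice in clinical variant interpretation; each is documented below with
#' its unit and rationale.
#'
#' @param seg_strong,seg_moderate,seg_supporting LOD-score (log10 odds) cut
#'   points for segregation evidence tiers. A combined LOD of 3.0 is the
#'   classical genome-wide linkage significance bound and admits segregation as
#'   strong pathogenic evidence; 1.5 and 0.6 are conventional halvings for
#'   moderate and supporting.
#' @param benign_af Allele frequency above which (together with
#'   `benign_min_count`) a population observation is strong benign evidence.
#'   Default `5e-4`, appropriate for rare, penetrant cardiac conditions;
#'   raise it for more prevalent conditions.
#' @param benign_min_count Minimum allele count required alongside `benign_af`,
#'   guarding against frequency estimates built on one or two alleles.
#' @param absent_min_an Minimum cohort allele number for "absent from healthy
#'   controls" (allele count 0) to count as moderate pathogenic evidence.
#' @param case_count_min Number of unrelated probands with a specific matching
#'   phenotype required for the case-count criterion (moderate), and equally
#'   the proband count at which a gene-condition relationship becomes strong.
#' @param phenotype_match Fraction of a condition's feature tokens that must
#'   appear in a case's phenotype features for the case to count as
#'   manifesting that condition when the condition ids differ.
#' @param yield_threshold Fraction of diagnostic yield above which a gene in a
#'   yield table is treated as substantial when no curated flag is given.
#'
#' @return A list of class `genevalid_config`.
#' @examples
#' cfg <- rules_config(benign_af = 1e-3)
#' cfg$benign_af
#' @export
rules_config <- function(seg_strong = 3.0,
                         seg_moderate = 1.5,
                         seg_supporting = 0.6,
                         benign_af = 5e-4,
                         benign_min_count = 5L,
                         absent_min_an = 10000L,
                         case_count_min = 3L,
                         phenotype_match = 0.6,
                         yield_threshold = 0.05) {
  stopifnot(
    seg_strong >= seg_moderate, seg_moderate >= seg_supporting,
    seg_supporting > 0,
    benign_af > 0, benign_af < 1,
    benign_min_count >= 1, absent_min_an >= 1,
    case_count_min >= 1,
    phenotype_match > 0, phenotype_match <= 1,
    yield_threshold >= 0, yield_threshold <= 1
  )
  structure(
    list(
      seg_strong = seg_strong,
      seg_moderate = seg_moderate,
      seg_supporting = seg_supporting,
      benign_af = benign_af,
      benign_min_count = as.integer(benign_min_count),
      absent_min_an = as.integer(absent_min_an),
      case_count_min = as.integer(case_count_min),
      phenotype_match = phenotype_match,
      yield_threshold = yield_threshold
    ),
    class = "genevalid_config"
  )
}

#' @export
print.genevalid_config <- function(x, ...) {
  cat("<genevalid rules configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_rules_config <- function(config) {
  if (is.null(config)) return(rules_config())
  if (inherits(config, "genevalid_config")) return(config)
  if (is.list(config)) return(do.call(rules_config, config))
  abort("`config` must be NULL, a rules_config(), or a named list of overrides.")
}
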