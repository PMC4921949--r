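# Closed vocabularies for the evidence model. Every enum field is validated
# against these; serialization writes the bare strings.

#' Closed vocabularies used by the evidence model
#'
#' @format A named list of character vectors: one entry per enum-valued field
#'   of the evidence bundle.
#' @export
evidence_vocab <- list(
  preliminary_kind = c("case_series_vus_only", "linkage_only",
                       "functional_only", "animal_only"),
  inheritance   = c("AD", "AR", "XL"),
  consequence   = c("missense", "nonsense", "frameshift", "splice",
                    "exonic_deletion", "synonymous", "other"),
  severity      = c("mild", "classic", "severe"),
  onset         = c("infantile", "childhood", "adult"),
  de_novo       = c("none", "assumed", "confirmed_parentage"),
  zygosity      = c("het", "hom", "compound_het"),
  assay         = c("biochemical", "cellular", "animal_model"),
  effect        = c("loss_of_function", "gain_of_function", "no_effect")
)

# Empty, correctly typed collection prototypes. List-columns hold per-record
# character vectors (aliases, phenotype_features, features) or nested tibbles
# (preliminary_links).
bundle_prototypes <- function() {
  list(
    genes = tibble(
      symbol = character(), aliases = list(),
      preliminary_links = list()
    ),
    conditions = tibble(
      id = character(), name = character(), inheritance = list(),
      features = list(), is_syndromic = logical(), is_generic = logical()
    ),
    variants = tibble(
      id = character(), gene = character(), hgvs = character(),
      consequence = character(), in_silico_support = logical()
    ),
    cases = tibble(
      variant = character(), proband = character(), family = character(),
      condition = character(), phenotype_features = list(),
      severity = character(), onset = character(), de_novo = character(),
      zygosity = character()
    ),
    segregations = tibble(
      variant = character(), family = character(), lod = double(),
      families = integer(), condition = character()
    ),
    functionals = tibble(
      variant = character(), assay = character(), effect = character(),
      mechanism_concordant = logical()
    ),
    populations = tibble(
      variant = character(), cohort = character(),
      allele_count = integer(), allele_number = integer()
    )
  )
}

collection_names <- c("genes", "conditions", "variants", "cases",
                      "segregations", "functionals", "populations")

generic_condition_id <- function(symbol) paste0(symbol, "_related")

#' Construct an evidence bundle
#'
#' An evidence bundle is the complete structured evidence store the rules
#' engine consumes: genes, conditions, clinically observed variants, case
#' observations, segregation data, functional-assay data, and population
#' frequencies, as seven cross-referencing tibbles. Missing collections
#' default to empty; every supplied collection is coerced to the prototype
#' column set and the whole bundle is validated (`validate_bundle()`).
#'
#' @param genes Tibble with columns `symbol`, `aliases` (list of character),
#'   `preliminary_links` (list of tibbles with columns `condition`, `kind`).
#' @param conditions Tibble with `id`, `name`, `inheritance` (list of subsets
#'   of AD/AR/XL), `features` (list of character phenotype tokens),
#'   `is_syndromic`, `is_generic`.
#' @param variants Tibble with `id`, `gene`, `hgvs`, `consequence`, and
#'   optional `in_silico_support` (pre-tagged computational support flag).
#' @param cases Tibble of case observations: `variant`, `proband`, `family`,
#'   `condition`, `phenotype_features` (list), `severity`, `onset`, `de_novo`,
#'   `zygosity`. Distinct family ids define unrelatedness.
#' @param segregations Tibble with `variant`, `family`, `lod` (log10 odds,
#'   possibly a combined multi-family value), `families` (family count >= 1),
#'   `condition`.
#' @param functionals Tibble with `variant`, `assay`, `effect`,
#'   `mechanism_concordant` (assay demonstrates the disease-relevant
#'   mechanism).
#' @param populations Tibble with `variant`, `cohort`, `allele_count`,
#'   `allele_number`.
#'
#' @return A validated object of class `evidence_bundle` (a named list of
#'   seven tibbles).
#' @examples
#' b <- evidence_bundle(
#'   genes = tibble::tibble(symbol = "MYH7"),
#'   conditions = tibble::tibble(id = "HCM", name = "Hypertrophic cardiomyopathy"),
#'   variants = tibble::tibble(id = "v1", gene = "MYH7", hgvs = "p.Arg403Gln",
#'                             consequence = "missense")
#' )
#' b
#' @export
evidence_bundle <- function(genes = NULL, conditions = NULL, variants = NULL,
                            cases = NULL, segregations = NULL,
                            functionals = NULL, populations = NULL) {
  proto <- bundle_prototypes()
  supplied <- list(genes = genes, conditions = conditions, variants = variants,
                   cases = cases, segregations = segregations,
                   functionals = functionals, populations = populations)
  out <- purrr::imap(proto, function(p, nm) {
    coerce_collection(supplied[[nm]], p, nm)
  })
  bundle <- structure(out, class = "evidence_bundle")
  validate_bundle(bundle)
}

# Fill in missing columns with typed defaults and order columns as the
# prototype; scalar list-column entries are normalised to character(0)/NULL.
coerce_collection <- function(x, proto, name) {
  if (is.null(x)) return(proto)
  x <- as_tibble(x)
  for (col in names(proto)) {
    if (!col %in% names(x)) {
      x[[col]] <- default_column(col, nrow(x), proto[[col]])
    }
  }
  extra <- setdiff(names(x), names(proto))
  if (length(extra) > 0) {
    abort(sprintf("Unknown column(s) in `%s`: %s", name,
                  paste(extra, collapse = ", ")))
  }
  x <- x[names(proto)]
  for (col in names(proto)) {
    if (is.list(proto[[col]]) && !is.list(x[[col]])) {
      x[[col]] <- as.list(x[[col]])
    }
    # boolean flags default FALSE even when bind_rows left NAs behind
    if (is.logical(proto[[col]]) && anyNA(x[[col]])) {
      x[[col]][is.na(x[[col]])] <- FALSE
    }
  }
  x
}

default_column <- function(col, n, proto_col) {
  if (is.list(proto_col)) {
    if (col == "preliminary_links") {
      rep(list(tibble(condition = character(), kind = character())), n)
    } else {
      rep(list(character()), n)
    }
  } else {
    switch(col,
      in_silico_support = rep(FALSE, n),
      is_syndromic = rep(FALSE, n),
      is_generic = rep(FALSE, n),
      families = rep(1L, n),
      name = rep(NA_character_, n),
      rep(vctrs_na(proto_col), n)
    )
  }
}

vctrs_na <- function(proto_col) {
  if (is.character(proto_col)) NA_character_
  else if (is.integer(proto_col)) NA_integer_
  else if (is.double(proto_col)) NA_real_
  else NA
}

validation_error <- function(fmt, ...) {
  abort(sprintf(fmt, ...), class = "genevalid_validation_error")
}

integrity_error <- function(fmt, ...) {
  abort(sprintf(fmt, ...), class = c("genevalid_integrity_error",
                                     "genevalid_validation_error"))
}

check_enum <- function(values, vocab_name, collection, field, ids) {
  vocab <- evidence_vocab[[vocab_name]]
  bad <- !is.na(values) & !values %in% vocab
  if (any(bad)) {
    validation_error(
      "Invalid `%s` in `%s` for record '%s': '%s' (allowed: %s)",
      field, collection, ids[which(bad)[1]], values[which(bad)[1]],
      paste(vocab, collapse = ", ")
    )
  }
}

check_resolves <- function(refs, universe, collection, field, ids) {
  bad <- !is.na(refs) & !refs %in% universe
  if (any(bad)) {
    i <- which(bad)[1]
    integrity_error(
      "Dangling reference in `%s`: field `%s` of record '%s' refers to unknown id '%s'",
      collection, field, ids[i], refs[i]
    )
  }
}

#' Validate an evidence bundle
#'
#' Checks every invariant of the evidence model: non-empty unique ids, closed
#' enumerations, referential integrity across all seven collections, HGVS
#' token syntax, LOD finiteness, allele count consistency, and the one
#' generic condition per gene rule. Errors name the offending collection,
#' field, and record id.
#'
#' @param bundle An `evidence_bundle`.
#' @return The bundle, invisibly classed, if valid; otherwise an error of
#'   class `genevalid_validation_error` (dangling references additionally
#'   carry class `genevalid_integrity_error`).
#' @export
validate_bundle <- function(bundle) {
  stopifnot(is.list(bundle), all(collection_names %in% names(bundle)))
  g <- bundle$genes; co <- bundle$conditions; v <- bundle$variants
  ca <- bundle$cases; se <- bundle$segregations; fu <- bundle$functionals
  po <- bundle$populations

  if (any(is.na(g$symbol) | g$symbol == "")) {
    validation_error("Gene `symbol` must be non-empty.")
  }
  if (anyDuplicated(g$symbol)) {
    validation_error("Duplicate gene symbol: '%s'",
                     g$symbol[duplicated(g$symbol)][1])
  }
  for (i in seq_len(nrow(g))) {
    pl <- g$preliminary_links[[i]]
    if (length(pl) == 0) next
    pl <- as_tibble(pl)
    check_enum(pl$kind, "preliminary_kind", "genes", "preliminary_links$kind",
               rep(g$symbol[i], nrow(pl)))
    check_resolves(pl$condition, co$id, "genes", "preliminary_links$condition",
                   rep(g$symbol[i], nrow(pl)))
  }

  if (anyDuplicated(co$id)) {
    validation_error("Duplicate condition id: '%s'", co$id[duplicated(co$id)][1])
  }
  for (i in seq_len(nrow(co))) {
    inh <- unlist(co$inheritance[[i]])
    check_enum(inh, "inheritance", "conditions", "inheritance",
               rep(co$id[i], max(1, length(inh))))
  }
  gen <- co$id[co$is_generic]
  expected <- generic_condition_id(g$symbol)
  if (any(!gen %in% expected)) {
    validation_error(
      "Generic condition '%s' is not named '<gene symbol>_related' for any bundle gene.",
      gen[!gen %in% expected][1]
    )
  }
  if (anyDuplicated(gen)) {
    validation_error("More than one generic condition for a gene: '%s'",
                     gen[duplicated(gen)][1])
  }

  if (anyDuplicated(v$id)) {
    validation_error("Duplicate variant id: '%s'", v$id[duplicated(v$id)][1])
  }
  check_resolves(v$gene, g$symbol, "variants", "gene", v$id)
  check_enum(v$consequence, "consequence", "variants", "consequence", v$id)
  bad_hgvs <- !is.na(v$hgvs) & !grepl("^[cpgmnr]\\.\\S+$", v$hgvs)
  if (any(bad_hgvs)) {
    validation_error("Variant '%s' has malformed hgvs token '%s'",
                     v$id[bad_hgvs][1], v$hgvs[bad_hgvs][1])
  }

  check_resolves(ca$variant, v$id, "cases", "variant", ca$proband)
  check_resolves(ca$condition, co$id, "cases", "condition", ca$proband)
  check_enum(ca$severity, "severity", "cases", "severity", ca$proband)
  check_enum(ca$onset, "onset", "cases", "onset", ca$proband)
  check_enum(ca$de_novo, "de_novo", "cases", "de_novo", ca$proband)
  check_enum(ca$zygosity, "zygosity", "cases", "zygosity", ca$proband)

  check_resolves(se$variant, v$id, "segregations", "variant", se$variant)
  check_resolves(se$condition, co$id, "segregations", "condition", se$variant)
  if (any(!is.finite(se$lod))) {
    validation_error("Non-finite LOD for segregation datum on variant '%s'",
                     se$variant[!is.finite(se$lod)][1])
  }
  if (any(se$families < 1L)) {
    validation_error("Segregation family count < 1 on variant '%s'",
                     se$variant[se$families < 1L][1])
  }

  check_resolves(fu$variant, v$id, "functionals", "variant", fu$variant)
  check_enum(fu$assay, "assay", "functionals", "assay", fu$variant)
  check_enum(fu$effect, "effect", "functionals", "effect", fu$variant)

  check_resolves(po$variant, v$id, "populations", "variant", po$variant)
  if (any(po$allele_number <= 0L)) {
    validation_error("Allele number must be positive (variant '%s')",
                     po$variant[po$allele_number <= 0L][1])
  }
  if (any(po$allele_count < 0L | po$allele_count > po$allele_number)) {
    validation_error("Allele count outside [0, allele_number] (variant '%s')",
                     po$variant[po$allele_count < 0L |
                                po$allele_count > po$allele_number][1])
  }

  structure(bundle, class = "evidence_bundle")
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("<evidence_bundle>\n")
  for (nm in collection_names) {
    cat(sprintf("  %-13s %d record%s\n", nm, nrow(x[[nm]]),
                if (nrow(x[[nm]]) == 1) "" else "s"))
  }
  invisible(x)
}

#' Compare two evidence bundles structurally
#'
#' Row order within collections is immaterial; list-column contents are
#' compared element-wise after sorting rows on their identifying fields.
#'
#' @param a,b Evidence bundles.
#' @return TRUE or FALSE.
#' @export
bundles_equal <- function(a, b) {
  key_cols <- list(genes = "symbol", conditions = "id", variants = "id",
                   cases = c("variant", "proband"),
                   segregations = c("variant", "family"),
                   functionals = c("variant", "assay"),
                   populations = c("variant", "cohort"))
  for (nm in collection_names) {
    ta <- dplyr::arrange(a[[nm]], dplyr::across(dplyr::all_of(key_cols[[nm]])))
    tb <- dplyr::arrange(b[[nm]], dplyr::across(dplyr::all_of(key_cols[[nm]])))
    ta <- normalise_lists(ta)
    tb <- normalise_lists(tb)
    if (!isTRUE(all.equal(ta, tb, check.attributes = FALSE))) return(FALSE)
  }
  TRUE
}

normalise_lists <- function(tb) {
  for (col in names(tb)) {
    if (is.list(tb[[col]])) {
      tb[[col]] <- lapply(tb[[col]], function(el) {
        if (is.data.frame(el)) {
          el <- as_tibble(el)
          el[order(do.call(paste, el)), , drop = FALSE]
        } else {
          sort(as.character(unlist(el) %||% character()))
        }
      })
    }
  }
  tb
}
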