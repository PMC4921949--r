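# JSON serialization of evidence bundles. The on-disk dialect is an object
# with the seven collection keys, each an array of records; list-valued
# fields become JSON arrays and nested preliminary links become arrays of
# {condition, kind} objects. The shipped schema file documents the dialect:
# system.file("extdata", "bundle-schema.json", package = "genevalid").

#' Read an evidence bundle from JSON
#'
#' @param path Path to a bundle JSON file (UTF-8, top-level keys `genes`,
#'   `conditions`, `variants`, `cases`, `segregations`, `functionals`,
#'   `populations`; any key may be absent or empty).
#' @return A validated [evidence_bundle()].
#' @seealso [write_bundle()] for the inverse; round-tripping is the identity
#'   on valid bundles.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such bundle file: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(raw)) validation_error("Bundle file is not a JSON object: '%s'", path)
  unknown <- setdiff(names(raw), collection_names)
  if (length(unknown) > 0) {
    validation_error("Unknown top-level key(s) in bundle file: %s",
                     paste(unknown, collapse = ", "))
  }
  records <- function(key) raw[[key]] %||% list()
  chr1 <- function(rec, f, default = NA_character_) {
    val <- rec[[f]]
    if (is.null(val)) default else as.character(val)
  }
  chrs <- function(rec, f) as.character(unlist(rec[[f]]) %||% character())

  genes <- purrr::map(records("genes"), function(r) {
    pl <- r$preliminary_links %||% list()
    pl_tb <- tibble(
      condition = purrr::map_chr(pl, ~ chr1(.x, "condition")),
      kind = purrr::map_chr(pl, ~ chr1(.x, "kind"))
    )
    tibble(symbol = chr1(r, "symbol"), aliases = list(chrs(r, "aliases")),
           preliminary_links = list(pl_tb))
  }) |> bind_rows()

  conditions <- purrr::map(records("conditions"), function(r) {
    tibble(id = chr1(r, "id"), name = chr1(r, "name"),
           inheritance = list(chrs(r, "inheritance")),
           features = list(chrs(r, "features")),
           is_syndromic = isTRUE(r$is_syndromic),
           is_generic = isTRUE(r$is_generic))
  }) |> bind_rows()

  variants <- purrr::map(records("variants"), function(r) {
    tibble(id = chr1(r, "id"), gene = chr1(r, "gene"), hgvs = chr1(r, "hgvs"),
           consequence = chr1(r, "consequence"),
           in_silico_support = isTRUE(r$in_silico_support))
  }) |> bind_rows()

  cases <- purrr::map(records("cases"), function(r) {
    tibble(variant = chr1(r, "variant"), proband = chr1(r, "proband"),
           family = chr1(r, "family"), condition = chr1(r, "condition"),
           phenotype_features = list(chrs(r, "phenotype_features")),
           severity = chr1(r, "severity"), onset = chr1(r, "onset"),
           de_novo = chr1(r, "de_novo", "none"),
           zygosity = chr1(r, "zygosity", "het"))
  }) |> bind_rows()

  segregations <- purrr::map(records("segregations"), function(r) {
    tibble(variant = chr1(r, "variant"), family = chr1(r, "family"),
           lod = as.numeric(r$lod %||% NA_real_),
           families = as.integer(r$families %||% 1L),
           condition = chr1(r, "condition"))
  }) |> bind_rows()

  functionals <- purrr::map(records("functionals"), function(r) {
    tibble(variant = chr1(r, "variant"), assay = chr1(r, "assay"),
           effect = chr1(r, "effect"),
           mechanism_concordant = isTRUE(r$mechanism_concordant))
  }) |> bind_rows()

  populations <- purrr::map(records("populations"), function(r) {
    tibble(variant = chr1(r, "variant"), cohort = chr1(r, "cohort"),
           allele_count = as.integer(r$allele_count %||% NA_integer_),
           allele_number = as.integer(r$allele_number %||% NA_integer_))
  }) |> bind_rows()

  evidence_bundle(genes = genes, conditions = conditions, variants = variants,
                  cases = cases, segregations = segregations,
                  functionals = functionals, populations = populations)
}

#' Write an evidence bundle to JSON
#'
#' @param bundle A validated [evidence_bundle()].
#' @param path Output path.
#' @return `path`, invisibly. `read_bundle(write_bundle(b, p))` is
#'   structurally equal to `b` ([bundles_equal()]).
#' @export
write_bundle <- function(bundle, path) {
  bundle <- validate_bundle(bundle)
  row_records <- function(tb) {
    list_cols <- names(tb)[vapply(tb, is.list, logical(1))]
    purrr::pmap(tb, function(...) {
      rec <- list(...)
      purrr::imap(rec, function(val, nm) {
        if (is.data.frame(val)) {
          purrr::pmap(val, function(...) list(...))
        } else if (nm %in% list_cols) {
          as.list(unlist(val) %||% character())
        } else {
          val
        }
      })
    })
  }
  out <- purrr::map(bundle[collection_names], row_records)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tryCatch(
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE),
    error = function(e) abort(sprintf("Cannot write bundle to '%s': %s",
                                      path, conditionMessage(e)))
  )
  invisible(path)
}
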