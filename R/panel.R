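# Diagnostic panel assembly over overlapping clinical presentations. A panel
# targeted at one condition carries three classes of genes: proven for the
# condition, suspected (emerging/suggested) for the condition, and proven for
# a condition in the clinical differential (conditions whose true presentation
# can mimic, progress to, or syndromically include the target). Panel validity
# requires every gene accounting for a substantial share of the diagnostic
# yield to be present.

panel_classes <- c("proven_for_condition", "suspected_for_condition",
                   "proven_for_differential")

#' Read a clinical-overlap map from JSON
#'
#' The overlap map sends each presenting feature/condition token to the set
#' of true underlying conditions it may represent. A curated cardiac map
#' mirroring common cardiomyopathy/arrhythmia overlaps ships with the
#' package: `system.file("extdata", "cardiac_overlap.json",
#' package = "genevalid")`. The map is a data file, deliberately editable,
#' and not meant to be comprehensive.
#'
#' @param path JSON file: object mapping condition token -> array of
#'   condition tokens.
#' @return Named list of character vectors.
#' @export
read_overlap_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such overlap map: '%s'", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  purrr::map(raw, as.character)
}

#' The clinical differential of a target condition
#'
#' @param condition Target condition token, present in the map.
#' @param overlap_map Named list from [read_overlap_map()].
#' @return Character vector: the target plus every condition whose true
#'   presentation can mimic or progress to it.
#' @examples
#' m <- read_overlap_map(system.file("extdata", "cardiac_overlap.json",
#'                                   package = "genevalid"))
#' differential("HCM", m)
#' @export
differential <- function(condition, overlap_map) {
  if (!condition %in% names(overlap_map)) {
    abort(sprintf("Condition '%s' absent from overlap map", condition),
          class = "genevalid_lookup_error")
  }
  union(condition, overlap_map[[condition]])
}

#' Classify one gene's role on a condition-targeted panel
#'
#' Precedence: `proven_for_condition` (strong assertion for the target) over
#' `suspected_for_condition` (emerging or suggested for the target) over
#' `proven_for_differential` (strong for some other condition in the target's
#' differential). A gene with only suggested links to a differential
#' condition is excluded (`NA`): the differential class requires conclusive
#' proof.
#'
#' @param gene Gene symbol.
#' @param condition Target condition token.
#' @param assertions Assertion tibble (columns `gene`, `condition`,
#'   `strength`), e.g. `tidy(assess_validity(bundle))`.
#' @param overlap_map Named list from [read_overlap_map()].
#' @return One of the three class labels, or `NA_character_` if excluded.
#' @export
classify_panel_gene <- function(gene, condition, assertions, overlap_map) {
  a <- filter(assertions, .data$gene == !!gene)
  strength_for <- function(cond) {
    s <- a$strength[a$condition == cond]
    if (length(s) == 0) "none" else s[1]
  }
  target_strength <- strength_for(condition)
  if (target_strength == "strong") return("proven_for_condition")
  if (target_strength %in% c("emerging", "suggested")) {
    return("suspected_for_condition")
  }
  diff <- setdiff(differential(condition, overlap_map), condition)
  if (any(a$strength == "strong" & a$condition %in% diff)) {
    return("proven_for_differential")
  }
  NA_character_
}

#' Assemble a condition-targeted gene panel
#'
#' Includes every gene classifiable into one of the three panel classes, in
#' deterministic order (class, then symbol). The returned panel is
#' unvalidated; run [validate_panel()] against a yield table to fill in
#' validity.
#'
#' @param condition Target condition token (must be in the overlap map).
#' @param assertions Assertion tibble (columns `gene`, `condition`,
#'   `strength`).
#' @param overlap_map Named list from [read_overlap_map()].
#' @return An object of class `panel_spec`: list with `target`, `entries`
#'   (tibble `gene`, `class`), `validity` (`NA` until validated),
#'   `missing_required`.
#' @examples
#' va <- assess_validity(worked_examples()$bundle)
#' m <- read_overlap_map(system.file("extdata", "cardiac_overlap.json",
#'                                   package = "genevalid"))
#' design_panel("HCM", tidy(va), m)
#' @export
design_panel <- function(condition, assertions, overlap_map) {
  if (!condition %in% names(overlap_map)) {
    abort(sprintf("Condition '%s' absent from overlap map", condition),
          class = "genevalid_lookup_error")
  }
  genes <- sort(unique(assertions$gene))
  cls <- purrr::map_chr(genes, classify_panel_gene, condition = condition,
                        assertions = assertions, overlap_map = overlap_map)
  entries <- tibble(gene = genes, class = cls) |>
    filter(!is.na(.data$class)) |>
    mutate(class = factor(.data$class, levels = panel_classes)) |>
    arrange(.data$class, .data$gene) |>
    mutate(class = as.character(.data$class))
  structure(
    list(target = condition, entries = entries, validity = NA_character_,
         missing_required = character()),
    class = "panel_spec"
  )
}

#' Read a yield table from TSV
#'
#' Columns: `gene`, `condition`, `substantial` (logical flag curated from the
#' literature), optional `yield_fraction` in `[0,1]`. A curated cardiac table
#' ships at `system.file("extdata", "cardiac_yield.tsv", package =
#' "genevalid")`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_yield_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such yield table: '%s'", path))
  yt <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE) |>
    as_tibble()
  if (!all(c("gene", "condition", "substantial") %in% names(yt))) {
    abort("Yield table needs columns gene, condition, substantial.")
  }
  yt$substantial <- as.logical(yt$substantial)
  if ("yield_fraction" %in% names(yt)) {
    bad <- !is.na(yt$yield_fraction) &
      (yt$yield_fraction < 0 | yt$yield_fraction > 1)
    if (any(bad)) abort("yield_fraction outside [0,1].")
  }
  yt
}

#' Validate a panel against a yield table
#'
#' A panel is invalid exactly when it omits a gene that accounts for a
#' substantial proportion of the known genetic risk for the target condition.
#' "Substantial" is the curated boolean flag; when the flag is missing for a
#' row, a `yield_fraction` at or above `config$yield_threshold` substitutes.
#' Extra suspected-only genes never affect validity.
#'
#' @param panel A `panel_spec` from [design_panel()].
#' @param yield_table Tibble from [read_yield_table()].
#' @param config Optional [rules_config()].
#' @return The panel with `validity` (`"valid"`/`"invalid"`) and
#'   `missing_required` filled in.
#' @export
validate_panel <- function(panel, yield_table, config = NULL) {
  cfg <- as_rules_config(config)
  yt <- filter(yield_table, .data$condition == panel$target)
  if (nrow(yt) == 0) {
    abort(sprintf("Yield table has no rows for condition '%s'", panel$target),
          class = "genevalid_config_error")
  }
  substantial <- yt$substantial
  if ("yield_fraction" %in% names(yt)) {
    substantial <- ifelse(is.na(substantial),
                          !is.na(yt$yield_fraction) &
                            yt$yield_fraction >= cfg$yield_threshold,
                          substantial)
  }
  required <- yt$gene[isTRUE_v(substantial)]
  missing <- setdiff(required, panel$entries$gene)
  panel$missing_required <- missing
  panel$validity <- if (length(missing) > 0) "invalid" else "valid"
  panel
}

isTRUE_v <- function(x) !is.na(x) & x

#' Clinical-utility guidance for a panel finding
#'
#' Maps a gene's panel class and a variant verdict onto the appropriate use
#' of the finding: pathogenic findings in genes proven for the condition are
#' diagnostic and actionable; a VUS there suggests family segregation
#' studies; pathogenic findings in differential-class genes represent either
#' phenotype expansion or an incidental finding; a VUS there suggests
#' clinical re-review; anything in suspected-only genes is held for research;
#' benign-side verdicts require no action.
#'
#' @param class One of the three panel classes.
#' @param verdict A five-level pathogenicity verdict.
#' @return One of `diagnostic_actionable`, `segregation_studies_suggested`,
#'   `expansion_or_incidental`, `clinical_rereview_suggested`,
#'   `research_hold`, `no_action`.
#' @examples
#' interpret_result("proven_for_condition", "pathogenic")
#' interpret_result("suspected_for_condition", "pathogenic")
#' @export
interpret_result <- function(class, verdict) {
  stopifnot(class %in% panel_classes, verdict %in% verdict_levels)
  if (verdict %in% c("benign", "likely_benign")) return("no_action")
  if (class == "suspected_for_condition") return("research_hold")
  path_side <- verdict %in% c("pathogenic", "likely_pathogenic")
  if (class == "proven_for_condition") {
    if (path_side) "diagnostic_actionable" else "segregation_studies_suggested"
  } else {
    if (path_side) "expansion_or_incidental" else "clinical_rereview_suggested"
  }
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("<panel_spec> target: %s (%d genes, validity: %s)\n",
              x$target, nrow(x$entries), x$validity))
  print(x$entries)
  if (length(x$missing_required) > 0) {
    cat("  missing required:", paste(x$missing_required, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a panel specification as JSON
#'
#' @param panel A `panel_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- list(
    target = panel$target,
    entries = purrr::pmap(panel$entries, function(gene, class) {
      list(gene = gene, class = class)
    }),
    validity = panel$validity,
    missing_required = as.list(panel$missing_required)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
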