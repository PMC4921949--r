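# Gene-level clinical validity. A gene is proven when at least one clinically
# observed variant (>= 1 case observation) classifies as pathogenic; gene-
# condition strength follows the unrelated-proband heuristic: >= 3 unrelated
# probands with the specific condition => strong, 1-2 in an already-proven
# gene => emerging, preliminary evidence only => suggested. Because criterion
# assignment is modulated by gene status and link strength, and those derive
# from variant verdicts, the joint assessment is computed as the fixed point
# of a monotone update from the maximally conservative start.

strength_levels <- c("none", "suggested", "emerging", "strong")

# Does a case manifest a condition? Either the asserted condition id matches,
# or at least `phenotype_match` of the condition's feature tokens appear in
# the case's phenotype features.
case_matches_condition <- function(case_condition, case_features, condition_id,
                                   condition_features, cfg) {
  if (identical(case_condition, condition_id)) return(TRUE)
  feats <- unlist(condition_features)
  if (length(feats) == 0) return(FALSE)
  mean(feats %in% unlist(case_features)) >= cfg$phenotype_match
}

# Case observations of a gene's pathogenic variants that manifest `condition`,
# with recessive-zygosity filtering. Returns the matching case rows.
matching_pathogenic_cases <- function(bundle, classifications, gene,
                                      condition, cfg) {
  cond_row <- filter(bundle$conditions, .data$id == condition)
  if (nrow(cond_row) == 0) {
    abort(sprintf("Unknown condition id '%s'", condition),
          class = "genevalid_lookup_error")
  }
  path_variants <- classifications$variant[
    classifications$gene == gene & classifications$verdict == "pathogenic"
  ]
  ca <- filter(bundle$cases, .data$variant %in% path_variants)
  if (nrow(ca) == 0) return(ca)
  hit <- purrr::map2_lgl(ca$condition, ca$phenotype_features,
                         case_matches_condition,
                         condition_id = condition,
                         condition_features = cond_row$features[[1]],
                         cfg = cfg)
  ca <- ca[hit, , drop = FALSE]

  inh <- unlist(cond_row$inheritance[[1]])
  if (length(inh) > 0 && all(inh == "AR")) {
    # strictly recessive condition: a proband counts when biallelic --
    # homozygous for a pathogenic variant, or compound heterozygous with
    # every observed allele pathogenic-classified
    all_path <- classifications$variant[classifications$verdict == "pathogenic"]
    keep <- vapply(unique(ca$proband), function(p) {
      rows <- bundle$cases[bundle$cases$proband == p, , drop = FALSE]
      if (any(rows$zygosity == "hom" & rows$variant %in% path_variants)) {
        return(TRUE)
      }
      ch <- rows[rows$zygosity == "compound_het", , drop = FALSE]
      nrow(ch) >= 2 && all(ch$variant %in% all_path)
    }, logical(1))
    ca <- ca[ca$proband %in% unique(ca$proband)[keep], , drop = FALSE]
  }
  ca
}

#' Count unrelated probands supporting a gene-condition relationship
#'
#' Counts distinct family ids among case observations whose variant is
#' classified pathogenic and which manifest the condition (matching condition
#' id, or sufficient phenotype-feature overlap). For strictly recessive
#' conditions only biallelic probands count, and compound-heterozygous
#' probands count only when both observed alleles are pathogenic-classified.
#'
#' @param bundle An [evidence_bundle()].
#' @param classifications Output of [classify_variants()] covering the gene's
#'   variants.
#' @param gene Gene symbol.
#' @param condition Condition id.
#' @param config Optional [rules_config()].
#' @return Integer count of distinct families.
#' @export
count_unrelated_probands <- function(bundle, classifications, gene, condition,
                                     config = NULL) {
  cfg <- as_rules_config(config)
  if (!gene %in% bundle$genes$symbol) {
    abort(sprintf("Unknown gene '%s'", gene),
          class = "genevalid_lookup_error")
  }
  ca <- matching_pathogenic_cases(bundle, classifications, gene, condition, cfg)
  n_distinct(ca$family)
}

#' Assess gene-level clinical validity
#'
#' A gene is `proven` when at least one clinically observed variant (a variant
#' with at least one case observation) is classified pathogenic; otherwise it
#' remains a gene of uncertain significance (`uncertain`).
#'
#' @inheritParams count_unrelated_probands
#' @return One-row tibble: `gene`, `status`, and `proving_variants`
#'   (list-column; non-empty exactly when `status == "proven"`).
#' @export
assess_gene <- function(bundle, classifications, gene) {
  if (!gene %in% bundle$genes$symbol) {
    abort(sprintf("Unknown gene '%s'", gene),
          class = "genevalid_lookup_error")
  }
  assess_genes(bundle, classifications) |> filter(.data$gene == !!gene)
}

#' Assess every gene in a bundle
#'
#' @inheritParams count_unrelated_probands
#' @return Tibble with one row per gene: `gene`, `status`,
#'   `proving_variants`.
#' @export
assess_genes <- function(bundle, classifications) {
  observed <- unique(bundle$cases$variant)
  proving <- classifications |>
    filter(.data$verdict == "pathogenic", .data$variant %in% observed)
  tibble(gene = bundle$genes$symbol) |>
    mutate(
      proving_variants = purrr::map(.data$gene, function(g) {
        proving$variant[proving$gene == g]
      }),
      status = ifelse(lengths(.data$proving_variants) > 0,
                      "proven", "uncertain")
    ) |>
    select(dplyr::all_of(c("gene", "status", "proving_variants")))
}

has_preliminary_link <- function(bundle, gene, condition) {
  i <- match(gene, bundle$genes$symbol)
  pl <- bundle$genes$preliminary_links[[i]]
  length(pl) > 0 && condition %in% as_tibble(pl)$condition
}

#' Assert the strength of one gene-condition relationship
#'
#' Applies the strength heuristic: `strong` at >= 3 unrelated pathogenic-
#' variant probands manifesting the condition; `emerging` at 1-2 such probands
#' in an already-proven gene; `suggested` when no pathogenic variant exists
#' but preliminary evidence (case series of VUSes, linkage, functional or
#' animal data) links the pair; `none` otherwise. The gene-anchored generic
#' condition ("<GENE>_related") is `strong` whenever the gene is proven.
#'
#' @inheritParams count_unrelated_probands
#' @param status Tibble from [assess_genes()].
#' @return One-row tibble: `gene`, `condition`, `strength`,
#'   `unrelated_proband_count`, `pathogenic_variants` (list-column),
#'   `expansion_flag` (filled by [phenotype_expansion_flags()]; here
#'   `not_applicable`).
#' @export
assert_gene_condition <- function(bundle, classifications, status, gene,
                                  condition, config = NULL) {
  cfg <- as_rules_config(config)
  st <- status$status[match(gene, status$gene)]
  if (is.na(st)) {
    abort(sprintf("No status computed for gene '%s'", gene),
          class = "genevalid_lookup_error")
  }
  cond_row <- filter(bundle$conditions, .data$id == condition)
  if (nrow(cond_row) == 0) {
    abort(sprintf("Unknown condition id '%s'", condition),
          class = "genevalid_lookup_error")
  }

  if (isTRUE(cond_row$is_generic) &&
      condition == generic_condition_id(gene)) {
    proving <- status$proving_variants[[match(gene, status$gene)]]
    ca <- filter(bundle$cases, .data$variant %in% proving)
    return(tibble(
      gene = gene, condition = condition,
      strength = if (st == "proven") "strong" else "none",
      unrelated_proband_count = n_distinct(ca$family),
      pathogenic_variants = list(proving),
      expansion_flag = "not_applicable"
    ))
  }

  ca <- matching_pathogenic_cases(bundle, classifications, gene, condition, cfg)
  n <- n_distinct(ca$family)
  path_vars <- unique(ca$variant)
  if (n > 0 && length(path_vars) == 0) {
    abort("Internal consistency error: proband count > 0 without pathogenic variants.",
          class = "genevalid_internal_error")
  }
  strength <- if (n >= cfg$case_count_min) {
    "strong"
  } else if (n >= 1 && st == "proven") {
    "emerging"
  } else if (n == 0 && has_preliminary_link(bundle, gene, condition)) {
    "suggested"
  } else {
    "none"
  }
  tibble(
    gene = gene, condition = condition, strength = strength,
    unrelated_proband_count = n,
    pathogenic_variants = list(path_vars),
    expansion_flag = "not_applicable"
  )
}

# Candidate (gene, condition) pairs worth asserting: pairs linked by a case
# observation, by a preliminary link, or by the gene's generic condition.
candidate_pairs <- function(bundle) {
  from_cases <- bundle$cases |>
    left_join(select(bundle$variants, "id", "gene"), by = c(variant = "id")) |>
    distinct(.data$gene, .data$condition)
  from_prelim <- purrr::map2(bundle$genes$symbol,
                             bundle$genes$preliminary_links,
                             function(g, pl) {
                               pl <- as_tibble(pl)
                               if (nrow(pl) == 0) return(NULL)
                               tibble(gene = g, condition = pl$condition)
                             }) |> bind_rows()
  generic <- bundle$conditions |>
    filter(.data$is_generic) |>
    transmute(gene = sub("_related$", "", .data$id), condition = .data$id)
  bind_rows(from_cases, from_prelim, generic) |>
    filter(.data$gene %in% bundle$genes$symbol) |>
    distinct() |>
    arrange(.data$gene, .data$condition)
}

assert_all <- function(bundle, classifications, status, config = NULL) {
  pairs <- candidate_pairs(bundle)
  if (nrow(pairs) == 0) {
    return(tibble(gene = character(), condition = character(),
                  strength = character(),
                  unrelated_proband_count = integer(),
                  pathogenic_variants = list(),
                  expansion_flag = character()))
  }
  purrr::map2(pairs$gene, pairs$condition,
              ~ assert_gene_condition(bundle, classifications, status,
                                      .x, .y, config)) |>
    bind_rows()
}

#' Jointly assess variant pathogenicity, gene validity, and strengths
#'
#' Variant classification is modulated by gene status and link strength, and
#' both of those derive from variant classifications. `assess_validity()`
#' resolves the circularity by iterating from the maximally conservative
#' start (every gene uncertain, every link not strong): classify all variants
#' under the current maps, recompute statuses and assertions, repeat until
#' nothing changes. Statuses move only from uncertain to proven and strengths
#' only upward, so the iteration is a monotone update on a finite lattice and
#' the fixed point is reached in at most a few sweeps; the returned
#' `iterations` counts the state-changing sweeps.
#'
#' @param bundle An [evidence_bundle()].
#' @param config Optional [rules_config()].
#' @return An object of class `validity_assessment`: a list with
#'   `gene_status`, `assertions` (including phenotype-expansion flags),
#'   `classifications`, `expansion` (per condition pair), and `iterations`.
#'   Use [tidy()] for the assertion table, [glance()] for a one-row summary,
#'   and [autoplot()] for the assertion-matrix plot.
#' @examples
#' wx <- worked_examples()
#' va <- assess_validity(wx$bundle)
#' tidy(va)
#' glance(va)
#' @export
assess_validity <- function(bundle, config = NULL) {
  cfg <- as_rules_config(config)
  bundle <- validate_bundle(bundle)
  status <- tibble(gene = bundle$genes$symbol, status = "uncertain",
                   proving_variants = list(character()))
  links <- NULL
  prev_state <- NULL
  n_changed <- 0L
  max_sweeps <- nrow(bundle$genes) + 2L

  repeat {
    cls <- classify_variants(bundle, status, links, cfg)
    status <- assess_genes(bundle, cls)
    assertions <- assert_all(bundle, cls, status, cfg)
    state <- list(
      verdicts = stats::setNames(cls$verdict, cls$variant),
      status = stats::setNames(status$status, status$gene),
      strength = stats::setNames(assertions$strength,
                                 paste(assertions$gene, assertions$condition))
    )
    if (identical(state, prev_state)) break
    prev_state <- state
    links <- assertions
    n_changed <- n_changed + 1L
    if (n_changed > max_sweeps) {
      abort("Fixed-point assessment failed to converge; this indicates a non-monotone rule configuration.")
    }
  }

  expansion <- phenotype_expansion_flags(bundle, assertions, cls, cfg)
  assertions <- annotate_expansion(assertions, expansion)
  structure(
    list(gene_status = status, assertions = assertions,
         classifications = cls, expansion = expansion,
         iterations = n_changed),
    class = "validity_assessment"
  )
}

#' @export
print.validity_assessment <- function(x, ...) {
  cat("<validity_assessment>\n")
  cat(sprintf("  %d genes (%d proven, %d uncertain), %d variants, %d assertions; %d sweep(s)\n",
              nrow(x$gene_status), sum(x$gene_status$status == "proven"),
              sum(x$gene_status$status == "uncertain"),
              nrow(x$classifications), nrow(x$assertions), x$iterations))
  print(select(x$assertions,
               dplyr::all_of(c("gene", "condition", "strength",
                               "unrelated_proband_count", "expansion_flag"))))
  invisible(x)
}

# ---- phenotype expansion ----------------------------------------------------

probands_of <- function(bundle, classifications, gene, condition, cfg) {
  ca <- matching_pathogenic_cases(bundle, classifications, gene, condition, cfg)
  list(probands = unique(ca$proband), variants = unique(ca$variant))
}

inheritance_of <- function(bundle, condition) {
  unlist(bundle$conditions$inheritance[[match(condition,
                                              bundle$conditions$id)]])
}

#' Judge phenotype expansion versus distinct conditions
#'
#' For every gene asserted against two or more specific (non-generic)
#' conditions at emerging strength or above, judges each condition pair:
#' `complex_phenotype` when at least one proband with a pathogenic variant
#' manifests features of both conditions, or (failing the distinctness test)
#' when the same pathogenic variant is observed in probands of each
#' condition; `distinct_conditions` when the two proband sets are disjoint
#' and the conditions' inheritance modes do not overlap; `not_applicable`
#' otherwise.
#'
#' @param bundle An [evidence_bundle()].
#' @param assertions Assertion tibble (from [assess_validity()]).
#' @param classifications Classification tibble covering the bundle.
#' @param config Optional [rules_config()].
#' @return Tibble: `gene`, `condition_a`, `condition_b`, `flag`.
#' @export
phenotype_expansion_flags <- function(bundle, assertions, classifications,
                                      config = NULL) {
  cfg <- as_rules_config(config)
  out <- tibble(gene = character(), condition_a = character(),
                condition_b = character(), flag = character())
  generic_ids <- bundle$conditions$id[bundle$conditions$is_generic]
  qual <- assertions |>
    filter(.data$strength %in% c("emerging", "strong"),
           !.data$condition %in% generic_ids)
  for (g in unique(qual$gene)) {
    conds <- sort(qual$condition[qual$gene == g])
    if (length(conds) < 2) next
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    for (pr in pairs) {
      out <- bind_rows(out, tibble(
        gene = g, condition_a = pr[1], condition_b = pr[2],
        flag = expansion_flag_for_pair(bundle, classifications, g,
                                       pr[1], pr[2], cfg)
      ))
    }
  }
  out
}

expansion_flag_for_pair <- function(bundle, classifications, gene, c1, c2,
                                    cfg) {
  p1 <- probands_of(bundle, classifications, gene, c1, cfg)
  p2 <- probands_of(bundle, classifications, gene, c2, cfg)
  both <- intersect(p1$probands, p2$probands)
  if (length(both) > 0) return("complex_phenotype")
  inh_disjoint <- length(intersect(inheritance_of(bundle, c1),
                                   inheritance_of(bundle, c2))) == 0
  if (inh_disjoint && length(intersect(p1$probands, p2$probands)) == 0) {
    return("distinct_conditions")
  }
  if (length(intersect(p1$variants, p2$variants)) > 0) {
    return("complex_phenotype")
  }
  "not_applicable"
}

annotate_expansion <- function(assertions, expansion) {
  if (nrow(expansion) == 0) return(assertions)
  flags <- bind_rows(
    select(expansion, "gene", condition = "condition_a", "flag"),
    select(expansion, "gene", condition = "condition_b", "flag")
  ) |>
    filter(.data$flag != "not_applicable") |>
    distinct(.data$gene, .data$condition, .keep_all = TRUE)
  assertions |>
    left_join(flags, by = c("gene", "condition")) |>
    mutate(expansion_flag = dplyr::coalesce(.data$flag,
                                            .data$expansion_flag)) |>
    select(-dplyr::all_of("flag"))
}

# ---- exports ---------------------------------------------------------------

#' Write an assertion matrix as TSV
#'
#' Rows are genes, columns are conditions, cells are
#' `strong`/`emerging`/`suggested`/`""`, mirroring the shape of a curated
#' gene-condition strength table.
#'
#' @param assertions Assertion tibble (or a `validity_assessment`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assertion_matrix <- function(assertions, path) {
  if (inherits(assertions, "validity_assessment")) {
    assertions <- assertions$assertions
  }
  wide <- assertions |>
    mutate(cell = ifelse(.data$strength == "none", "", .data$strength)) |>
    select(dplyr::all_of(c("gene", "condition", "cell"))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "cell",
                       values_fill = "") |>
    arrange(.data$gene)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
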