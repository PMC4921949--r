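# Variant-level rules engine: evidence records -> criterion assignments ->
# five-level verdict. Criterion strengths follow the ACMG-style tier
# vocabulary; the combining table is reproduced in verdict_from_counts().
#
# Modulation cautions couple criterion strength to gene-level knowledge:
# case-count criteria are capped at supporting until the specific
# gene-condition relationship is strong, and molecular-consequence criteria
# are capped until the gene itself is proven (the gene-anchored generic
# relationship is strong), because mechanism understanding is gene-level.
# Functional evidence is capped unless the assay demonstrates the
# disease-relevant mechanism. Two classes of evidence are never down-weighted:
# confirmed de novo occurrence in a severe, early-onset phenotype, and
# population frequency above the benign threshold.

path_codes <- c("path_very_strong", "path_strong", "path_moderate",
                "path_supporting")
benign_codes <- c("benign_standalone", "benign_strong", "benign_supporting")
criterion_codes <- c(path_codes, benign_codes)
verdict_levels <- c("benign", "likely_benign", "VUS", "likely_pathogenic",
                    "pathogenic")

#' Tier segregation evidence from a LOD score
#'
#' Maps a (possibly multi-family combined) log10 odds of segregation onto an
#' evidence tier. The default cut points are LOD >= 3.0 strong (the classical
#' linkage significance bound), >= 1.5 moderate, >= 0.6 supporting.
#'
#' @param lod Finite numeric vector of log10 odds.
#' @param config Optional [rules_config()].
#' @return Character vector in `none`, `supporting`, `moderate`, `strong`;
#'   monotone non-decreasing in `lod`.
#' @examples
#' segregation_tier(c(0, 0.7, 1.8, 3.4))
#' @export
segregation_tier <- function(lod, config = NULL) {
  cfg <- as_rules_config(config)
  if (!is.numeric(lod) || any(!is.finite(lod))) {
    abort("`lod` must be finite numeric.", class = "genevalid_input_error")
  }
  dplyr::case_when(
    lod >= cfg$seg_strong ~ "strong",
    lod >= cfg$seg_moderate ~ "moderate",
    lod >= cfg$seg_supporting ~ "supporting",
    TRUE ~ "none"
  )
}

# Normalise a gene-status input (NULL, tibble(gene,status), or named vector)
# to a named character vector gene -> proven/uncertain.
as_status_map <- function(gene_status, genes) {
  out <- stats::setNames(rep("uncertain", length(genes)), genes)
  if (is.null(gene_status)) return(out)
  if (is.data.frame(gene_status)) {
    gene_status <- stats::setNames(gene_status$status, gene_status$gene)
  }
  keep <- intersect(names(gene_status), genes)
  out[keep] <- unname(gene_status[keep])
  stopifnot(all(out %in% c("proven", "uncertain")))
  out
}

# Normalise a link-strength input to a named vector "gene|condition" ->
# strength, defaulting to "none".
as_link_map <- function(link_strength) {
  if (is.null(link_strength)) return(character())
  if (is.data.frame(link_strength)) {
    stats::setNames(link_strength$strength,
                    paste(link_strength$gene, link_strength$condition,
                          sep = "|"))
  } else {
    link_strength
  }
}

link_is_strong <- function(link_map, gene, condition) {
  key <- paste(gene, condition, sep = "|")
  val <- unname(link_map[key])
  !is.na(val) & val == "strong"
}

criterion_row <- function(variant, criterion, code, modulated_from = NA_character_,
                          source = NA_character_, note = NA_character_) {
  tibble(variant = unname(variant), criterion = unname(criterion),
         code = unname(code), modulated_from = unname(modulated_from),
         source = unname(source), note = unname(note))
}

# Assign criteria for every variant in the bundle in one vectorised pass.
# Returns a tibble (variant, criterion, code, modulated_from, source, note).
assign_criteria_all <- function(bundle, gene_status = NULL,
                                link_strength = NULL, config = NULL) {
  cfg <- as_rules_config(config)
  v <- bundle$variants
  if (nrow(v) == 0) {
    return(criterion_row(character(), character(), character())[0, ])
  }
  status <- as_status_map(gene_status, v$gene)
  links <- as_link_map(link_strength)
  out <- list()

  # segregation: combined LOD per variant (independent families are additive)
  if (nrow(bundle$segregations) > 0) {
    seg <- bundle$segregations |>
      group_by(.data$variant) |>
      summarise(lod = sum(.data$lod),
                source = paste0("seg:", .data$variant[1], ":",
                                paste(.data$family, collapse = "+")),
                .groups = "drop") |>
      mutate(tier = segregation_tier(.data$lod, cfg)) |>
      filter(.data$tier != "none")
    if (nrow(seg) > 0) {
      out$segregation <- criterion_row(
        seg$variant, "segregation", paste0("path_", seg$tier),
        source = seg$source,
        note = sprintf("combined LOD %.2f", seg$lod)
      )
    }
  }

  # functional: one aggregated criterion per variant with an aberrant effect;
  # strong only when some assay is mechanism-concordant (animal models fold in)
  if (nrow(bundle$functionals) > 0) {
    fn <- bundle$functionals |>
      filter(.data$effect != "no_effect") |>
      group_by(.data$variant) |>
      summarise(concordant = any(.data$mechanism_concordant),
                assays = paste(unique(.data$assay), collapse = "+"),
                .groups = "drop")
    if (nrow(fn) > 0) {
      out$functional <- criterion_row(
        fn$variant, "functional",
        ifelse(fn$concordant, "path_strong", "path_supporting"),
        modulated_from = ifelse(fn$concordant, NA_character_, "path_strong"),
        source = paste0("func:", fn$variant, ":", fn$assays),
        note = ifelse(fn$concordant,
                      "aberrant effect, disease-relevant mechanism shown",
                      "aberrant effect, mechanism concordance not shown")
      )
    }
    bn <- bundle$functionals |>
      filter(.data$effect == "no_effect") |>
      distinct(.data$variant)
    # a well-performed assay showing no effect argues weakly for benign
    if (nrow(bn) > 0 &&
        !any(bn$variant %in% (out$functional$variant %||% character()))) {
      out$functional_benign <- criterion_row(
        bn$variant, "functional_no_effect", "benign_supporting",
        source = paste0("func:", bn$variant),
        note = "assay shows no functional effect"
      )
    }
  }

  # population: benign frequency beats absence; both uncapped
  if (nrow(bundle$populations) > 0) {
    po <- bundle$populations |>
      mutate(freq = .data$allele_count / .data$allele_number) |>
      group_by(.data$variant) |>
      summarise(
        common = any(.data$freq > cfg$benign_af &
                       .data$allele_count >= cfg$benign_min_count),
        absent = any(.data$allele_count == 0L &
                       .data$allele_number >= cfg$absent_min_an),
        max_freq = max(.data$freq),
        cohorts = paste(unique(.data$cohort), collapse = "+"),
        .groups = "drop"
      )
    common <- filter(po, .data$common)
    if (nrow(common) > 0) {
      out$frequency <- criterion_row(
        common$variant, "population_frequency", "benign_strong",
        source = paste0("pop:", common$variant, ":", common$cohorts),
        note = sprintf("allele frequency %.2g above benign threshold %.2g",
                       common$max_freq, cfg$benign_af)
      )
    }
    absent <- filter(po, .data$absent & !.data$common)
    if (nrow(absent) > 0) {
      out$absence <- criterion_row(
        absent$variant, "absence_in_controls", "path_moderate",
        source = paste0("pop:", absent$variant, ":", absent$cohorts),
        note = sprintf("absent from >= %d control alleles", cfg$absent_min_an)
      )
    }
  }

  if (nrow(bundle$cases) > 0) {
    ca <- left_join(bundle$cases, select(v, "id", "gene"),
                    by = c(variant = "id"))

    # case count: per (variant, presenting condition), distinct families;
    # moderate, capped at supporting until that gene-condition link is strong
    cc <- ca |>
      group_by(.data$variant, .data$gene, .data$condition) |>
      summarise(n_fam = n_distinct(.data$family), .groups = "drop") |>
      filter(.data$n_fam >= cfg$case_count_min)
    if (nrow(cc) > 0) {
      strong_link <- link_is_strong(links, cc$gene, cc$condition)
      out$case_count <- criterion_row(
        cc$variant, paste0("case_count:", cc$condition),
        ifelse(strong_link, "path_moderate", "path_supporting"),
        modulated_from = ifelse(strong_link, NA_character_, "path_moderate"),
        source = paste0("cases:", cc$variant, ":", cc$condition),
        note = ifelse(strong_link,
                      sprintf("%d unrelated probands with established condition",
                              cc$n_fam),
                      sprintf("%d unrelated probands; capped: gene-condition link not strong",
                              cc$n_fam))
      )
    }

    # de novo occurrence: strongest qualifying case per variant
    dn <- ca |>
      filter(.data$de_novo %in% c("assumed", "confirmed_parentage")) |>
      mutate(
        retained = .data$de_novo == "confirmed_parentage" &
          .data$severity == "severe" &
          .data$onset %in% c("infantile", "childhood"),
        base = ifelse(.data$de_novo == "confirmed_parentage",
                      "path_strong", "path_moderate")
      ) |>
      group_by(.data$variant, .data$gene) |>
      arrange(desc(.data$retained), desc(.data$base)) |>
      slice(1) |>
      ungroup()
    if (nrow(dn) > 0) {
      strong_link <- link_is_strong(links, dn$gene, dn$condition)
      keep_tier <- dn$retained | strong_link
      out$de_novo <- criterion_row(
        dn$variant, "de_novo",
        ifelse(keep_tier, dn$base, "path_supporting"),
        modulated_from = ifelse(keep_tier, NA_character_, dn$base),
        source = paste0("case:", dn$variant, ":", dn$proband),
        note = dplyr::case_when(
          dn$retained ~ "confirmed de novo, severe early-onset specific phenotype",
          dn$de_novo == "confirmed_parentage" ~ "confirmed de novo",
          TRUE ~ "assumed de novo (parentage not confirmed)"
        )
      )
    }
  }

  # molecular consequence: loss-of-function variant class; very strong only
  # once the gene is proven (generic gene-level relationship strong), since
  # before that the disease mechanism is not established
  lof <- v |>
    filter(.data$consequence %in% c("nonsense", "frameshift", "splice",
                                    "exonic_deletion"))
  if (nrow(lof) > 0) {
    proven <- status[lof$gene] == "proven"
    out$consequence <- criterion_row(
      lof$id, "molecular_consequence",
      ifelse(proven, "path_very_strong", "path_supporting"),
      modulated_from = ifelse(proven, NA_character_, "path_very_strong"),
      source = paste0("variant:", lof$id),
      note = ifelse(proven,
                    paste0("loss-of-function (", lof$consequence,
                           "), mechanism established via proven gene"),
                    paste0("loss-of-function (", lof$consequence,
                           "); capped: gene not yet proven"))
    )
  }

  # pre-tagged computational support (never more than supporting)
  insil <- filter(v, .data$in_silico_support)
  if (nrow(insil) > 0) {
    out$computational <- criterion_row(
      insil$id, "computational", "path_supporting",
      source = paste0("variant:", insil$id),
      note = "pre-tagged in-silico support"
    )
  }

  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(criterion_row(character(), character(), character()))
  }
  arrange(res, .data$variant, .data$criterion)
}

#' Assign evidence criteria for one variant
#'
#' Runs the full criterion-assignment rules for a single variant: segregation
#' tiering, functional-assay aggregation, population frequency/absence,
#' case counting over unrelated families, de novo occurrence, molecular
#' consequence, and pre-tagged computational support, applying the modulation
#' cautions described in `vignette("genevalid-methods")`.
#'
#' @param bundle An [evidence_bundle()].
#' @param variant_id A variant id present in the bundle.
#' @param gene_status Optional tibble (`gene`, `status`) or named vector with
#'   status in `proven`/`uncertain`; genes default to `uncertain`.
#' @param link_strength Optional tibble (`gene`, `condition`, `strength`);
#'   links default to not-strong.
#' @param config Optional [rules_config()].
#' @return Tibble with columns `variant`, `criterion`, `code`,
#'   `modulated_from` (the original tier when a cap was applied), `source`,
#'   `note`. Zero rows when no evidence triggers.
#' @export
assign_criteria <- function(bundle, variant_id, gene_status = NULL,
                            link_strength = NULL, config = NULL) {
  if (!variant_id %in% bundle$variants$id) {
    abort(sprintf("Unknown variant id '%s'", variant_id),
          class = "genevalid_lookup_error")
  }
  assign_criteria_all(bundle, gene_status, link_strength, config) |>
    filter(.data$variant == variant_id)
}

# The combining table, fully vectorised over per-tier counts. Arguments are
# integer vectors: counts of very-strong/strong/moderate/supporting pathogenic
# and stand-alone/strong/supporting benign criteria.
verdict_from_counts <- function(pvs, ps, pm, pp, ba, bs, bp) {
  pathogenic <-
    (pvs >= 1 & ps >= 1) |
    (pvs >= 1 & pm >= 2) |
    (pvs >= 1 & pm >= 1 & pp >= 1) |
    (pvs >= 1 & pp >= 2) |
    (ps >= 2) |
    (ps >= 1 & pm >= 3) |
    (ps >= 1 & pm >= 2 & pp >= 2) |
    (ps >= 1 & pm >= 1 & pp >= 4)
  likely_pathogenic <-
    (pvs >= 1 & pm >= 1) |
    (ps >= 1 & pm >= 1) |
    (ps >= 1 & pp >= 2) |
    (pm >= 3) |
    (pm >= 2 & pp >= 2) |
    (pm >= 1 & pp >= 4)
  benign <- (ba >= 1) | (bs >= 2)
  likely_benign <- (bs >= 1 & bp >= 1) | (bp >= 2)

  path_side <- pathogenic | likely_pathogenic
  benign_side <- benign | likely_benign
  strong_conflict <- (pvs + ps >= 1) & (ba + bs >= 1)
  conflict <- strong_conflict | (path_side & benign_side)

  dplyr::case_when(
    conflict ~ "VUS",
    pathogenic ~ "pathogenic",
    benign ~ "benign",
    likely_pathogenic ~ "likely_pathogenic",
    likely_benign ~ "likely_benign",
    TRUE ~ "VUS"
  )
}

criteria_counts <- function(codes) {
  vapply(criterion_codes, function(cc) sum(codes == cc), integer(1))
}

#' Combine evidence criteria into a pathogenicity verdict
#'
#' Deterministically combines a multiset of criterion assignments using the
#' standard combining table (see `vignette("genevalid-methods")` for the full
#' row list). The empty set yields VUS; co-occurring strong benign and strong
#' pathogenic evidence, or simultaneously satisfied pathogenic-side and
#' benign-side rows, conflict to VUS.
#'
#' @param criteria A character vector of criterion codes, or a tibble with a
#'   `code` column as produced by [assign_criteria()].
#' @return One of `pathogenic`, `likely_pathogenic`, `VUS`, `likely_benign`,
#'   `benign`.
#' @examples
#' combine_criteria(c("path_very_strong", "path_strong"))
#' combine_criteria(character())
#' @export
combine_criteria <- function(criteria) {
  codes <- if (is.data.frame(criteria)) criteria$code else criteria
  codes <- as.character(codes %||% character())
  bad <- setdiff(codes, criterion_codes)
  if (length(bad) > 0) {
    abort(sprintf("Malformed criterion code(s): %s",
                  paste(unique(bad), collapse = ", ")),
          class = "genevalid_input_error")
  }
  k <- criteria_counts(codes)
  verdict_from_counts(k[["path_very_strong"]], k[["path_strong"]],
                      k[["path_moderate"]], k[["path_supporting"]],
                      k[["benign_standalone"]], k[["benign_strong"]],
                      k[["benign_supporting"]])
}

#' Classify every variant in a bundle
#'
#' @inheritParams assign_criteria
#' @return A tibble with one row per variant: `variant`, `gene`, `verdict`,
#'   `n_criteria`, and a `criteria` list-column of per-variant criterion
#'   tibbles. Verdicts are exactly `combine_criteria()` of the assigned
#'   criteria.
#' @export
classify_variants <- function(bundle, gene_status = NULL,
                              link_strength = NULL, config = NULL) {
  crit <- assign_criteria_all(bundle, gene_status, link_strength, config)
  per_variant <- split(crit, factor(crit$variant, levels = bundle$variants$id))
  tibble(
    variant = bundle$variants$id,
    gene = bundle$variants$gene,
    criteria = unname(per_variant[bundle$variants$id])
  ) |>
    mutate(
      verdict = purrr::map_chr(.data$criteria, combine_criteria),
      n_criteria = purrr::map_int(.data$criteria, nrow)
    ) |>
    select(dplyr::all_of(c("variant", "gene", "verdict", "n_criteria",
                           "criteria")))
}

#' Classify a single variant with full criterion provenance
#'
#' @inheritParams assign_criteria
#' @return A one-row tibble as in [classify_variants()].
#' @examples
#' wx <- worked_examples()
#' classify_variant(wx$bundle, "MYH7_R403Q")
#' @export
classify_variant <- function(bundle, variant_id, gene_status = NULL,
                             link_strength = NULL, config = NULL) {
  if (!variant_id %in% bundle$variants$id) {
    abort(sprintf("Unknown variant id '%s'", variant_id),
          class = "genevalid_lookup_error")
  }
  classify_variants(bundle, gene_status, link_strength, config) |>
    filter(.data$variant == variant_id)
}
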