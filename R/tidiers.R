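#' Tidy a validity assessment into its assertion table
#'
#' @param x A `validity_assessment` from [assess_validity()].
#' @param ... Unused.
#' @return Tibble with one row per gene-condition assertion: `gene`,
#'   `condition`, `strength`, `unrelated_proband_count`,
#'   `pathogenic_variants`, `expansion_flag`, plus the gene `status`.
#' @method tidy validity_assessment
#' @export
tidy.validity_assessment <- function(x, ...) {
  x$assertions |>
    left_join(select(x$gene_status, "gene", "status"), by = "gene") |>
    arrange(.data$gene, .data$condition)
}

#' One-row summary of a validity assessment
#'
#' @inheritParams tidy.validity_assessment
#' @return Tibble with gene, variant, and assertion counts and the number of
#'   state-changing fixed-point sweeps.
#' @method glance validity_assessment
#' @export
glance.validity_assessment <- function(x, ...) {
  tibble(
    n_genes = nrow(x$gene_status),
    n_proven = sum(x$gene_status$status == "proven"),
    n_gus = sum(x$gene_status$status == "uncertain"),
    n_variants = nrow(x$classifications),
    n_pathogenic = sum(x$classifications$verdict == "pathogenic"),
    n_vus = sum(x$classifications$verdict == "VUS"),
    n_strong = sum(x$assertions$strength == "strong"),
    n_emerging = sum(x$assertions$strength == "emerging"),
    n_suggested = sum(x$assertions$strength == "suggested"),
    iterations = x$iterations
  )
}

#' Plot an assertion matrix
#'
#' Gene-by-condition tile plot of assertion strengths, mirroring the shape of
#' a curated strength table.
#'
#' @param object A `validity_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot validity_assessment
#' @export
autoplot.validity_assessment <- function(object, ...) {
  d <- object$assertions |>
    filter(.data$strength != "none") |>
    mutate(strength = factor(.data$strength,
                             levels = c("suggested", "emerging", "strong")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$gene,
                                  fill = .data$strength)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(suggested = "#c6dbef",
                                          emerging = "#6baed6",
                                          strong = "#2171b5"),
                               drop = FALSE) +
    ggplot2::labs(x = "condition", y = "gene", fill = "strength",
                  title = "Gene-condition assertion strengths") +
    ggplot2::theme_minimal()
}

#' Tidy a panel specification
#'
#' @param x A `panel_spec` from [design_panel()].
#' @param ... Unused.
#' @return Tibble of panel entries with the target condition and validity
#'   attached.
#' @method tidy panel_spec
#' @export
tidy.panel_spec <- function(x, ...) {
  x$entries |>
    mutate(target = x$target, validity = x$validity)
}

#' One-row summary of a panel specification
#'
#' @inheritParams tidy.panel_spec
#' @return Tibble: target, per-class gene counts, validity, and the number of
#'   missing required genes.
#' @method glance panel_spec
#' @export
glance.panel_spec <- function(x, ...) {
  tibble(
    target = x$target,
    n_genes = nrow(x$entries),
    n_proven = sum(x$entries$class == "proven_for_condition"),
    n_suspected = sum(x$entries$class == "suspected_for_condition"),
    n_differential = sum(x$entries$class == "proven_for_differential"),
    validity = x$validity,
    n_missing_required = length(x$missing_required)
  )
}

#' Plot panel composition
#'
#' @param object A `panel_spec`.
#' @param ... Unused.
#' @return A ggplot object: genes grouped by panel class.
#' @method autoplot panel_spec
#' @export
autoplot.panel_spec <- function(object, ...) {
  d <- object$entries |>
    mutate(class = factor(.data$class, levels = panel_classes)) |>
    group_by(.data$class) |>
    mutate(pos = dplyr::row_number()) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$pos)) +
    ggplot2::geom_label(ggplot2::aes(label = .data$gene, fill = .data$class),
                        colour = "white", show.legend = FALSE) +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("Panel composition: %s (%s)",
                                  object$target, object$validity)) +
    ggplot2::theme_minimal()
}
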