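#' Plot the locus feature-category distribution per line
#'
#' Bar chart of enriched-locus counts by feature category and line, one
#' panel per integration stage (after enrichment filtering, and after the
#' up-regulation filter).
#'
#' @param targets A `tf_targets` object (or its `locus_table` tibble).
#' @return A ggplot object.
#' @export
plot_locus_categories <- function(targets) {
  tab <- if (inherits(targets, "tf_targets")) {
    targets$locus_table
  } else {
    targets
  }
  ggplot(tab, aes(x = .data$category, y = .data$n, fill = .data$line)) +
    geom_col(position = "dodge") +
    facet_wrap(~stage, scales = "free_y") +
    labs(
      x = "feature category", y = "loci",
      title = "Enriched-locus distribution by feature category"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 45, hjust = 1
    ))
}

#' Plot the Venn-cell gene counts of a direct-target partition
#'
#' @param object A `tf_venn` object from [venn_partition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_venn <- function(object, ...) {
  cells <- object$cells |>
    mutate(subset = factor(.data$subset, levels = .data$subset))
  ggplot(cells, aes(
    x = .data$subset, y = .data$n_genes,
    fill = factor(.data$n_lines)
  )) +
    geom_col() +
    coord_flip() +
    labs(
      x = "line subset", y = "direct-target genes", fill = "lines",
      title = "Direct targets shared across lines"
    ) +
    ggplot2::theme_minimal()
}

#' Dot plot of the top enriched GO terms
#'
#' @param object A `tf_sea` result.
#' @param n_top Number of terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_sea <- function(object, n_top = 15, ...) {
  top <- as_tibble(unclass(object)) |>
    arrange(.data$p_value) |>
    head(n_top) |>
    mutate(
      label = ifelse(is.na(.data$name), .data$term_id, .data$name),
      label = factor(.data$label, levels = rev(unique(.data$label)))
    )
  ggplot(top, aes(
    x = -log10(.data$fdr), y = .data$label,
    size = .data$k, colour = .data$significant
  )) +
    geom_point() +
    labs(
      x = "-log10 FDR", y = NULL, size = "study genes",
      colour = "significant",
      title = "GO singular enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Volcano-style plot of per-line differential expression
#'
#' @param degs A `tf_deg` tibble.
#' @return A ggplot object.
#' @export
plot_deg_volcano <- function(degs) {
  d <- as_tibble(unclass(degs)) |>
    mutate(neglogp = -log10(pmax(.data$p_value, 1e-300)))
  ggplot(d, aes(
    x = .data$log2_fold_change, y = .data$neglogp,
    colour = .data$direction
  )) +
    geom_point(alpha = 0.5, size = 0.8) +
    facet_wrap(~condition) +
    labs(
      x = "log2 fold change (FPKM + 1)", y = "-log10 p",
      title = "Differential expression vs control"
    ) +
    ggplot2::theme_minimal()
}
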