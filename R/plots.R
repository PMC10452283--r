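#' Violin plot of per-species percent identity
#'
#' @param hits Hit tibble with `species` and `pident` columns.
#' @return A ggplot.
#' @export
plot_identity <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(
    x = factor(.data$species, levels = model_species()),
    y = .data$pident
  )) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::stat_summary(fun = median, geom = "point", size = 1.5) +
    ggplot2::labs(x = NULL, y = "% identity to human CDS") +
    ggplot2::theme_minimal()
}

#' Upset-style bar chart of conservation patterns
#'
#' @param object A [build_conserved_set()] result.
#' @param ... Unused.
#' @return A ggplot of per-pattern counts (all-zero pattern dropped).
#' @export
autoplot.conserved_set <- function(object, ...) {
  counts <- intersection_counts(object)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$pattern, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "membership pattern (macaque..rat)", y = "CDS count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of disease-category percentages per species
#'
#' The species attaining each category's maximum is outlined.
#'
#' @param object A [category_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.disease_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$species, levels = model_species()),
    y = .data$category, fill = .data$pct
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(object, .data$is_max),
                       fill = NA, colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "darkgreen",
                                 name = "% of diseases") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Synteny fragmentation overview
#'
#' Number of source chromosomes per (human chromosome, species) cell;
#' intact cells (a single source) are marked.
#'
#' @param object A [synteny_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.synteny_map <- function(object, ...) {
  d <- dplyr::mutate(object,
                     human_chromosome = factor(.data$human_chromosome,
                                               levels = chrom_levels()),
                     n_sources = lengths(.data$sources))
  ggplot2::ggplot(d, ggplot2::aes(
    x = factor(.data$species, levels = model_species()),
    y = .data$human_chromosome, fill = .data$n_sources
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(d, .data$intact), size = 1) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "source chromosomes") +
    ggplot2::labs(x = NULL, y = "human chromosome",
                  caption = "dot = intact (single source chromosome)") +
    ggplot2::theme_minimal()
}
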