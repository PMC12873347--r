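# ggplot2 views of the main result types

#' Ranked enrichment plot of a microarray screen
#'
#' Log2 fold change against rank, with the hit threshold drawn as a
#' horizontal reference — the standard way to eyeball how sharply the
#' repertoire tails off.
#'
#' @param enrichment A tibble from [fold_change()].
#' @param threshold Hit threshold drawn as reference lines.
#' @param label_top How many top antigens to label.
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment, threshold = 2.5, label_top = 10) {
  top <- utils::head(enrichment, label_top)
  ggplot2::ggplot(enrichment, ggplot2::aes(x = .data$rank, y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
      linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$antigen_id),
      hjust = -0.1, vjust = 0.5, size = 2.8) +
    ggplot2::labs(x = "antigen rank", y = "log2 fold change (cases / controls)")
}

#' Seroprevalence bar chart by group
#'
#' @param prev A tibble from [prevalence_by_group()].
#' @return A ggplot faceted by antigen.
#' @export
plot_prevalence <- function(prev) {
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$group, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~antigen_id) +
    ggplot2::labs(x = NULL, y = "seroprevalence (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Neoplasm proportion heatmap
#'
#' @param prop A tibble from [proportion_heatmap()].
#' @return A ggplot tile map.
#' @export
plot_proportion_heatmap <- function(prop) {
  ggplot2::ggplot(prop,
    ggplot2::aes(x = .data$antigen_id, y = .data$neoplasm, fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
      limits = c(0, 1), name = "proportion") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn pca_profiles Score plot (PC1 vs PC2), optionally coloured
#'   by a named per-sample grouping vector.
#' @param object A `sero_pca` object.
#' @param colour_by Optional named character vector `sample_id -> label`.
#' @param ... Unused.
#' @method autoplot sero_pca
#' @export
autoplot.sero_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  ve <- object$variance_explained
  if (!is.null(colour_by)) df$group <- unname(colour_by[df$sample_id])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ve[1]),
      y = sprintf("PC2 (%.1f%%)", ve[2])
    )
  if (is.null(colour_by)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  }
}

#' Scree plot of a serological PCA
#'
#' @param pca A `sero_pca` object.
#' @param n_components How many leading components to show.
#' @return A ggplot.
#' @export
plot_scree <- function(pca, n_components = 10) {
  df <- utils::head(augment(pca), n_components)
  ggplot2::ggplot(df,
    ggplot2::aes(x = .data$component, y = .data$variance_explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "component", y = "variance explained (%)")
}

#' Panel sensitivity/specificity versus panel size
#'
#' Shows the best panel at each size — sensitivity climbs with added
#' antigens and stabilizes, while specificity stays near its ceiling.
#'
#' @param search A `panel_search` tibble.
#' @return A ggplot.
#' @export
plot_panel_sizes <- function(search) {
  best <- as_tibble(search) |>
    group_by(.data$size) |>
    dplyr::slice_max(.data$auc, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("size", "sensitivity", "specificity") |>
    tidyr::pivot_longer(-"size", names_to = "metric", values_to = "value")
  ggplot2::ggplot(best,
    ggplot2::aes(x = .data$size, y = .data$value, colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "panel size (antigens)", y = NULL, colour = NULL)
}
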