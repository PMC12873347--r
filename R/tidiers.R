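# broom-style tidiers for the fitted/derived result objects

#' Tidy a PCA of serological profiles
#'
#' @param x A `sero_pca` object.
#' @param matrix Which block to return: `"scores"`, `"loadings"` or
#'   `"contributions"`.
#' @param ... Unused.
#' @return A long tibble (`sample_id` or `antigen_id`, `component`,
#'   `value`).
#' @method tidy sero_pca
#' @export
tidy.sero_pca <- function(x, matrix = c("scores", "loadings", "contributions"), ...) {
  matrix <- match.arg(matrix)
  block <- x[[matrix]]
  id <- names(block)[1]
  tidyr::pivot_longer(block, -all_of(id), names_to = "component",
    values_to = "value") |>
    mutate(component = as.integer(sub("^PC", "", .data$component)))
}

#' One-row summary of a serological PCA
#'
#' @param x A `sero_pca` object.
#' @param ... Unused.
#' @return Tibble with the component count and the variance explained by
#'   the first two components (the two major serological profiles).
#' @method glance sero_pca
#' @export
glance.sero_pca <- function(x, ...) {
  ve <- x$variance_explained
  tibble(
    n_components = length(ve),
    var_pc1 = ve[1],
    var_pc2 = if (length(ve) > 1) ve[2] else NA_real_,
    var_pc1_pc2 = ve[1] + if (length(ve) > 1) ve[2] else 0,
    transform = x$transform
  )
}

#' Scree table of a serological PCA
#'
#' @param x A `sero_pca` object.
#' @param ... Unused.
#' @return Tibble `component`, `variance_explained` (percent),
#'   `cumulative`.
#' @method augment sero_pca
#' @export
augment.sero_pca <- function(x, ...) {
  ve <- x$variance_explained
  tibble(
    component = seq_along(ve),
    variance_explained = ve,
    cumulative = cumsum(ve)
  )
}

#' Tidy a ranked panel search
#'
#' @param x A `panel_search` tibble.
#' @param ... Unused.
#' @return The ranked tibble with the panel spelled out as a `+`-joined
#'   label column.
#' @method tidy panel_search
#' @export
tidy.panel_search <- function(x, ...) {
  out <- as_tibble(x)
  out$panel <- vapply(out$antigens, function(a) paste(a, collapse = "+"), "")
  select(out, "rank", "panel", "size", "sensitivity", "specificity", "auc")
}

#' One-row summary of a panel search
#'
#' @param x A `panel_search` tibble.
#' @param ... Unused.
#' @return Tibble with the number of panels evaluated and the top panel's
#'   operating characteristics.
#' @method glance panel_search
#' @export
glance.panel_search <- function(x, ...) {
  top <- x[1, ]
  tibble(
    n_evaluated = attr(x, "n_evaluated", exact = TRUE),
    best_panel = paste(top$antigens[[1]], collapse = "+"),
    best_size = top$size,
    best_sensitivity = top$sensitivity,
    best_specificity = top$specificity,
    best_auc = top$auc
  )
}

#' Tidy a Fisher's exact association result
#'
#' @param x A `sero_assoc` object.
#' @param ... Unused.
#' @return One-row tibble with the 2x2 counts and the two-sided p-value.
#' @method tidy sero_assoc
#' @export
tidy.sero_assoc <- function(x, ...) {
  tab <- x$table
  tibble(
    antigen_id = x$antigen, feature = x$feature,
    pos_with_feature = tab[1, 1], neg_with_feature = tab[1, 2],
    pos_without_feature = tab[2, 1], neg_without_feature = tab[2, 2],
    p_two_sided = x$p_two_sided,
    degenerate = x$degenerate, n_excluded = x$n_excluded
  )
}

#' Tidy a repertoire result
#'
#' @param x A `sero_repertoire` tibble.
#' @param ... Unused.
#' @return The hit tibble with `k` and `threshold` as columns.
#' @method tidy sero_repertoire
#' @export
tidy.sero_repertoire <- function(x, ...) {
  mutate(as_tibble(x),
    k = attr(x, "k", exact = TRUE),
    threshold = attr(x, "threshold", exact = TRUE)
  )
}

#' One-row summary of a repertoire result
#'
#' @param x A `sero_repertoire` tibble.
#' @param ... Unused.
#' @return Tibble `k`, `threshold`, `n_hits`, `n_positive`, `n_negative`.
#' @method glance sero_repertoire
#' @export
glance.sero_repertoire <- function(x, ...) {
  tibble(
    k = attr(x, "k", exact = TRUE),
    threshold = attr(x, "threshold", exact = TRUE),
    n_hits = nrow(x),
    n_positive = sum(x$direction == "positive"),
    n_negative = sum(x$direction == "negative")
  )
}
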