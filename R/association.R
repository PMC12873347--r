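#' Fisher's exact association between positivity and a clinical feature
#'
#' Builds the 2x2 table of antigen positivity against a clinical feature
#' among PNP cases and computes the two-sided Fisher's exact p-value
#' (summing hypergeometric probabilities no larger than the observed
#' table's). Samples whose feature is undefined (e.g. unknown neoplasm
#' when testing a neoplasm feature) are excluded and reported in a
#' message. A table with a zero margin carries no information and returns
#' p = 1 with the `degenerate` flag set.
#'
#' @param calls A `sero_calls` tibble from [call_positives()].
#' @param meta Sample metadata.
#' @param antigen Antigen id.
#' @param feature Either the name of a built-in feature —
#'   `"bronchiolitis_obliterans"`, `"thymoma"`, `"follicular_lymphoma"` —
#'   or a predicate `function(meta) logical` (NA = undefined, sample
#'   excluded). Built-ins are evaluated over PNP samples only.
#' @return A `sero_assoc` object: list with `antigen`, `feature`, `table`
#'   (2x2: feature x positivity), `p_two_sided`, `n_excluded`,
#'   `degenerate`.
#' @export
fisher_association <- function(calls, meta, antigen, feature) {
  meta <- as_sample_meta(meta)
  meta <- meta[meta$sample_id %in% calls$sample_id, ]
  feature_name <- if (is.character(feature)) feature else "custom"
  pred <- feature_predicate(feature)
  feat <- pred(meta)
  keep <- meta$group == "PNP"
  if (!is.character(feature)) keep <- rep(TRUE, nrow(meta))
  undefined <- keep & is.na(feat)
  if (any(undefined)) {
    inform(sprintf("fisher_association: excluding %d sample(s) with undefined '%s'",
      sum(undefined), feature_name))
  }
  use <- keep & !is.na(feat)
  ids <- meta$sample_id[use]
  if (!antigen %in% antigen_cols(calls)) {
    abort(sprintf("unknown antigen '%s'", antigen), class = "pnpsero_argument_error")
  }
  pos <- calls_values(calls)[ids, antigen]
  f <- feat[use]
  tab <- matrix(
    c(sum(f & pos), sum(f & !pos), sum(!f & pos), sum(!f & !pos)),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      feature = c("present", "absent"),
      positivity = c("positive", "negative")
    )
  )
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else fisher.test(tab)$p.value
  structure(
    list(
      antigen = antigen, feature = feature_name, table = tab,
      p_two_sided = min(p, 1), n_excluded = sum(undefined),
      degenerate = degenerate
    ),
    class = "sero_assoc"
  )
}

feature_predicate <- function(feature) {
  if (is.function(feature)) return(feature)
  switch(feature,
    bronchiolitis_obliterans = function(meta) meta$bronchiolitis_obliterans,
    thymoma = function(meta) {
      ifelse(is.na(meta$neoplasm), NA, meta$neoplasm == "thymoma")
    },
    follicular_lymphoma = function(meta) {
      ifelse(is.na(meta$neoplasm), NA, meta$neoplasm == "lymphoma_follicular")
    },
    abort(sprintf("unknown feature '%s'", feature), class = "pnpsero_argument_error")
  )
}

#' @export
print.sero_assoc <- function(x, ...) {
  cat(sprintf("# Fisher's exact association: %s ~ %s\n", x$antigen, x$feature))
  print(x$table)
  cat(sprintf("  two-sided p = %.4g%s\n", x$p_two_sided,
    if (x$degenerate) " (degenerate table: zero margin)" else ""))
  invisible(x)
}

#' Association grid over antigens and clinical features
#'
#' @param calls A `sero_calls` tibble.
#' @param meta Sample metadata.
#' @param antigens Antigen ids (default: all called).
#' @param features Built-in feature names (see [fisher_association()]).
#' @return Tidy tibble with one row per antigen x feature:
#'   counts, raw two-sided p, and a Benjamini-Hochberg adjusted column
#'   (reported for transparency; headline calls use the raw p).
#' @export
association_grid <- function(calls, meta,
                             antigens = NULL,
                             features = c("bronchiolitis_obliterans",
                               "thymoma", "follicular_lymphoma")) {
  antigens <- antigens %||% antigen_cols(calls)
  out <- purrr::map_dfr(features, function(f) {
    purrr::map_dfr(antigens, function(a) {
      tidy(suppressMessages(fisher_association(calls, meta, a, f)))
    })
  })
  out$p_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  out
}

#' Neoplasm-stratified signal proportion table
#'
#' For each neoplasm category with at least `min_group_size` PNP patients,
#' the fraction of patients whose signal exceeds `threshold` (default 1000
#' fluorescence units), per antigen. Categories below the size floor are
#' dropped.
#'
#' @param matrix A `sero_signal` tibble.
#' @param meta Sample metadata; only PNP samples with a known neoplasm are
#'   stratified.
#' @param threshold Positive signal threshold.
#' @param min_group_size Smallest neoplasm group reported (default 2).
#' @return Long tibble `neoplasm`, `antigen_id`, `n`, `proportion`.
#' @export
proportion_heatmap <- function(matrix, meta, threshold = 1000, min_group_size = 2) {
  if (threshold <= 0) {
    abort("threshold must be > 0", class = "pnpsero_argument_error")
  }
  meta <- as_sample_meta(meta)
  meta <- meta[meta$sample_id %in% matrix$sample_id, ]
  strat <- meta[meta$group == "PNP" & !is.na(meta$neoplasm), ]
  vals <- signal_values(matrix)
  groups <- split(strat$sample_id, strat$neoplasm)
  groups <- groups[lengths(groups) >= min_group_size]
  purrr::imap_dfr(groups, function(ids, neo) {
    above <- colMeans(vals[ids, , drop = FALSE] > threshold)
    tibble(neoplasm = neo, antigen_id = names(above),
      n = length(ids), proportion = unname(above))
  })
}

#' Principal component analysis of autoantibody signal profiles
#'
#' Decomposes the (transformed) samples-by-antigens matrix by SVD.
#' The default transform is log10(signal + 1), centered and unit-scaled
#' per antigen: serological intensities span orders of magnitude, and
#' without the log a handful of extreme titers dominates every component.
#' `raw_centered` centers the raw intensities only. Per-component antigen
#' contributions (squared loading share, in %) identify the antigens
#' driving each axis.
#'
#' @param matrix A `sero_signal` tibble with >= 2 samples and >= 2
#'   antigens.
#' @param transform `"log10p1_scaled"` (default) or `"raw_centered"`.
#' @return A `sero_pca` object: `scores` tibble (sample_id + PC columns),
#'   `loadings` tibble (antigen_id + PC columns), `contributions` (same
#'   shape as loadings, percent per component), `variance_explained`
#'   (percent per component, non-increasing).
#' @export
pca_profiles <- function(matrix, transform = c("log10p1_scaled", "raw_centered")) {
  transform <- match.arg(transform)
  vals <- signal_values(matrix)
  if (nrow(vals) < 2 || ncol(vals) < 2) {
    abort("PCA needs at least 2 samples and 2 antigens",
      class = "pnpsero_argument_error")
  }
  x <- if (transform == "log10p1_scaled") log10(vals + 1) else vals
  sds <- apply(x, 2, sd)
  if (all(sds == 0)) {
    warn("constant matrix: PCA is degenerate, zero variance explained")
    k <- min(nrow(vals) - 1, ncol(vals))
    zero_scores <- matrix(0, nrow(vals), k)
    zero_load <- matrix(0, ncol(vals), k)
    colnames(zero_scores) <- colnames(zero_load) <- paste0("PC", seq_len(k))
    return(new_sero_pca(rownames(vals), colnames(vals), zero_scores, zero_load,
      rep(0, k), transform))
  }
  scale_arg <- if (transform == "log10p1_scaled") {
    # constant antigens carry no information; leave them unscaled
    ifelse(sds > 0, sds, 1)
  } else {
    FALSE
  }
  fit <- prcomp(x, center = TRUE, scale. = scale_arg)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  new_sero_pca(rownames(vals), colnames(vals), fit$x, fit$rotation, ve, transform)
}

new_sero_pca <- function(sample_ids, antigen_ids, scores, loadings, ve, transform) {
  contrib <- apply(loadings, 2, function(l) {
    s <- sum(l^2)
    if (s == 0) rep(0, length(l)) else 100 * l^2 / s
  })
  structure(
    list(
      scores = dplyr::bind_cols(tibble(sample_id = sample_ids), as_tibble(scores)),
      loadings = dplyr::bind_cols(tibble(antigen_id = antigen_ids), as_tibble(loadings)),
      contributions = dplyr::bind_cols(
        tibble(antigen_id = antigen_ids),
        as_tibble(contrib)
      ),
      variance_explained = as.numeric(ve),
      transform = transform
    ),
    class = "sero_pca"
  )
}

#' @export
print.sero_pca <- function(x, ...) {
  k <- min(4, length(x$variance_explained))
  cat(sprintf("# PCA of autoantibody profiles (%s): %d samples x %d antigens\n",
    x$transform, nrow(x$scores), nrow(x$loadings)))
  cat("  variance explained (%):",
    paste(sprintf("PC%d=%.1f", seq_len(k), x$variance_explained[seq_len(k)]),
      collapse = ", "), "\n")
  invisible(x)
}

#' Top contributing antigens per principal component
#'
#' @param pca A `sero_pca` object.
#' @param component Component number.
#' @param n How many antigens.
#' @return Tibble `antigen_id`, `contribution` (percent), `loading`.
#' @export
top_contributors <- function(pca, component = 1, n = 5) {
  pc <- paste0("PC", component)
  tibble(
    antigen_id = pca$contributions$antigen_id,
    contribution = pca$contributions[[pc]],
    loading = pca$loadings[[pc]]
  ) |>
    arrange(desc(.data$contribution)) |>
    utils::head(n)
}
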