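#' Collapse duplicate microarray spots to per-sample signals
#'
#' Proteins are printed in duplicate; the per-sample signal for a protein
#' is defined as the maximum of its two replicate spots. Pairs with any
#' other replicate count are a structural error.
#'
#' @param spots Long tibble with columns `sample_id`, `antigen_id`,
#'   `replicate`, `signal` and exactly two rows per (sample, antigen).
#' @return A microarray `sero_signal` tibble.
#' @examples
#' spots <- tibble::tibble(
#'   sample_id = "s1", antigen_id = "PKP1",
#'   replicate = 1:2, signal = c(3.1, 5.2)
#' )
#' collapse_duplicates(spots) # s1/PKP1 -> 5.2
#' @export
collapse_duplicates <- function(spots) {
  spots <- as_tibble(spots)
  req <- c("sample_id", "antigen_id", "signal")
  if (!all(req %in% names(spots))) {
    abort(sprintf("spot table needs columns: %s", paste(req, collapse = ", ")),
      class = "pnpsero_format_error")
  }
  counts <- dplyr::count(spots, .data$sample_id, .data$antigen_id)
  bad <- filter(counts, n != 2L)
  if (nrow(bad) > 0) {
    abort(
      sprintf(
        "expected exactly 2 replicate spots per (sample, antigen); offending pair(s): %s",
        paste(sprintf("(%s, %s): %d", bad$sample_id, bad$antigen_id, bad$n)[
          seq_len(min(5, nrow(bad)))], collapse = "; ")
      ),
      class = "pnpsero_structure_error"
    )
  }
  wide <- spots |>
    group_by(.data$sample_id, .data$antigen_id) |>
    summarise(signal = max(.data$signal), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "antigen_id", values_from = "signal")
  # preserve first-appearance order of samples and antigens from the input
  wide <- wide[match(unique(spots$sample_id), wide$sample_id),
    c("sample_id", unique(spots$antigen_id))]
  as_signal_matrix(wide, assay = "microarray")
}

#' Quantile-normalize signal distributions across samples
#'
#' Forces every sample's value distribution onto the common rank-mean
#' reference (the mean of the per-sample sorted vectors), preserving
#' within-sample ranks. Used to control for technical variation between
#' arrays before case-control enrichment. Ties within a sample receive the
#' mean of the reference values across their rank span.
#'
#' @param matrix A `sero_signal` tibble with at least 2 samples (a single
#'   sample is returned unchanged with a warning).
#' @return A `sero_signal` tibble of the same shape.
#' @examples
#' m <- as_signal_matrix(
#'   data.frame(sample_id = c("a", "b"), g1 = c(1, 4), g2 = c(2, 5), g3 = c(3, 6))
#' )
#' quantile_normalize(m) # both samples become 2.5, 3.5, 4.5
#' @export
quantile_normalize <- function(matrix) {
  vals <- signal_values(matrix)
  if (nrow(vals) < 2) {
    warn("quantile normalization needs >= 2 samples; returning input unchanged")
    return(matrix)
  }
  sorted <- apply(vals, 1, sort) # antigens x samples
  ref <- rowMeans(sorted)
  out <- t(apply(vals, 1, function(x) {
    pos <- integer(length(x))
    pos[order(x)] <- seq_along(x)
    # tie groups share the mean reference value over their rank span
    stats::ave(ref[pos], match(x, x), FUN = mean)
  }))
  dimnames(out) <- dimnames(vals)
  signal_from_values(out, matrix)
}

#' Case-control fold-change enrichment per antigen
#'
#' For each antigen, computes the arithmetic mean signal in cases and in
#' controls and the enrichment `log2((mu_cases + epsilon) / (mu_controls +
#' epsilon))`; antigens are ranked by descending log2 fold change (ties
#' broken by antigen id). `epsilon` (default 1 intensity unit) guards
#' against zero means.
#'
#' @param matrix A `sero_signal` tibble (typically duplicate-collapsed and
#'   quantile-normalized).
#' @param case_ids,control_ids Disjoint, non-empty sample id sets.
#' @param epsilon Pseudo-intensity added to both means.
#' @return An enrichment tibble: `antigen_id`, `mu_cases`, `mu_controls`,
#'   `log2fc`, `rank`.
#' @export
fold_change <- function(matrix, case_ids, control_ids, epsilon = 1) {
  if (length(case_ids) == 0 || length(control_ids) == 0) {
    abort("case and control sets must be non-empty", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, control_ids)
  assert_samples_present(matrix, c(case_ids, control_ids))
  vals <- signal_values(matrix)
  mu_cases <- colMeans(vals[case_ids, , drop = FALSE])
  mu_controls <- colMeans(vals[control_ids, , drop = FALSE])
  out <- tibble(
    antigen_id = colnames(vals),
    mu_cases = unname(mu_cases),
    mu_controls = unname(mu_controls),
    log2fc = log2((mu_cases + epsilon) / (mu_controls + epsilon))
  )
  out <- arrange(out, desc(.data$log2fc), .data$antigen_id)
  out$rank <- seq_len(nrow(out))
  out
}

#' Autoantibody repertoire size at an enrichment threshold
#'
#' Counts antigens whose |log2 fold change| meets the threshold,
#' annotating the direction (positive = enriched in cases, negative =
#' enriched in controls). The headline repertoire comparison uses
#' threshold 2.5, i.e. five- to six-fold enrichment.
#'
#' @param enrichment An enrichment tibble from [fold_change()].
#' @param threshold Positive threshold on |log2 FC|.
#' @return A `sero_repertoire` tibble of hits (`antigen_id`, `log2fc`,
#'   `direction`) with attributes `k = 0`, `threshold`, and `n_hits`.
#' @export
repertoire_size <- function(enrichment, threshold = 2.5) {
  if (threshold <= 0) {
    abort("threshold must be > 0", class = "pnpsero_argument_error")
  }
  hits <- enrichment |>
    filter(abs(.data$log2fc) >= threshold) |>
    mutate(direction = ifelse(.data$log2fc > 0, "positive", "negative")) |>
    select("antigen_id", "log2fc", "direction") |>
    arrange(desc(abs(.data$log2fc)), .data$antigen_id)
  structure(hits,
    k = 0L, threshold = threshold, n_hits = nrow(hits),
    class = c("sero_repertoire", class(hits))
  )
}

#' Shared-reactivity repertoire via leave-k-out enrichment
#'
#' Private reactivities — antigens driven by a single extreme patient —
#' inflate a naive repertoire count. For each antigen this re-computes the
#' case mean after excluding the k case samples with the strongest signal
#' for that antigen; antigens still meeting the fold-change threshold are
#' shared by at least k + 1 patients. `k = 0` reduces to the
#' positive-direction hits of [repertoire_size()] on [fold_change()]
#' output.
#'
#' @param matrix A `sero_signal` tibble.
#' @param case_ids,control_ids Disjoint sample id sets; `k < length(case_ids)`.
#' @param k Number of strongest case samples excluded per antigen.
#' @param threshold Hit threshold on the recomputed log2 FC.
#' @param epsilon Pseudo-intensity, as in [fold_change()].
#' @return A `sero_repertoire` tibble of shared hits with attributes `k`,
#'   `threshold`, `n_hits`.
#' @export
leave_k_out_repertoire <- function(matrix, case_ids, control_ids, k,
                                   threshold = 2.5, epsilon = 1) {
  k <- as.integer(k)
  if (k < 0 || k >= length(case_ids)) {
    abort("k must satisfy 0 <= k < number of cases", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, control_ids)
  assert_samples_present(matrix, c(case_ids, control_ids))
  vals <- signal_values(matrix)
  cases <- vals[case_ids, , drop = FALSE]
  mu_controls <- colMeans(vals[control_ids, , drop = FALSE])
  mu_cases <- if (k == 0) {
    colMeans(cases)
  } else {
    apply(cases, 2, function(v) mean(sort(v, decreasing = TRUE)[-seq_len(k)]))
  }
  log2fc <- log2((mu_cases + epsilon) / (mu_controls + epsilon))
  hits <- tibble(
    antigen_id = colnames(vals),
    mu_cases = unname(mu_cases),
    mu_controls = unname(mu_controls),
    log2fc = unname(log2fc)
  ) |>
    filter(.data$log2fc >= threshold) |>
    mutate(direction = "positive") |>
    select("antigen_id", "log2fc", "direction") |>
    arrange(desc(.data$log2fc), .data$antigen_id)
  structure(hits,
    k = k, threshold = threshold, n_hits = nrow(hits),
    class = c("sero_repertoire", class(hits))
  )
}

#' Number of hits in a repertoire result
#'
#' @param x A `sero_repertoire` tibble.
#' @param direction `"both"` (default), `"positive"` or `"negative"`.
#' @return Integer hit count.
#' @export
n_hits <- function(x, direction = c("both", "positive", "negative")) {
  direction <- match.arg(direction)
  if (direction == "both") nrow(x) else sum(x$direction == direction)
}
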