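#' Rank-based two-class AUC of a continuous marker
#'
#' The probability that a random case signal exceeds a random non-case
#' signal, with ties counting one half — the Mann-Whitney identity,
#' computed from midranks. Used to screen antigens before the panel
#' search: only markers with AUC above the prefilter (default 0.50) enter
#' the combinatorial search.
#'
#' @param matrix A `sero_signal` tibble.
#' @param case_ids,noncase_ids Non-empty, disjoint sample id sets.
#' @param antigen Antigen id.
#' @return AUC in \[0, 1\].
#' @examples
#' m <- as_signal_matrix(data.frame(
#'   sample_id = c("c1", "c2", "n1", "n2"), AG = c(10, 20, 1, 2)
#' ), assay = "bead")
#' marker_auc(m, c("c1", "c2"), c("n1", "n2"), "AG") # 1.0
#' @export
marker_auc <- function(matrix, case_ids, noncase_ids, antigen) {
  if (length(case_ids) == 0 || length(noncase_ids) == 0) {
    abort("both classes must be non-empty", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, noncase_ids, c("case", "non-case"))
  assert_samples_present(matrix, c(case_ids, noncase_ids))
  vals <- signal_values(matrix)
  x <- vals[case_ids, antigen]
  y <- vals[noncase_ids, antigen]
  r <- rank(c(x, y), ties.method = "average")
  n1 <- length(x)
  n2 <- length(y)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Screen antigens by AUC for panel-search admission
#'
#' @param matrix A `sero_signal` tibble.
#' @param case_ids,noncase_ids Class sample id sets.
#' @param auc_prefilter Retention threshold (strict `>`; default 0.50).
#' @return Tibble `antigen_id`, `auc_mw`, `retained`.
#' @export
marker_screen <- function(matrix, case_ids, noncase_ids, auc_prefilter = 0.50) {
  purrr::map_dfr(antigen_cols(matrix), function(a) {
    auc <- marker_auc(matrix, case_ids, noncase_ids, a)
    tibble(antigen_id = a, auc_mw = auc, retained = auc > auc_prefilter)
  })
}

#' Exact number of antigen combinations
#'
#' The binomial coefficient n! / ((n - r)! r!): the number of distinct
#' panels of r antigens drawn from n candidates. With n = 15, r = 5 there
#' are 3003 such panels.
#'
#' @param n Total number of antigens.
#' @param r Panel size, `0 <= r <= n`.
#' @return Exact integer-valued count.
#' @export
count_combinations <- function(n, r) {
  if (r < 0 || n < 0 || r > n) {
    abort("need 0 <= r <= n", class = "pnpsero_argument_error")
  }
  choose(n, r)
}

#' Evaluate a union-rule diagnostic panel
#'
#' A sample is panel-positive when it is positive for at least one panel
#' antigen. Sensitivity is the panel-positive fraction of cases,
#' specificity the panel-negative fraction of non-cases, and the panel
#' "AUC" is the balanced accuracy (sensitivity + specificity) / 2 — the
#' trapezoidal area under the one-point ROC of a binary classifier.
#'
#' @param calls A `sero_calls` tibble from [call_positives()].
#' @param antigens Panel antigen ids (subset of the called antigens; an
#'   empty panel is vacuously negative for everyone).
#' @param case_ids,noncase_ids Non-empty, disjoint sample id sets.
#' @return One-row tibble `antigens` (list-column), `size`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
evaluate_panel <- function(calls, antigens, case_ids, noncase_ids) {
  if (length(case_ids) == 0 || length(noncase_ids) == 0) {
    abort("both classes must be non-empty", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, noncase_ids, c("case", "non-case"))
  unknown <- setdiff(antigens, antigen_cols(calls))
  if (length(unknown) > 0) {
    abort(sprintf("unknown antigen(s): %s", paste(unknown, collapse = ", ")),
      class = "pnpsero_argument_error")
  }
  pos <- calls_values(calls)[, antigens, drop = FALSE]
  panel_pos <- rowSums(pos) > 0
  sens <- mean(panel_pos[case_ids])
  spec <- mean(!panel_pos[noncase_ids])
  tibble(
    antigens = list(sort(antigens)), size = length(antigens),
    sensitivity = sens, specificity = spec, auc = (sens + spec) / 2
  )
}

# family-legal subset masks: at most one antigen of each constrained family
legal_masks <- function(antigens, antigen_meta, max_size) {
  n <- length(antigens)
  fam <- rep("none", n)
  if (!is.null(antigen_meta)) {
    antigen_meta <- as_antigen_meta(antigen_meta)
    idx <- match(antigens, antigen_meta$antigen_id)
    fam[!is.na(idx)] <- antigen_meta$family[idx[!is.na(idx)]]
  }
  masks <- 0L
  # grow the legal set one antigen at a time, pruning family violations
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    if (fam[i] == "none") {
      masks <- c(masks, bitwOr(masks, bit))
    } else {
      fam_bits <- Reduce(bitwOr, bitwShiftL(1L, which(fam == fam[i]) - 1L), 0L)
      ok <- bitwAnd(masks, fam_bits) == 0L
      masks <- c(masks, bitwOr(masks[ok], bit))
    }
  }
  masks <- masks[masks != 0L]
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0), 0)
  masks[sizes <= max_size]
}

#' Exhaustively search union-rule panels for the best balanced AUC
#'
#' Enumerates every family-legal subset of the retained antigens from size
#' 1 up to `max_size` (at most one antigen per cross-reactive family,
#' enforced during enumeration) and scores each as a union-rule panel.
#' Results are ranked by balanced AUC, then smaller panels first
#' (parsimony), then lexicographically. Internally each sample's
#' positivity pattern is encoded as a bitmask so all panels are scored
#' with a single pattern-by-mask product.
#'
#' @param calls A `sero_calls` tibble.
#' @param screen A [marker_screen()] tibble; only `retained` antigens are
#'   enumerated. `NULL` retains every called antigen.
#' @param antigen_meta Antigen metadata with family tags, or `NULL` for no
#'   constraint.
#' @param case_ids,noncase_ids Class sample id sets.
#' @param max_size Largest panel size (default 15).
#' @param guard Maximum retained antigens before refusing to enumerate
#'   (default 25).
#' @return A `panel_search` tibble of every evaluated panel, ranked; the
#'   number of evaluated panels is attached as attribute `n_evaluated`.
#' @export
exhaustive_search <- function(calls, screen = NULL, antigen_meta = NULL,
                              case_ids, noncase_ids, max_size = 15,
                              guard = 25) {
  antigens <- antigen_cols(calls)
  if (!is.null(screen)) {
    antigens <- intersect(antigens, screen$antigen_id[screen$retained])
  }
  n <- length(antigens)
  if (n == 0) {
    abort("no antigens retained for the panel search", class = "pnpsero_argument_error")
  }
  if (n > guard) {
    abort(
      sprintf(paste0(
        "%d retained antigens would enumerate too many panels; ",
        "tighten the AUC prefilter or raise `guard`"), n),
      class = "pnpsero_capacity_error"
    )
  }
  if (length(case_ids) == 0 || length(noncase_ids) == 0) {
    abort("both classes must be non-empty", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, noncase_ids, c("case", "non-case"))

  masks <- legal_masks(antigens, antigen_meta, max_size)
  pos <- calls_values(calls)[, antigens, drop = FALSE]
  pattern <- as.integer(pos %*% bitwShiftL(1L, seq_len(n) - 1L))
  names(pattern) <- rownames(pos)

  score_class <- function(ids) {
    tab <- table(pattern[ids])
    pats <- as.integer(names(tab))
    cnt <- as.numeric(tab)
    hit <- outer(masks, pats, bitwAnd) > 0
    as.numeric(hit %*% cnt) / length(ids)
  }
  sens <- score_class(case_ids)
  fpr <- score_class(noncase_ids)
  spec <- 1 - fpr

  bits <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0))
  panel_list <- lapply(bits, function(i) antigens[i])
  out <- tibble(
    antigens = panel_list,
    size = lengths(panel_list),
    sensitivity = sens,
    specificity = spec,
    auc = (sens + spec) / 2
  )
  key <- vapply(out$antigens, function(a) paste(sort(a), collapse = "+"), "")
  out <- out[order(-out$auc, out$size, key), ]
  out$rank <- seq_len(nrow(out))
  structure(out,
    n_evaluated = length(masks),
    class = c("panel_search", class(out))
  )
}
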