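#' Per-antigen positivity cutoffs from healthy controls
#'
#' The bead-array positivity rule: an antigen's cutoff is the healthy-
#' control mean + `multiplier` standard deviations (sample SD, n - 1
#' denominator), floored at `floor` MFI units — by default mean + 5 SD or
#' at least 500 MFI. The floor makes weak-signal antigens conservative.
#' `rule = "min"` gives the alternative reading where the 500-MFI level
#' caps the cutoff instead.
#'
#' @param matrix A bead `sero_signal` tibble.
#' @param hc_ids Healthy-control sample ids (at least 2).
#' @param multiplier SD multiplier (default 5).
#' @param floor MFI floor (default 500).
#' @param rule `"max"` (default) or `"min"`.
#' @return A `sero_cutoffs` tibble: `antigen_id`, `hc_mean`, `hc_sd`,
#'   `cutoff`.
#' @examples
#' m <- as_signal_matrix(
#'   data.frame(sample_id = c("h1", "h2", "h3"), AG = c(100, 200, 300)),
#'   assay = "bead"
#' )
#' compute_cutoffs(m, hc_ids = c("h1", "h2", "h3"))
#' @export
compute_cutoffs <- function(matrix, hc_ids, multiplier = 5, floor = 500,
                            rule = c("max", "min")) {
  rule <- match.arg(rule)
  if (length(hc_ids) < 2) {
    abort("need at least 2 healthy controls to estimate cutoffs",
      class = "pnpsero_estimation_error")
  }
  assert_samples_present(matrix, hc_ids, "healthy control")
  vals <- signal_values(matrix)[hc_ids, , drop = FALSE]
  hc_mean <- colMeans(vals)
  hc_sd <- apply(vals, 2, sd)
  combine <- if (rule == "max") pmax else pmin
  out <- tibble(
    antigen_id = colnames(vals),
    hc_mean = unname(hc_mean),
    hc_sd = unname(hc_sd),
    cutoff = unname(combine(hc_mean + multiplier * hc_sd, floor))
  )
  structure(out, multiplier = multiplier, floor = floor, rule = rule,
    class = c("sero_cutoffs", class(out)))
}

#' Call sample positivity against per-antigen cutoffs
#'
#' A sample is positive for an antigen when its signal strictly exceeds
#' the cutoff; ties at the cutoff are negative (conservative).
#'
#' @param matrix A bead `sero_signal` tibble.
#' @param cutoffs A `sero_cutoffs` tibble covering the same antigens.
#' @return A `sero_calls` tibble: `sample_id` plus one logical column per
#'   antigen, with the cutoff table attached as attribute `cutoffs`.
#' @export
call_positives <- function(matrix, cutoffs) {
  vals <- signal_values(matrix)
  mismatch <- union(
    setdiff(colnames(vals), cutoffs$antigen_id),
    setdiff(cutoffs$antigen_id, colnames(vals))
  )
  if (length(mismatch) > 0) {
    abort(
      sprintf("antigen sets differ between matrix and cutoffs: %s",
        paste(mismatch, collapse = ", ")),
      class = "pnpsero_argument_error"
    )
  }
  cut <- setNames(cutoffs$cutoff, cutoffs$antigen_id)[colnames(vals)]
  pos <- sweep(vals, 2, cut, `>`)
  out <- as_tibble(pos)
  out <- dplyr::bind_cols(tibble(sample_id = rownames(vals)), out)
  structure(out, cutoffs = cutoffs, class = c("sero_calls", class(out)))
}

calls_values <- function(calls) {
  m <- as.matrix(calls[antigen_cols(calls)])
  rownames(m) <- calls$sample_id
  storage.mode(m) <- "logical"
  m
}

#' Seroprevalence of an antigen in a sample group
#'
#' Positive fraction among the group, with the percentage rounded half
#' away from zero to match printed integer prevalences (e.g. 13/14 -> 93%).
#'
#' @param calls A `sero_calls` tibble from [call_positives()].
#' @param group_ids Non-empty sample id set.
#' @param antigen Antigen id.
#' @return Tibble `antigen_id`, `count`, `total`, `percent`.
#' @export
prevalence <- function(calls, group_ids, antigen) {
  if (length(group_ids) == 0) {
    abort("group is empty", class = "pnpsero_argument_error")
  }
  assert_samples_present(calls, group_ids, "group")
  if (!antigen %in% antigen_cols(calls)) {
    abort(sprintf("unknown antigen '%s'", antigen), class = "pnpsero_argument_error")
  }
  pos <- calls_values(calls)[group_ids, antigen]
  count <- sum(pos)
  total <- length(pos)
  tibble(
    antigen_id = antigen, count = count, total = total,
    percent = round_half_up(100 * count / total)
  )
}

#' Group-by-antigen seroprevalence summary
#'
#' @param calls A `sero_calls` tibble.
#' @param meta Sample metadata covering the called samples.
#' @return Long tibble `group`, `antigen_id`, `count`, `total`, `percent`.
#' @export
prevalence_by_group <- function(calls, meta) {
  meta <- as_sample_meta(meta)
  missing <- setdiff(calls$sample_id, meta$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("no metadata for sample(s): %s", paste(missing, collapse = ", ")),
      class = "pnpsero_join_error")
  }
  meta <- meta[meta$sample_id %in% calls$sample_id, ]
  sets <- split(meta$sample_id, meta$group)
  purrr::imap_dfr(sets, function(ids, grp) {
    purrr::map_dfr(antigen_cols(calls), function(a) {
      mutate(prevalence(calls, ids, a), group = grp, .before = 1)
    })
  })
}

#' False-discovery summary of a validated antigen
#'
#' The false discovery rate of an antigen's positivity call is the share
#' of its positives that fall outside the case group: FP / (FP + TP),
#' where TP counts case positives and FP counts non-case positives; 0 by
#' convention when there are no positives at all. The companion count of
#' raw non-case positives is also returned, since "0% FDR" is sometimes
#' read simply as zero control positives.
#'
#' @param calls A `sero_calls` tibble.
#' @param case_ids,noncase_ids Disjoint, non-empty sample id sets.
#' @param antigen Antigen id.
#' @return Tibble `antigen_id`, `tp`, `fp`, `fdr` (proportion in \[0, 1\]),
#'   `fdr_percent`.
#' @export
false_discovery_rate <- function(calls, case_ids, noncase_ids, antigen) {
  if (length(case_ids) == 0 || length(noncase_ids) == 0) {
    abort("case and non-case sets must be non-empty", class = "pnpsero_argument_error")
  }
  assert_disjoint(case_ids, noncase_ids, c("case", "non-case"))
  pos <- calls_values(calls)[, antigen]
  tp <- sum(pos[case_ids])
  fp <- sum(pos[noncase_ids])
  fdr <- if (tp + fp == 0) 0 else fp / (tp + fp)
  tibble(
    antigen_id = antigen, tp = tp, fp = fp, fdr = fdr,
    fdr_percent = round_half_up(100 * fdr)
  )
}
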