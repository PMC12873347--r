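# shared fixture builders: everything is generated in code at test time

# small wide signal tibble from a plain matrix
sig <- function(values, assay = "bead", samples = NULL, antigens = NULL) {
  values <- as.matrix(values)
  samples <- samples %||% sprintf("s%d", seq_len(nrow(values)))
  antigens <- antigens %||% sprintf("AG%d", seq_len(ncol(values)))
  df <- as.data.frame(values)
  names(df) <- antigens
  df <- cbind(data.frame(sample_id = samples), df)
  as_signal_matrix(df, assay = assay)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# positivity calls straight from a logical matrix (cutoff bookkeeping not
# under test)
calls_from_logical <- function(pos, samples = NULL, antigens = NULL) {
  pos <- as.matrix(pos)
  samples <- samples %||% sprintf("s%d", seq_len(nrow(pos)))
  antigens <- antigens %||% sprintf("AG%d", seq_len(ncol(pos)))
  m <- sig(ifelse(pos, 1000, 0), samples = samples, antigens = antigens)
  cuts <- compute_cutoffs(
    sig(matrix(0, 2, ncol(pos)), samples = c("hc_a", "hc_b"), antigens = antigens),
    hc_ids = c("hc_a", "hc_b")
  )
  call_positives(m, cuts)
}

# a small bead cohort with one strongly planted antigen
small_bead_spec <- function(seed = 1, n_pnp = 20, n_hc = 30,
                            prevalence = 0.5, effect = 50) {
  cohort_spec(
    n_per_group = c(PNP = n_pnp, HC = n_hc),
    n_antigens_background = 4,
    planted_reactivities = tibble::tibble(
      antigen_id = "SERPINB3", target_group = "PNP",
      prevalence = prevalence, effect_multiplier = effect
    ),
    seed = seed
  )
}

# independent brute-force panel evaluator: loops subsets, scores each with
# hand-rolled union logic (no calls into evaluate_panel / exhaustive_search)
brute_force_panels <- function(calls, antigens, case_ids, noncase_ids,
                               max_size = length(antigens),
                               antigen_meta = NULL) {
  pos <- as.matrix(calls[setdiff(names(calls), "sample_id")])
  rownames(pos) <- calls$sample_id
  fam <- setNames(rep("none", length(antigens)), antigens)
  if (!is.null(antigen_meta)) {
    idx <- match(antigens, antigen_meta$antigen_id)
    fam[!is.na(idx)] <- antigen_meta$family[idx[!is.na(idx)]]
  }
  rows <- list()
  for (r in seq_len(min(max_size, length(antigens)))) {
    combos <- utils::combn(antigens, r, simplify = FALSE)
    for (cmb in combos) {
      f <- fam[cmb]
      tab <- table(f[f != "none"])
      if (length(tab) > 0 && any(tab > 1)) next
      panel_pos <- apply(pos[, cmb, drop = FALSE], 1, any)
      sens <- mean(panel_pos[case_ids])
      spec <- mean(!panel_pos[noncase_ids])
      rows[[length(rows) + 1]] <- data.frame(
        panel = paste(sort(cmb), collapse = "+"),
        size = r, sensitivity = sens, specificity = spec,
        auc = (sens + spec) / 2
      )
    }
  }
  do.call(rbind, rows)
}

# independent rank-mean quantile normalization oracle (loop-based)
qn_oracle <- function(values) {
  sorted <- apply(values, 1, sort)
  ref <- rowMeans(sorted)
  out <- values
  for (i in seq_len(nrow(values))) {
    x <- values[i, ]
    o <- order(x)
    pos <- integer(length(x))
    pos[o] <- seq_along(x)
    for (v in unique(x)) {
      span <- pos[x == v]
      out[i, x == v] <- mean(ref[span])
    }
  }
  out
}

# independent two-sided Fisher oracle: enumerate the hypergeometric support
# and sum probabilities <= the observed table's (with the conventional
# relative tolerance for floating-point equality)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
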