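test_that("duplicate spots collapse to the per-pair maximum", {
  spots <- tibble::tibble(
    sample_id = rep("s1", 4),
    antigen_id = rep(c("A", "B"), each = 2),
    replicate = rep(1:2, 2),
    signal = c(3.1, 5.2, 7, 7)
  )
  m <- collapse_duplicates(spots)
  expect_equal(m$A, 5.2)
  expect_equal(m$B, 7)

  triple <- dplyr::bind_rows(spots,
    tibble::tibble(sample_id = "s1", antigen_id = "A", replicate = 3L, signal = 1))
  err <- expect_error(collapse_duplicates(triple), class = "pnpsero_structure_error")
  expect_match(conditionMessage(err), "s1, A")
})

test_that("quantile normalization maps samples onto the rank-mean reference", {
  m <- sig(rbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unlist(qn[1, -1], use.names = FALSE), c(2.5, 3.5, 4.5))
  expect_equal(unlist(qn[2, -1], use.names = FALSE), c(2.5, 3.5, 4.5))

  # identical samples pass through unchanged
  same <- sig(rbind(c(2, 9, 4), c(2, 9, 4)))
  expect_equal(as.data.frame(quantile_normalize(same)), as.data.frame(same))

  # defining property: per-sample sorted vectors identical across samples
  set.seed(31)
  r <- sig(matrix(rlnorm(6 * 20), 6, 20))
  qr <- quantile_normalize(r)
  sorted <- apply(as.matrix(qr[-1]), 1, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))

  # ranks within each sample are preserved
  expect_equal(
    t(apply(as.matrix(qr[-1]), 1, rank)),
    t(apply(as.matrix(r[-1]), 1, rank))
  )
})

test_that("quantile normalization is idempotent and matches the loop oracle", {
  set.seed(77)
  vals <- matrix(rlnorm(5 * 7, log(100), 0.8), 5, 7)
  m <- sig(vals)
  qn1 <- quantile_normalize(m)
  qn2 <- quantile_normalize(qn1)
  expect_equal(as.data.frame(qn2), as.data.frame(qn1), tolerance = 1e-12)
  expect_equal(unname(as.matrix(qn1[-1])), unname(qn_oracle(vals)), tolerance = 1e-12)

  # ties share the mean of the reference values over their rank span
  tied <- sig(rbind(c(5, 5, 1), c(10, 20, 30)))
  qt <- quantile_normalize(tied)
  ref <- sort(rowMeans(apply(rbind(c(5, 5, 1), c(10, 20, 30)), 1, sort)))
  expect_equal(unlist(qt[1, -1], use.names = FALSE),
    c(mean(ref[2:3]), mean(ref[2:3]), ref[1]))
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(5)
  vals <- matrix(rlnorm(8 * 40, log(200), 0.6), 8, 40)
  ours <- as.matrix(quantile_normalize(sig(vals))[-1])
  # limma normalizes columns; our samples are rows
  theirs <- t(limma::normalizeQuantiles(t(vals), ties = TRUE))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("single-sample normalization is a warned no-op", {
  one <- sig(matrix(c(3, 1, 2), 1, 3))
  expect_warning(out <- quantile_normalize(one), "2 samples")
  expect_equal(as.data.frame(out), as.data.frame(one))
})

test_that("fold change reproduces hand-computed means and ranks", {
  m <- sig(matrix(c(2, 4, 6, 1, 3), 5, 1), samples = sprintf("s%d", 1:5),
    antigens = "AG")
  fc <- fold_change(m, case_ids = c("s1", "s2", "s3"),
    control_ids = c("s4", "s5"), epsilon = 0)
  expect_equal(fc$mu_cases, 4)
  expect_equal(fc$mu_controls, 2)
  expect_equal(fc$log2fc, 1)

  m2 <- sig(rbind(c(8, 4), c(8, 4), c(2, 4), c(2, 4)),
    samples = sprintf("s%d", 1:4), antigens = c("up", "flat"))
  fc2 <- fold_change(m2, c("s1", "s2"), c("s3", "s4"), epsilon = 0)
  expect_equal(fc2$log2fc[fc2$antigen_id == "up"], 2)
  expect_equal(fc2$log2fc[fc2$antigen_id == "flat"], 0)
  expect_equal(fc2$antigen_id[fc2$rank == 1], "up") # ranked by descending log2fc

  expect_error(fold_change(m2, c("s1", "s2"), c("s2", "s3")),
    class = "pnpsero_argument_error")
})

test_that("fold change is antisymmetric under case/control swap", {
  set.seed(13)
  m <- sig(matrix(rlnorm(10 * 25, log(100), 0.5), 10, 25))
  cases <- sprintf("s%d", 1:5)
  ctrls <- sprintf("s%d", 6:10)
  fwd <- fold_change(m, cases, ctrls, epsilon = 0)
  rev <- fold_change(m, ctrls, cases, epsilon = 0)
  expect_equal(
    fwd$log2fc[order(fwd$antigen_id)],
    -rev$log2fc[order(rev$antigen_id)],
    tolerance = 1e-12
  )
})

test_that("repertoire size counts hits in both directions", {
  enr <- tibble::tibble(
    antigen_id = c("a", "b", "c", "d"),
    mu_cases = 1, mu_controls = 1,
    log2fc = c(3.0, 2.5, 2.49, -2.6),
    rank = 1:4
  )
  rep0 <- repertoire_size(enr, threshold = 2.5)
  expect_equal(n_hits(rep0), 3)
  expect_equal(n_hits(rep0, "positive"), 2)
  expect_equal(n_hits(rep0, "negative"), 1)

  none <- repertoire_size(dplyr::mutate(enr, log2fc = 0), threshold = 2.5)
  expect_equal(n_hits(none), 0)

  # threshold monotonicity
  counts <- vapply(c(1, 2, 2.5, 3, 4), function(th) {
    n_hits(repertoire_size(enr, th))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("leave-k-out discounts private reactivities and reduces at k = 0", {
  # one extreme case drives the enrichment of antigen "private"; antigen
  # "shared" is elevated in every case
  m <- sig(
    rbind(
      c(10000, 500), c(10, 500), c(12, 480), c(9, 520), c(11, 510), # cases
      c(10, 10), c(12, 11), c(11, 9), c(9, 12) # controls
    ),
    samples = sprintf("s%d", 1:9), antigens = c("private", "shared")
  )
  cases <- sprintf("s%d", 1:5)
  ctrls <- sprintf("s%d", 6:9)

  k0 <- leave_k_out_repertoire(m, cases, ctrls, k = 0, threshold = 2.5, epsilon = 0)
  expect_setequal(k0$antigen_id, c("private", "shared"))
  # k = 0 equals the positive-direction repertoire on fold_change output
  ref <- repertoire_size(fold_change(m, cases, ctrls, epsilon = 0), 2.5)
  expect_setequal(k0$antigen_id, ref$antigen_id[ref$direction == "positive"])

  # hand recomputation at k = 1: private mean drops to mean(10,12,9,11) = 10.5
  k1 <- leave_k_out_repertoire(m, cases, ctrls, k = 1, threshold = 2.5, epsilon = 0)
  expect_equal(k1$antigen_id, "shared")
  expect_false("private" %in% k1$antigen_id)

  # an antigen elevated in all cases stays a hit for every admissible k
  for (k in 0:4) {
    expect_true("shared" %in%
      leave_k_out_repertoire(m, cases, ctrls, k, 2.5, epsilon = 0)$antigen_id)
  }
  expect_error(leave_k_out_repertoire(m, cases, ctrls, k = 5),
    class = "pnpsero_argument_error")
})

test_that("repertoire size is non-increasing in k", {
  spec <- cohort_spec(
    n_per_group = c(PNP = 14, HC = 18), n_antigens_background = 120,
    planted_reactivities = tibble::tibble(
      antigen_id = sprintf("HIT%02d", 1:8), target_group = "PNP",
      prevalence = 0.5, effect_multiplier = 30
    ),
    duplicate_cv = 0.1, seed = 21
  )
  sim <- simulate_microarray(spec)
  m <- quantile_normalize(collapse_duplicates(sim$spots))
  cases <- sim$meta$sample_id[sim$meta$group == "PNP"]
  ctrls <- sim$meta$sample_id[sim$meta$group == "HC"]
  counts <- vapply(0:6, function(k) {
    n_hits(leave_k_out_repertoire(m, cases, ctrls, k))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("the k = 1 shared repertoire recovers planted antigens from simulation", {
  # broadly shared, saturating reactivities (100x background, present in
  # most cases) on a discovery-sized array; joint quantile normalization
  # compresses case-exclusive tails, so recovery is assessed under signal
  # magnitudes typical of genuine autoantibody reactivities
  hits <- 0
  planted_total <- 0
  background_hits <- 0
  for (seed in 1:6) {
    spec <- cohort_spec(
      n_per_group = c(PNP = 14, HC = 18), n_antigens_background = 2000,
      planted_reactivities = tibble::tibble(
        antigen_id = sprintf("HIT%02d", 1:21), target_group = "PNP",
        prevalence = 0.8, effect_multiplier = 100
      ),
      duplicate_cv = 0.1, seed = seed
    )
    sim <- simulate_microarray(spec)
    m <- quantile_normalize(collapse_duplicates(sim$spots))
    cases <- sim$meta$sample_id[sim$meta$group == "PNP"]
    ctrls <- sim$meta$sample_id[sim$meta$group == "HC"]
    k1 <- leave_k_out_repertoire(m, cases, ctrls, k = 1)
    hits <- hits + sum(grepl("^HIT", k1$antigen_id))
    planted_total <- planted_total + 21
    background_hits <- background_hits + sum(grepl("^BG", k1$antigen_id))
  }
  expect_gte(hits / planted_total, 0.95)
  expect_equal(background_hits, 0)
})
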