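# construct calls + metadata realizing a given 2x2 table of
# feature (bronchiolitis obliterans) x positivity among PNP samples
assoc_fixture <- function(a, b, c, d) {
  n <- a + b + c + d
  ids <- sprintf("s%d", seq_len(n))
  pos <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  bo <- c(rep(TRUE, a + b), rep(FALSE, c + d))
  calls <- calls_from_logical(matrix(pos, n, 1), samples = ids,
    antigens = "SERPINB3")
  meta <- data.frame(sample_id = ids, group = "PNP",
    bronchiolitis_obliterans = bo)
  list(calls = calls, meta = meta)
}

test_that("Fisher's exact p matches hand-enumerated hypergeometric sums", {
  fx <- assoc_fixture(5, 0, 0, 5)
  res <- fisher_association(fx$calls, fx$meta, "SERPINB3",
    "bronchiolitis_obliterans")
  expect_equal(res$p_two_sided, 2 / 252, tolerance = 1e-12) # 2 / C(10,5)

  balanced <- assoc_fixture(2, 2, 2, 2)
  expect_equal(
    fisher_association(balanced$calls, balanced$meta, "SERPINB3",
      "bronchiolitis_obliterans")$p_two_sided, 1)

  indep <- assoc_fixture(10, 10, 10, 10)
  expect_equal(
    fisher_association(indep$calls, indep$meta, "SERPINB3",
      "bronchiolitis_obliterans")$p_two_sided, 1)
})

test_that("Fisher's exact matches the enumeration oracle across random tables", {
  set.seed(59)
  for (i in 1:40) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = runif(4, 0.1, 1)))
    fx <- assoc_fixture(cells[1], cells[2], cells[3], cells[4])
    res <- fisher_association(fx$calls, fx$meta, "SERPINB3",
      "bronchiolitis_obliterans")
    expect_equal(res$p_two_sided,
      fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
      tolerance = 1e-7)
  }
})

test_that("zero-margin tables are flagged degenerate with p = 1", {
  fx <- assoc_fixture(0, 6, 0, 6) # nobody positive
  res <- fisher_association(fx$calls, fx$meta, "SERPINB3",
    "bronchiolitis_obliterans")
  expect_true(res$degenerate)
  expect_equal(res$p_two_sided, 1)
})

test_that("samples with undefined features are excluded and reported", {
  fx <- assoc_fixture(3, 2, 2, 3)
  fx$meta$bronchiolitis_obliterans[1] <- NA
  expect_message(
    res <- fisher_association(fx$calls, fx$meta, "SERPINB3",
      "bronchiolitis_obliterans"),
    "excluding 1"
  )
  expect_equal(sum(res$table), 9)
  expect_equal(res$n_excluded, 1)
})

test_that("built-in neoplasm features are evaluated over PNP cases only", {
  ids <- sprintf("s%d", 1:10)
  calls <- calls_from_logical(matrix(c(rep(TRUE, 4), rep(FALSE, 6)), 10, 1),
    samples = ids, antigens = "IFNA1")
  meta <- data.frame(
    sample_id = ids,
    group = c(rep("PNP", 8), "HC", "HC"),
    neoplasm = c(rep("thymoma", 3), rep("solid_tumor", 5), NA, NA)
  )
  res <- fisher_association(calls, meta, "IFNA1", "thymoma")
  expect_equal(sum(res$table), 8) # the two HC samples never enter
  expect_equal(res$table["present", "positive"], 3)
  grid <- association_grid(calls, meta, antigens = "IFNA1",
    features = c("thymoma", "follicular_lymphoma"))
  expect_equal(nrow(grid), 2)
  expect_true(all(grid$p_bh >= grid$p_two_sided - 1e-12))
})

test_that("proportion tables follow the >threshold rule and the size floor", {
  ids <- sprintf("s%d", 1:7)
  m <- sig(matrix(c(1500, 900, 2000, 100, 5000, 100, 800), 7, 1),
    samples = ids, antigens = "SERPINB3")
  meta <- data.frame(
    sample_id = ids, group = "PNP",
    neoplasm = c(rep("lymphoma_follicular", 4), rep("thymoma", 2), "leukemia")
  )
  tab <- proportion_heatmap(m, meta, threshold = 1000, min_group_size = 2)
  expect_equal(tab$proportion[tab$neoplasm == "lymphoma_follicular"], 0.5)
  expect_equal(tab$proportion[tab$neoplasm == "thymoma"], 0.5)
  expect_false("leukemia" %in% tab$neoplasm) # single patient excluded

  # all below threshold -> zero row; proportions bounded in [0, 1]
  low <- sig(matrix(rep(10, 7), 7, 1), samples = ids, antigens = "SERPINB3")
  tab0 <- proportion_heatmap(low, meta)
  expect_true(all(tab0$proportion == 0))

  # invariant to sample order
  perm <- sample(7)
  m_perm <- sig(matrix(c(1500, 900, 2000, 100, 5000, 100, 800)[perm], 7, 1),
    samples = ids[perm], antigens = "SERPINB3")
  tab_perm <- proportion_heatmap(m_perm, meta, threshold = 1000)
  expect_equal(
    tab_perm[order(tab_perm$neoplasm), ],
    tab[order(tab$neoplasm), ]
  )
})

test_that("PCA satisfies the reconstruction and conservation identities", {
  set.seed(61)
  m <- sig(matrix(rlnorm(12 * 6, log(200), 0.7), 12, 6))
  pca <- pca_profiles(m, transform = "raw_centered")
  # variance explained sums to 100 and is non-increasing
  expect_equal(sum(pca$variance_explained), 100, tolerance = 1e-8)
  expect_true(all(diff(pca$variance_explained) <= 1e-8))
  # scores x loadings' reconstructs the centered matrix
  scores <- as.matrix(pca$scores[-1])
  loadings <- as.matrix(pca$loadings[-1])
  vals <- as.matrix(m[-1])
  centered <- scale(vals, center = TRUE, scale = FALSE)
  expect_equal(unname(scores %*% t(loadings)),
    matrix(centered, nrow(centered)), tolerance = 1e-8)
  # loadings are orthonormal
  expect_equal(unname(t(loadings) %*% loadings), diag(ncol(loadings)),
    tolerance = 1e-8)
})

test_that("two perfectly correlated antigens load one component entirely", {
  x <- rlnorm(10, log(100), 0.5)
  m <- sig(cbind(x, 2 * x), antigens = c("SERPINB3", "SERPINB4"))
  pca <- pca_profiles(m, transform = "raw_centered")
  expect_equal(pca$variance_explained[1], 100, tolerance = 1e-8)
})

test_that("a constant matrix degenerates with a warning", {
  m <- sig(matrix(5, 4, 3))
  expect_warning(pca <- pca_profiles(m, transform = "raw_centered"), "degenerate")
  expect_equal(sum(pca$variance_explained), 0)
})

test_that("planted two-block structure dominates the two leading components", {
  # cytokine block carried by a thymoma-like subgroup, serpin block by a
  # second subgroup; background antigens carry no structure, so the top
  # contributors of PC1/PC2 must come from the planted blocks
  cyto <- c("IFNA1", "IFNA2", "IFNA4")
  serp <- c("SERPINB3", "SERPINB4", "A2ML1")
  is_thy <- function(meta) !is.na(meta$neoplasm) & meta$neoplasm == "thymoma"
  is_bo <- function(meta) {
    !is.na(meta$bronchiolitis_obliterans) & meta$bronchiolitis_obliterans
  }
  two_block_spec <- function(seed) {
    cohort_spec(
      n_per_group = c(PNP = 60, HC = 60), n_antigens_background = 12,
      planted_reactivities = tibble::tibble(
        antigen_id = c(cyto, serp), target_group = "PNP",
        prevalence = 0, effect_multiplier = 50
      ),
      subgroup_rules = tibble::tibble(
        antigen_id = c(cyto, serp),
        subgroup = c(rep(list(is_thy), 3), rep(list(is_bo), 3)),
        prevalence = 1
      ),
      pnp_neoplasms = c(thymoma = 15),
      n_bronchiolitis_obliterans = 20,
      seed = seed
    )
  }
  recovered <- 0
  for (seed in 1:5) {
    sim <- simulate_bead_cohort(two_block_spec(seed))
    pca <- pca_profiles(sim$signal)
    top1 <- top_contributors(pca, 1, n = 3)$antigen_id
    top2 <- top_contributors(pca, 2, n = 3)$antigen_id
    lead1 <- top1[1:2]
    lead2 <- top2[1:2]
    block_of <- function(lead) {
      if (all(lead %in% cyto)) "cyto" else if (all(lead %in% serp)) "serp" else NA
    }
    ok <- all(c(top1, top2) %in% c(cyto, serp)) && # no background antigen
      !is.na(block_of(lead1)) && !is.na(block_of(lead2)) &&
      block_of(lead1) != block_of(lead2) # one block per axis
    if (ok) recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
})

test_that("thymoma patients separate on the cytokine-dominated component", {
  separated <- 0
  for (seed in 1:10) {
    sim <- simulate_bead_cohort(study_bead_spec(seed = seed))
    pnp <- sim$meta$group == "PNP"
    pca <- pca_profiles(sim$signal)
    cyto <- c("IFNA1", "IFNA2", "IFNA4", "IFNL2", "IL12", "IL22", "IL23")
    # pick the component (of the first two) with the larger cytokine share
    share <- vapply(1:2, function(k) {
      ct <- pca$contributions[[paste0("PC", k)]]
      sum(ct[pca$contributions$antigen_id %in% cyto])
    }, 0)
    pc <- paste0("PC", which.max(share))
    scores <- pca$scores[[pc]][pnp]
    thy <- sim$meta$neoplasm[pnp] == "thymoma" & !is.na(sim$meta$neoplasm[pnp])
    # silhouette of the 1-d two-cluster split along the component
    a <- scores[thy]
    b <- scores[!thy]
    sil <- mean(vapply(seq_along(a), function(i) {
      within <- mean(abs(a[i] - a[-i]))
      between <- mean(abs(a[i] - b))
      (between - within) / max(between, within)
    }, 0))
    if (sil > 0) separated <- separated + 1
  }
  expect_gte(separated, 9)
})
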