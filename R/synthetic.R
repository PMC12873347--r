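#' Specify a synthetic serological cohort
#'
#' A cohort spec fixes everything the generators need: group sizes, the
#' antigen panel size, which reactivities are planted where (antigen,
#' target group, prevalence, multiplicative effect), subgroup rules that
#' override prevalence inside a clinically defined subset (e.g. cytokine
#' autoantibodies in thymoma patients), and the log-normal background
#' noise model. Backgrounds are log-normal because serological MFI
#' distributions are right-skewed; planted positives multiply the
#' background rather than shifting it, so they stay positive on the log
#' scale used downstream.
#'
#' @param n_per_group Named integer vector of samples per disease group
#'   (names from `PNP, PV, PF, BP, EBA, Ap200P, CA, HC`).
#' @param n_antigens_background Total number of antigens; antigens beyond
#'   the planted ones are pure background named `BG_0001, ...`.
#' @param planted_reactivities Tibble with columns `antigen_id`,
#'   `target_group`, `prevalence` (in \[0, 1\]), `effect_multiplier` (> 1).
#' @param subgroup_rules Optional tibble with columns `antigen_id`,
#'   `subgroup` (list-column of predicate functions `meta -> logical`),
#'   `prevalence`, and optionally `effect_multiplier` (defaults to the
#'   planted multiplier for that antigen).
#' @param noise_meanlog,noise_sdlog Log-normal background parameters.
#' @param duplicate_cv Coefficient of variation of microarray duplicate
#'   spots around the latent signal (multiplicative log-normal; 0 gives
#'   exact duplicates).
#' @param pnp_neoplasms Named integer vector of neoplasm counts among PNP
#'   samples (levels of [as_sample_meta()]); remaining PNP samples get
#'   `unknown`.
#' @param n_bronchiolitis_obliterans Number of PNP samples flagged with
#'   bronchiolitis obliterans.
#' @param seed Integer RNG seed; identical spec + seed reproduces the
#'   cohort exactly.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group,
                        n_antigens_background,
                        planted_reactivities = NULL,
                        subgroup_rules = NULL,
                        noise_meanlog = log(100),
                        noise_sdlog = 0.5,
                        duplicate_cv = 0.1,
                        pnp_neoplasms = NULL,
                        n_bronchiolitis_obliterans = 0L,
                        seed = 1L) {
  bad <- setdiff(names(n_per_group), sample_groups())
  if (length(bad) > 0) {
    abort(sprintf("unknown group(s) in n_per_group: %s", paste(bad, collapse = ", ")),
      class = "pnpsero_spec_error")
  }
  if (any(n_per_group < 0) || n_antigens_background < 0) {
    abort("counts must be non-negative", class = "pnpsero_spec_error")
  }
  planted <- if (is.null(planted_reactivities)) {
    tibble(antigen_id = character(), target_group = character(),
      prevalence = numeric(), effect_multiplier = numeric())
  } else {
    as_tibble(planted_reactivities)
  }
  if (nrow(planted) > 0) {
    if (any(planted$prevalence < 0 | planted$prevalence > 1)) {
      abort("planted prevalences must lie in [0, 1]", class = "pnpsero_spec_error")
    }
    if (any(planted$effect_multiplier <= 1)) {
      abort("effect_multiplier must exceed 1", class = "pnpsero_spec_error")
    }
    empty <- setdiff(
      planted$target_group[planted$prevalence > 0], names(n_per_group)[n_per_group > 0])
    if (length(empty) > 0) {
      abort(
        sprintf("nonzero prevalence planted in empty group(s): %s",
          paste(unique(empty), collapse = ", ")),
        class = "pnpsero_spec_error"
      )
    }
  }
  if (duplicate_cv < 0) {
    abort("duplicate_cv must be >= 0", class = "pnpsero_spec_error")
  }
  structure(
    list(
      n_per_group = n_per_group,
      n_antigens_background = as.integer(n_antigens_background),
      planted_reactivities = planted,
      subgroup_rules = subgroup_rules,
      noise_meanlog = noise_meanlog,
      noise_sdlog = noise_sdlog,
      duplicate_cv = duplicate_cv,
      pnp_neoplasms = pnp_neoplasms,
      n_bronchiolitis_obliterans = as.integer(n_bronchiolitis_obliterans),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# build the per-sample metadata implied by a spec (deterministic given seed;
# neoplasm labels and the bronchiolitis-obliterans flag are assigned to a
# random subset of PNP samples)
build_meta <- function(spec) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  ids <- unlist(lapply(names(spec$n_per_group), function(g) {
    sprintf("%s_%03d", g, seq_len(spec$n_per_group[[g]]))
  }))
  meta <- tibble(
    sample_id = ids, group = groups,
    neoplasm = NA_character_, bronchiolitis_obliterans = NA,
    cohort = ifelse(groups %in% c("HC", "CA"), "control", "replication")
  )
  pnp <- which(meta$group == "PNP")
  if (length(pnp) > 0) {
    meta$bronchiolitis_obliterans[pnp] <- FALSE
    if (!is.null(spec$pnp_neoplasms)) {
      labels <- rep(names(spec$pnp_neoplasms), spec$pnp_neoplasms)
      if (length(labels) > length(pnp)) {
        abort("pnp_neoplasms counts exceed the PNP group size",
          class = "pnpsero_spec_error")
      }
      labels <- c(labels, rep("unknown", length(pnp) - length(labels)))
      meta$neoplasm[sample(pnp)] <- labels
    }
    nbo <- spec$n_bronchiolitis_obliterans
    if (nbo > 0) {
      if (nbo > length(pnp)) {
        abort("n_bronchiolitis_obliterans exceeds the PNP group size",
          class = "pnpsero_spec_error")
      }
      meta$bronchiolitis_obliterans[sample(pnp, nbo)] <- TRUE
    }
  }
  as_sample_meta(meta)
}

# antigen id vector: planted antigens first, background fillers after
spec_antigens <- function(spec) {
  planted <- unique(spec$planted_reactivities$antigen_id)
  n_bg <- spec$n_antigens_background - length(planted)
  if (n_bg < 0) {
    abort("n_antigens_background smaller than the number of planted antigens",
      class = "pnpsero_spec_error")
  }
  c(planted, if (n_bg > 0) sprintf("BG_%04d", seq_len(n_bg)))
}

# logical planted-positivity matrix plus the per-cell effect multiplier
plant_positives <- function(spec, meta, antigens) {
  n <- nrow(meta)
  m <- length(antigens)
  pos <- matrix(FALSE, n, m, dimnames = list(meta$sample_id, antigens))
  eff <- matrix(1, n, m, dimnames = list(meta$sample_id, antigens))
  pl <- spec$planted_reactivities
  for (i in seq_len(nrow(pl))) {
    rows <- which(meta$group == pl$target_group[i])
    if (length(rows) == 0) next
    hit <- rows[rbinom(length(rows), 1, pl$prevalence[i]) == 1]
    pos[hit, pl$antigen_id[i]] <- TRUE
    eff[hit, pl$antigen_id[i]] <- pl$effect_multiplier[i]
  }
  sr <- spec$subgroup_rules
  if (!is.null(sr)) {
    sr <- as_tibble(sr)
    for (i in seq_len(nrow(sr))) {
      in_sub <- which(sr$subgroup[[i]](meta))
      if (length(in_sub) == 0) next
      a <- sr$antigen_id[i]
      mult <- if ("effect_multiplier" %in% names(sr) && !is.na(sr$effect_multiplier[i])) {
        sr$effect_multiplier[i]
      } else {
        base <- pl$effect_multiplier[pl$antigen_id == a]
        if (length(base) == 0) {
          abort(sprintf("subgroup rule for '%s' needs an effect_multiplier", a),
            class = "pnpsero_spec_error")
        }
        base[1]
      }
      redraw <- rbinom(length(in_sub), 1, sr$prevalence[i]) == 1
      pos[in_sub, a] <- redraw
      eff[in_sub, a] <- ifelse(redraw, mult, 1)
    }
  }
  list(pos = pos, eff = eff)
}

truth_from_matrix <- function(pos) {
  idx <- which(pos, arr.ind = TRUE)
  tibble(
    sample_id = rownames(pos)[idx[, 1]],
    antigen_id = colnames(pos)[idx[, 2]]
  ) |> arrange(.data$antigen_id, .data$sample_id)
}

#' Simulate a bead-array validation cohort with planted positives
#'
#' Background MFI is drawn log-normal per cell; each planted positive
#' multiplies its background by the antigen's effect multiplier. The truth
#' table lists every planted positive cell, so recovery by
#' [compute_cutoffs()] + [call_positives()] can be scored exactly.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `signal` (a bead `sero_signal` tibble), `meta` (sample
#'   metadata), `truth` (tibble of planted `sample_id`/`antigen_id` pairs).
#' @examples
#' spec <- cohort_spec(
#'   n_per_group = c(PNP = 20, HC = 30), n_antigens_background = 3,
#'   planted_reactivities = tibble::tibble(
#'     antigen_id = "SERPINB3", target_group = "PNP",
#'     prevalence = 0.5, effect_multiplier = 50
#'   ), seed = 7
#' )
#' sim <- simulate_bead_cohort(spec)
#' nrow(sim$truth)
#' @export
simulate_bead_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  meta <- build_meta(spec)
  antigens <- spec_antigens(spec)
  n <- nrow(meta)
  m <- length(antigens)
  planted <- plant_positives(spec, meta, antigens)
  bg <- matrix(rlnorm(n * m, spec$noise_meanlog, spec$noise_sdlog), n, m,
    dimnames = list(meta$sample_id, antigens))
  values <- bg * planted$eff
  signal <- signal_tbl_from_matrix(values, assay = "bead")
  list(signal = signal, meta = meta, truth = truth_from_matrix(planted$pos))
}

signal_tbl_from_matrix <- function(values, assay) {
  df <- as_tibble(values)
  df <- dplyr::bind_cols(tibble(sample_id = rownames(values)), df)
  as_signal_matrix(df, assay = assay)
}

#' Simulate a duplicate-spot proteome microarray experiment
#'
#' Each (sample, antigen) pair gets a latent signal (log-normal background
#' times any planted effect) and exactly two replicate spot measurements,
#' perturbed multiplicatively with coefficient of variation `duplicate_cv`.
#' The mean of the perturbation is exactly 1, so `duplicate_cv = 0`
#' reproduces the latent signal in both spots.
#'
#' @param spec A [cohort_spec()].
#' @return A list: `spots` (long tibble `sample_id`, `antigen_id`,
#'   `replicate`, `signal`), `meta`, `truth`.
#' @export
simulate_microarray <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  meta <- build_meta(spec)
  antigens <- spec_antigens(spec)
  n <- nrow(meta)
  m <- length(antigens)
  planted <- plant_positives(spec, meta, antigens)
  bg <- matrix(rlnorm(n * m, spec$noise_meanlog, spec$noise_sdlog), n, m,
    dimnames = list(meta$sample_id, antigens))
  latent <- bg * planted$eff
  cv <- spec$duplicate_cv
  perturb <- function(x) {
    if (cv == 0) return(x)
    sdl <- sqrt(log(1 + cv^2))
    x * rlnorm(length(x), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  long <- tidyr::expand_grid(
    sample_id = meta$sample_id, antigen_id = antigens
  )
  lat <- as.vector(t(latent)) # row-major: sample blocks, antigens within
  spots <- bind_rows(
    mutate(long, replicate = 1L, signal = perturb(lat)),
    mutate(long, replicate = 2L, signal = perturb(lat))
  ) |> arrange(.data$sample_id, .data$antigen_id, .data$replicate)
  list(spots = spots, meta = meta, truth = truth_from_matrix(planted$pos))
}

#' Simulate a radioligand binding assay plate
#'
#' Healthy blood donors scatter around the negative-control level; cases
#' around `neg_cpm + case_effect * (pos_cpm - neg_cpm)`, so `case_effect`
#' is the target antibody index divided by 100. Control wells for the
#' positive (patient reference serum) and negative (buffer) controls are
#' included. All wells are pipetted in duplicate.
#'
#' @param n_donors,n_cases Numbers of donor and case samples.
#' @param pos_cpm,neg_cpm Positive/negative control counts per minute;
#'   `pos_cpm > neg_cpm > 0` is required.
#' @param case_effect Case position between the controls (1 = at the
#'   positive control).
#' @param cv Multiplicative noise CV on every well (0 = noise free).
#' @param seed Integer RNG seed.
#' @return An `rlba_plate` list: `wells` tibble (`sample_id`, `role`,
#'   `replicate`, `cpm`) with `pos_control`/`neg_control` ids attached.
#' @export
simulate_rlba <- function(n_donors, n_cases, pos_cpm, neg_cpm,
                          case_effect = 1, cv = 0.1, seed = 1L) {
  if (!(pos_cpm > neg_cpm && neg_cpm > 0)) {
    abort("need pos_cpm > neg_cpm > 0", class = "pnpsero_spec_error")
  }
  set.seed(as.integer(seed))
  case_level <- neg_cpm + case_effect * (pos_cpm - neg_cpm)
  ids <- c(
    sprintf("DON_%03d", seq_len(n_donors)),
    sprintf("CASE_%03d", seq_len(n_cases)),
    "POS_CTRL", "NEG_CTRL"
  )
  levels <- c(rep(neg_cpm, n_donors), rep(case_level, n_cases), pos_cpm, neg_cpm)
  roles <- c(rep("donor", n_donors), rep("case", n_cases),
    "pos_control", "neg_control")
  perturb <- function(x) {
    if (cv == 0) return(x)
    sdl <- sqrt(log(1 + cv^2))
    x * rlnorm(length(x), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  wells <- tibble(
    sample_id = rep(ids, each = 2),
    role = rep(roles, each = 2),
    replicate = rep(1:2, length(ids)),
    cpm = perturb(rep(levels, each = 2))
  )
  rlba_plate(wells, pos_control = "POS_CTRL", neg_control = "NEG_CTRL")
}

#' The default study-sized bead-array cohort specification
#'
#' Reproduces the validation-cohort structure: group sizes PNP 84, PV 19,
#' PF 20, BP 20, EBA 14, Ap200P 30, CA 38, HC 105; a 15-antigen bead panel
#' with PNP seroprevalences matching the reported validation rates
#' (SERPINB3 and A2ML1 53%, SERPINB4 40%, TGM1 17%, SFN 15%, cytokines
#' around 8–10% overall); a 4-patient thymoma subgroup carrying the
#' cytokine autoantibodies (IFNA1 at 3/4); and a 17-patient bronchiolitis
#' obliterans subgroup with SERPINB3 prevalence 14/17. PNP neoplasm counts
#' follow the reported distribution (11 follicular lymphoma, 18
#' unspecified lymphoma, 4 DLBCL, 6 Castleman, 13 solid tumors, 4 thymoma,
#' 1 leukemia, 27 unknown).
#'
#' @param seed Integer RNG seed.
#' @param effect_multiplier Multiplicative planted effect (default 50).
#' @return A [cohort_spec()].
#' @export
study_bead_spec <- function(seed = 1L, effect_multiplier = 50) {
  is_thymoma <- function(meta) {
    meta$group == "PNP" & !is.na(meta$neoplasm) & meta$neoplasm == "thymoma"
  }
  is_bo <- function(meta) {
    meta$group == "PNP" & !is.na(meta$bronchiolitis_obliterans) &
      meta$bronchiolitis_obliterans
  }
  cytokines <- c("IFNA1", "IFNA2", "IFNA4", "IFNL2", "IL12", "IL22", "IL23")
  planted <- tibble(
    antigen_id = c("SERPINB3", "SERPINB4", "A2ML1", "SFN", "TGM1",
      "PKP1", "PADI3", "ADH7", cytokines),
    target_group = "PNP",
    prevalence = c(0.455, 0.40, 0.53, 0.15, 0.17,
      0.10, 0.02, 0.02, rep(0.05, 3), 0.04, rep(0.04, 3)),
    effect_multiplier = effect_multiplier
  )
  rules <- tibble(
    antigen_id = c("SERPINB3", cytokines),
    subgroup = c(list(is_bo), rep(list(is_thymoma), length(cytokines))),
    prevalence = c(14 / 17, 0.75, 0.75, 0.75, 0.5, 0.75, 0.75, 0.75)
  )
  cohort_spec(
    n_per_group = c(PNP = 84, PV = 19, PF = 20, BP = 20, EBA = 14,
      Ap200P = 30, CA = 38, HC = 105),
    n_antigens_background = 15,
    planted_reactivities = planted,
    subgroup_rules = rules,
    noise_meanlog = log(100), noise_sdlog = 0.5,
    pnp_neoplasms = c(
      lymphoma_follicular = 11, lymphoma_unspecified = 18, lymphoma_DLBCL = 4,
      lymphoma_castleman = 6, solid_tumor = 13, thymoma = 4, leukemia = 1
    ),
    n_bronchiolitis_obliterans = 17,
    seed = seed
  )
}

#' Antigen metadata for the default bead panel
#'
#' Family tags drive the panel-search cross-reactivity constraint: the
#' three interferon-alpha antigens form the `type_I_IFN` family and IFNL2
#' the `IFNL` family, at most one of each per panel.
#'
#' @return An antigen metadata tibble (see [as_antigen_meta()]).
#' @export
study_antigen_meta <- function() {
  as_antigen_meta(tibble(
    antigen_id = c("SERPINB3", "SERPINB4", "A2ML1", "SFN", "TGM1",
      "PKP1", "PADI3", "ADH7", "IFNA1", "IFNA2", "IFNA4",
      "IFNL2", "IL12", "IL22", "IL23"),
    family = c(rep("none", 8), rep("type_I_IFN", 3), "IFNL", rep("none", 3)),
    is_cytokine = c(rep(FALSE, 8), rep(TRUE, 7))
  ))
}

#' Expected per-group prevalence implied by a cohort spec
#'
#' Mixes the base planted prevalence with any subgroup overrides using the
#' realized subgroup sizes in `meta`, giving the nominal positivity rate
#' the generator targets for each planted antigen in each group.
#'
#' @param spec A [cohort_spec()].
#' @param meta The metadata returned by the simulation.
#' @return Tibble `antigen_id`, `group`, `expected_prevalence`, `n`.
#' @export
expected_prevalence <- function(spec, meta) {
  pl <- spec$planted_reactivities
  out <- purrr::pmap_dfr(pl, function(antigen_id, target_group, prevalence, ...) {
    rows <- meta$group == target_group
    n <- sum(rows)
    p <- prevalence
    sr <- spec$subgroup_rules
    if (!is.null(sr)) {
      sr <- as_tibble(sr)
      for (i in which(sr$antigen_id == antigen_id)) {
        sub <- sr$subgroup[[i]](meta) & rows
        ns <- sum(sub)
        if (n > 0) p <- (p * (n - ns) + sr$prevalence[i] * ns) / n
      }
    }
    tibble(antigen_id = antigen_id, group = target_group,
      expected_prevalence = p, n = n)
  })
  out
}
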