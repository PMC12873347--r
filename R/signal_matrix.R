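#' Construct and validate a wide serological signal matrix
#'
#' A signal matrix is a wide tibble: one row per sample, a `sample_id`
#' column followed by one numeric column per antigen. Values are raw
#' non-negative intensities — microarray fluorescence, bead-array median
#' fluorescence intensity (MFI), or radioligand counts per minute —
#' depending on `assay`. Missing cells are rejected at ingestion: the
#' downstream statistics (means, cutoffs, ranks) assume a complete matrix
#' and no imputation step is defined for these assays.
#'
#' @param x A data frame with a `sample_id` column (or sample ids in the
#'   first column, any name) and numeric antigen columns.
#' @param assay One of `"microarray"`, `"bead"`, `"rlba"`.
#' @return A validated `sero_signal` tibble with an `assay` attribute.
#' @examples
#' as_signal_matrix(
#'   data.frame(sample_id = c("s1", "s2"), SERPINB3 = c(100, 5200)),
#'   assay = "bead"
#' )
#' @export
as_signal_matrix <- function(x, assay = c("microarray", "bead", "rlba")) {
  assay <- match.arg(assay)
  x <- as_tibble(x, .name_repair = "minimal")
  if (ncol(x) < 2) {
    abort("a signal matrix needs a sample id column and at least one antigen column",
      class = "pnpsero_format_error"
    )
  }
  if (!"sample_id" %in% names(x)) names(x)[1] <- "sample_id"
  x <- dplyr::relocate(x, "sample_id")
  x$sample_id <- as.character(x$sample_id)

  if (anyDuplicated(x$sample_id)) {
    dup <- unique(x$sample_id[duplicated(x$sample_id)])
    abort(sprintf("duplicate sample ids: %s", paste(dup, collapse = ", ")),
      class = "pnpsero_format_error"
    )
  }
  ag <- names(x)[-1] # not antigen_cols(): setdiff would mask duplicates
  if (anyDuplicated(ag)) {
    dup <- unique(ag[duplicated(ag)])
    abort(sprintf("duplicate antigen columns: %s", paste(dup, collapse = ", ")),
      class = "pnpsero_format_error"
    )
  }
  for (a in ag) {
    v <- x[[a]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      abort(
        sprintf("non-numeric signal at sample '%s', antigen '%s'",
          x$sample_id[bad %||% 1L], a),
        class = "pnpsero_value_error"
      )
    }
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      abort(
        sprintf("missing signal at sample '%s', antigen '%s'", x$sample_id[bad], a),
        class = "pnpsero_value_error"
      )
    }
    if (any(v < 0)) {
      bad <- which(v < 0)[1]
      abort(
        sprintf("negative signal %s at sample '%s', antigen '%s'",
          format(v[bad]), x$sample_id[bad], a),
        class = "pnpsero_value_error"
      )
    }
  }
  attr(x, "assay") <- assay
  class(x) <- c("sero_signal", class(x))
  x
}

#' Read a wide signal table from delimited text
#'
#' Reads a TSV (default) or CSV wide table whose first column holds sample
#' ids and whose remaining columns hold per-antigen signals, then validates
#' it with [as_signal_matrix()]. Raw scanner formats (e.g. GPR image grids)
#' are deliberately not parsed: all statistics start from per-protein
#' signal summaries.
#'
#' @param path Path to the delimited file.
#' @param assay Assay tag, see [as_signal_matrix()].
#' @param delim Field delimiter; `NULL` infers `","` for `.csv`, tab
#'   otherwise.
#' @return A `sero_signal` tibble; row and column order as in the file.
#' @export
read_signal_matrix <- function(path, assay = c("microarray", "bead", "rlba"),
                               delim = NULL) {
  assay <- match.arg(assay)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
    name_repair = "minimal")
  as_signal_matrix(raw, assay = assay)
}

#' Write a signal matrix to delimited text
#'
#' @param x A `sero_signal` tibble.
#' @param path Output path.
#' @param delim Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path, delim = "\t") {
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' @export
print.sero_signal <- function(x, ...) {
  cat(sprintf("# Signal matrix (%s): %d samples x %d antigens\n",
    attr(x, "assay", exact = TRUE) %||% "?", nrow(x), length(antigen_cols(x))))
  NextMethod()
}

sample_groups <- function() c("PNP", "PV", "PF", "BP", "EBA", "Ap200P", "CA", "HC")

neoplasm_levels <- function() {
  c("lymphoma_follicular", "lymphoma_DLBCL", "lymphoma_castleman",
    "lymphoma_unspecified", "solid_tumor", "thymoma", "leukemia", "unknown")
}

#' Validate a sample metadata table
#'
#' Metadata carries one row per sample: the disease `group` (PNP cases,
#' the non-paraneoplastic blistering diseases PV/PF/BP/EBA/Ap200P, cancer
#' controls CA, healthy controls HC), the underlying `neoplasm` category
#' for PNP cases, a `bronchiolitis_obliterans` flag, and the `cohort` role
#' (discovery / replication / control). Neoplasm annotations on non-PNP
#' samples are rejected: only the case group carries a tumor diagnosis.
#'
#' @param x A data frame with columns `sample_id`, `group`, and optionally
#'   `neoplasm`, `bronchiolitis_obliterans`, `cohort`.
#' @return A validated tibble.
#' @export
as_sample_meta <- function(x) {
  x <- as_tibble(x)
  req <- c("sample_id", "group")
  if (!all(req %in% names(x))) {
    abort(sprintf("metadata needs columns: %s", paste(req, collapse = ", ")),
      class = "pnpsero_format_error")
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    abort("duplicate sample ids in metadata", class = "pnpsero_format_error")
  }
  bad <- setdiff(unique(x$group), sample_groups())
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
      class = "pnpsero_value_error")
  }
  if (!"neoplasm" %in% names(x)) x$neoplasm <- NA_character_
  if (!"bronchiolitis_obliterans" %in% names(x)) x$bronchiolitis_obliterans <- NA
  if (!"cohort" %in% names(x)) x$cohort <- NA_character_
  x$bronchiolitis_obliterans <- as.logical(x$bronchiolitis_obliterans)
  badneo <- !is.na(x$neoplasm) & x$group != "PNP"
  if (any(badneo)) {
    abort(
      sprintf("neoplasm annotation on non-PNP sample(s): %s",
        paste(x$sample_id[badneo], collapse = ", ")),
      class = "pnpsero_value_error"
    )
  }
  badlev <- setdiff(unique(x$neoplasm[!is.na(x$neoplasm)]), neoplasm_levels())
  if (length(badlev) > 0) {
    abort(sprintf("unknown neoplasm label(s): %s", paste(badlev, collapse = ", ")),
      class = "pnpsero_value_error")
  }
  x
}

#' Validate an antigen metadata table
#'
#' Antigen metadata tags each antigen with a cross-reactivity `family`
#' (`type_I_IFN` for the interferon-alpha antigens, `IFNL` for lambda
#' interferons, `none` otherwise) and an `is_cytokine` flag. The family
#' tags drive the panel-search constraint that at most one antigen per
#' cross-reactive family may enter a panel.
#'
#' @param x A data frame with columns `antigen_id`, `family`, `is_cytokine`.
#' @return A validated tibble.
#' @export
as_antigen_meta <- function(x) {
  x <- as_tibble(x)
  req <- c("antigen_id", "family", "is_cytokine")
  if (!all(req %in% names(x))) {
    abort(sprintf("antigen metadata needs columns: %s", paste(req, collapse = ", ")),
      class = "pnpsero_format_error")
  }
  bad <- setdiff(unique(x$family), c("type_I_IFN", "IFNL", "none"))
  if (length(bad) > 0) {
    abort(sprintf("unknown family label(s): %s", paste(bad, collapse = ", ")),
      class = "pnpsero_value_error")
  }
  x$is_cytokine <- as.logical(x$is_cytokine)
  if (any(x$family == "type_I_IFN" & !x$is_cytokine)) {
    abort("type_I_IFN antigens must be flagged is_cytokine",
      class = "pnpsero_value_error")
  }
  x
}

#' Join a signal matrix with sample metadata into an annotated cohort
#'
#' Every sample in the matrix must have exactly one metadata row; metadata
#' rows for samples absent from the matrix are dropped with a warning.
#' The cohort exposes per-group sample index sets through [group_ids()].
#'
#' @param matrix A `sero_signal` tibble.
#' @param meta A sample metadata table (see [as_sample_meta()]).
#' @return A `sero_cohort` list with elements `signal` and `meta`.
#' @export
join_metadata <- function(matrix, meta) {
  meta <- as_sample_meta(meta)
  missing <- setdiff(matrix$sample_id, meta$sample_id)
  if (length(missing) > 0) {
    abort(
      sprintf("no metadata for sample(s): %s", paste(missing, collapse = ", ")),
      class = "pnpsero_join_error"
    )
  }
  extra <- setdiff(meta$sample_id, matrix$sample_id)
  if (length(extra) > 0) {
    warn(sprintf("dropping %d metadata row(s) not in the signal matrix: %s",
      length(extra), paste(extra, collapse = ", ")))
    meta <- meta[meta$sample_id %in% matrix$sample_id, ]
  }
  meta <- meta[match(matrix$sample_id, meta$sample_id), ]
  structure(list(signal = matrix, meta = meta), class = "sero_cohort")
}

#' Per-group sample id sets of a cohort
#'
#' @param cohort A `sero_cohort` from [join_metadata()].
#' @param group Optional group label; if given, returns that group's ids as
#'   a character vector, otherwise a named list over all groups present.
#' @return A character vector or named list of character vectors. The sets
#'   partition the cohort's samples.
#' @export
group_ids <- function(cohort, group = NULL) {
  stopifnot(inherits(cohort, "sero_cohort"))
  sets <- split(cohort$meta$sample_id, cohort$meta$group)
  if (is.null(group)) sets else sets[[group]] %||% character(0)
}

#' @export
print.sero_cohort <- function(x, ...) {
  cat(sprintf("# Annotated cohort: %d samples, %d antigens (%s assay)\n",
    nrow(x$signal), length(antigen_cols(x$signal)),
    attr(x$signal, "assay", exact = TRUE) %||% "?"))
  tab <- table(x$meta$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration with study defaults
#'
#' Central container for the tunable thresholds. Defaults are the study
#' rules: hits at |log2 fold change| >= 2.5 in the microarray screen; bead
#' positivity above max(healthy-control mean + 5 SD, 500 MFI); neoplasm
#' proportion tables thresholded at fluorescence > 1000; RLBA positivity
#' above donor mean + 3 SD; panel search restricted to antigens with
#' rank-based AUC > 0.50, panels up to 15 antigens.
#'
#' @param log2fc_threshold Microarray hit threshold on |log2 FC|.
#' @param cutoff_sd_multiplier Bead cutoff SD multiplier.
#' @param cutoff_floor_mfi Bead cutoff floor in MFI units.
#' @param heatmap_positivity_threshold Fluorescence threshold for the
#'   neoplasm proportion table.
#' @param rlba_sd_multiplier RLBA donor-cutoff SD multiplier.
#' @param auc_prefilter Minimum per-antigen AUC to enter the panel search.
#' @param max_panel_size Largest panel size enumerated.
#' @param cutoff_rule `"max"` (floor; default) or `"min"` for combining the
#'   mean + k SD rule with the MFI floor.
#' @param rng_seed Integer seed for any stage that randomizes.
#' @return A `pnpsero_config` list.
#' @export
pipeline_config <- function(log2fc_threshold = 2.5,
                            cutoff_sd_multiplier = 5,
                            cutoff_floor_mfi = 500,
                            heatmap_positivity_threshold = 1000,
                            rlba_sd_multiplier = 3,
                            auc_prefilter = 0.50,
                            max_panel_size = 15,
                            cutoff_rule = c("max", "min"),
                            rng_seed = 1L) {
  cutoff_rule <- match.arg(cutoff_rule)
  cfg <- list(
    log2fc_threshold = log2fc_threshold,
    cutoff_sd_multiplier = cutoff_sd_multiplier,
    cutoff_floor_mfi = cutoff_floor_mfi,
    heatmap_positivity_threshold = heatmap_positivity_threshold,
    rlba_sd_multiplier = rlba_sd_multiplier,
    auc_prefilter = auc_prefilter,
    max_panel_size = as.integer(max_panel_size),
    cutoff_rule = cutoff_rule,
    rng_seed = as.integer(rng_seed)
  )
  thr <- c(cfg$log2fc_threshold, cfg$cutoff_sd_multiplier, cfg$cutoff_floor_mfi,
    cfg$heatmap_positivity_threshold, cfg$rlba_sd_multiplier)
  if (any(thr <= 0) || cfg$max_panel_size < 1) {
    abort("all thresholds must be strictly positive and max_panel_size >= 1",
      class = "pnpsero_value_error")
  }
  structure(cfg, class = "pnpsero_config")
}
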