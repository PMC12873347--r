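#' Construct a radioligand binding assay plate
#'
#' Wraps well-level counts per minute (cpm) with the designated control
#' samples. The positive control is a reference patient serum, the
#' negative control a buffer-only well; the positive control must read
#' higher than the negative on average.
#'
#' @param wells Tibble with columns `sample_id`, `cpm` (and any others,
#'   e.g. `replicate`, `role`); samples may have any number of wells.
#' @param pos_control,neg_control Sample ids of the control sera.
#' @return An `rlba_plate` list with elements `wells`, `pos_control`,
#'   `neg_control`.
#' @export
rlba_plate <- function(wells, pos_control, neg_control) {
  wells <- as_tibble(wells)
  req <- c("sample_id", "cpm")
  if (!all(req %in% names(wells))) {
    abort(sprintf("well table needs columns: %s", paste(req, collapse = ", ")),
      class = "pnpsero_format_error")
  }
  if (any(wells$cpm < 0)) {
    abort("cpm must be non-negative", class = "pnpsero_value_error")
  }
  for (ctl in c(pos_control, neg_control)) {
    if (!ctl %in% wells$sample_id) {
      abort(sprintf("control sample '%s' has no wells", ctl),
        class = "pnpsero_format_error")
    }
  }
  pos_mean <- mean(wells$cpm[wells$sample_id == pos_control])
  neg_mean <- mean(wells$cpm[wells$sample_id == neg_control])
  if (!(pos_mean > neg_mean)) {
    abort("positive-control mean cpm must exceed the negative-control mean",
      class = "pnpsero_degenerate_assay_error")
  }
  structure(
    list(wells = wells, pos_control = pos_control, neg_control = neg_control),
    class = "rlba_plate"
  )
}

#' @export
print.rlba_plate <- function(x, ...) {
  cat(sprintf("# RLBA plate: %d wells, %d samples (pos ctrl '%s', neg ctrl '%s')\n",
    nrow(x$wells), length(unique(x$wells$sample_id)), x$pos_control, x$neg_control))
  invisible(x)
}

#' Antibody index of one sample on an RLBA plate
#'
#' Index = ((mean sample cpm - mean negative-control cpm) /
#' (mean positive-control cpm - mean negative-control cpm)) x 100.
#' Duplicate wells are averaged before the ratio. The index is not
#' clipped: it can fall below 0 or exceed 100.
#'
#' @param plate An [rlba_plate()].
#' @param sample_id Sample with at least one well on the plate.
#' @return The antibody index (real).
#' @examples
#' wells <- tibble::tibble(
#'   sample_id = c("NEG", "NEG", "POS", "POS", "p1", "p1"),
#'   cpm = c(200, 200, 1200, 1200, 700, 700)
#' )
#' plate <- rlba_plate(wells, pos_control = "POS", neg_control = "NEG")
#' antibody_index(plate, "p1") # 50
#' @export
antibody_index <- function(plate, sample_id) {
  stopifnot(inherits(plate, "rlba_plate"))
  rows <- plate$wells$sample_id == sample_id
  if (!any(rows)) {
    abort(sprintf("sample '%s' has no wells", sample_id),
      class = "pnpsero_argument_error")
  }
  s <- mean(plate$wells$cpm[rows])
  pos <- mean(plate$wells$cpm[plate$wells$sample_id == plate$pos_control])
  neg <- mean(plate$wells$cpm[plate$wells$sample_id == plate$neg_control])
  if (pos == neg) {
    abort("degenerate assay: positive and negative control means are equal",
      class = "pnpsero_degenerate_assay_error")
  }
  (s - neg) / (pos - neg) * 100
}

#' Antibody indices for every sample on a plate
#'
#' @param plate An [rlba_plate()].
#' @param include_controls Keep the control samples in the output?
#' @return Tibble `sample_id`, `n_wells`, `index` (plus `role` if present
#'   in the wells).
#' @export
rlba_indices <- function(plate, include_controls = FALSE) {
  ids <- unique(plate$wells$sample_id)
  if (!include_controls) {
    ids <- setdiff(ids, c(plate$pos_control, plate$neg_control))
  }
  out <- purrr::map_dfr(ids, function(id) {
    rows <- plate$wells$sample_id == id
    tibble(
      sample_id = id,
      n_wells = sum(rows),
      index = antibody_index(plate, id)
    )
  })
  if ("role" %in% names(plate$wells)) {
    roles <- dplyr::distinct(plate$wells, .data$sample_id, .data$role)
    out <- left_join(out, roles, by = "sample_id")
  }
  out
}

#' RLBA positivity cutoff from blood-donor indices
#'
#' Cutoff = donor mean + `multiplier` sample standard deviations (3 by
#' convention); a sample is positive when its index strictly exceeds the
#' cutoff.
#'
#' @param donor_indices Antibody indices of at least 2 blood donors.
#' @param multiplier SD multiplier (default 3).
#' @return The cutoff (real).
#' @export
rlba_cutoff <- function(donor_indices, multiplier = 3) {
  if (length(donor_indices) < 2) {
    abort("need at least 2 donors to estimate the cutoff",
      class = "pnpsero_estimation_error")
  }
  mean(donor_indices) + multiplier * sd(donor_indices)
}
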