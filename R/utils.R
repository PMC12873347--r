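# internal helpers shared across stages

# Round half away from zero: printed percentages are reported this way, and
# base round() (banker's rounding) would turn 0.5 into 0.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# signal tibbles are wide: first column sample_id, remaining columns antigens
antigen_cols <- function(x) setdiff(names(x), "sample_id")

# extract the numeric value block as a base matrix with sample_id rownames
signal_values <- function(x) {
  m <- as.matrix(x[antigen_cols(x)])
  rownames(m) <- x$sample_id
  m
}

# rebuild a signal tibble from a values matrix, preserving the assay attr
signal_from_values <- function(m, template) {
  out <- tibble::as_tibble(m)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)), out)
  attr(out, "assay") <- attr(template, "assay", exact = TRUE)
  class(out) <- class(template)
  out
}

assert_disjoint <- function(a, b, what = c("case", "control")) {
  overlap <- intersect(a, b)
  if (length(overlap) > 0) {
    abort(
      sprintf(
        "%s and %s sets overlap: %s", what[1], what[2],
        paste(overlap, collapse = ", ")
      ),
      class = "pnpsero_argument_error"
    )
  }
  invisible(TRUE)
}

assert_samples_present <- function(x, ids, what = "sample") {
  missing <- setdiff(ids, x$sample_id)
  if (length(missing) > 0) {
    abort(
      sprintf("%s ids not in signal matrix: %s", what, paste(missing, collapse = ", ")),
      class = "pnpsero_argument_error"
    )
  }
  invisible(TRUE)
}
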