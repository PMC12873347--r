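Package: pnpsero
Title: Autoantibody Repertoire Profiling for Paraneoplastic Pemphigus Serology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for serological discovery and validation of
    autoantibodies in paraneoplastic pemphigus and related autoimmune
    blistering diseases. Covers proteome-array discovery (duplicate-spot
    collapsing, quantile normalization, case-control fold-change ranking,
    leave-k-out shared-reactivity repertoire estimation), multiplex
    bead-array validation (healthy-control derived positivity cutoffs,
    seroprevalence, false-discovery summaries), exhaustive union-rule
    diagnostic panel optimization under cross-reactivity constraints,
    radioligand binding assay antibody indexing, and clinical association
    profiling (Fisher's exact tests, neoplasm-stratified proportion tables,
    principal component analysis of serological profiles). Includes a
    synthetic cohort generator with planted disease structure so every
    pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
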