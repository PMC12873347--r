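---
title: "Serological discovery and validation statistics in pnpsero"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serological discovery and validation statistics in pnpsero}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpsero)
```

`pnpsero` implements the statistics of a two-phase autoantibody study in
paraneoplastic pemphigus (PNP): proteome-array discovery, bead-array
validation, diagnostic-panel optimization, radioligand confirmation, and
clinical-association profiling. This vignette documents the models and
procedures, the parameters that matter, the synthetic-data generator that
stands in for patient cohorts, and the numerical and design choices made
where the method descriptions left room.

## Discovery phase: proteome-array enrichment

The discovery input is a duplicate-spot long table (sample, antigen,
replicate, fluorescence signal). Three steps turn it into a repertoire
estimate.

**Duplicate collapsing.** Proteins are printed twice per array; the
per-sample signal is defined as the maximum of the two spots. The maximum
(rather than the mean) is robust to a single failed spot, at the cost of a
small upward bias that is shared by cases and controls and cancels in the
fold-change ratio. Pairs with any replicate count other than two are a
structural error, not silently tolerated: a missing or triplicated spot
indicates a malformed export.

**Quantile normalization.** Arrays differ in overall brightness; quantile
normalization forces every sample's value distribution onto the
cross-sample rank-mean reference (the mean of the per-sample sorted
vectors), preserving within-sample ranks. Ties receive the mean of the
reference values across their rank span — the standard rank-mean dialect.
The operation is idempotent up to tie averaging and is applied *after*
duplicate collapsing, because the downstream enrichment statistics are
defined on the per-sample (collapsed) signals. A single-sample matrix is
returned unchanged with a warning, as no reference exists.

One behavior of joint quantile normalization deserves emphasis because it
shapes every calibration below: when a minority of samples (the cases)
carry strong reactivities, the reference tail averages those values with
the controls' background tail. Case-exclusive signals are thereby
*compressed* — roughly by the case fraction of the cohort — and the top
background ranks of every control sample are *inflated* by a factor that
grows with the ratio of reactivities to array size. Both effects are
intrinsic to the method, not artifacts of this implementation; they mean
that modest planted effects (20–30-fold) sitting just above the enrichment
threshold before normalization can land just below it afterwards.

**Fold-change ranking and repertoires.** Per antigen,

$$\log_2 \mathrm{FC} = \log_2 \frac{\mu_{\text{cases}} + \varepsilon}{\mu_{\text{controls}} + \varepsilon},$$

with arithmetic means and a pseudo-intensity $\varepsilon$ (default 1
fluorescence unit) guarding against zero means; the method description is
silent on zero handling and background-subtracted exports can contain
zeros. Antigens are ranked by descending log2 FC, ties broken by antigen
id so the ranking is a deterministic permutation. The repertoire at a
threshold (default 2.5, i.e. five- to six-fold) counts antigens with
$|\log_2 \mathrm{FC}|$ at or above it, annotated by direction;
case-enriched and control-enriched hits are reported separately because
the two readings of an "absolute fold-change" count (pooled vs
case-enriched only) differ, and both are legitimate summaries.

**Leave-k-out shared reactivities.** A private reactivity — one extreme
patient — can carry an antigen over the threshold. For each antigen the k
case samples with the strongest signal *for that antigen* are excluded
before recomputing the case mean; a surviving hit is shared by at least
k + 1 patients. The excluded sample is read as the strongest *case*
sample per protein: the purpose of the analysis is to discount private
reactivities within the enriched group, and removing control samples
would do the opposite. Only the positive (case-enriched) direction is
meaningful here. Hit counts are provably non-increasing in k, which the
test suite asserts as a property.

Healthy-donor arrays from earlier experiments enter as ordinary control
columns after joint quantile normalization; no batch correction is
applied because none is described for the assay, and the equal-sized
healthy-control internal comparison is implemented as a seeded random
halving of the control set.

## Validation phase: bead-array positivity

Per antigen, the positivity cutoff is

$$\mathrm{cutoff}_a = \max(\bar{x}_{\mathrm{HC},a} + 5\, s_{\mathrm{HC},a},\ 500\ \mathrm{MFI}),$$

with the sample SD (n − 1). The "either … or at least 500 units" rule is
read as a floor (`max`): it makes weak-signal antigens conservative and is
consistent with validation specificities near 100%. The alternative `min`
reading is available as `rule = "min"` in `compute_cutoffs()`. Positivity
is *strictly* above the cutoff; ties are negative — the conservative
choice where the rule's boundary behavior is unstated. At least two
healthy controls are required; fewer is an estimation error.

Seroprevalence percentages are rounded half away from zero, matching
printed integer prevalences (13/14 → 93%, 14/17 → 82%, 3/4 → 75%). The
false-discovery summary of an antigen is FP / (FP + TP), with TP the case
positives and FP the positives among *all* non-case groups (other
blistering diseases, cancer, healthy controls), since specificity is
validated against all of them; because "0% false discovery" is sometimes
read simply as zero control positives, the raw FP count is returned
alongside. A table with no positives at all has FDR 0 by convention.

## Diagnostic panel search

Antigens are screened by the rank-based two-class AUC (the Mann–Whitney
identity, ties counting one half); only antigens with AUC strictly above
0.50 enter the search. Every subset of the retained antigens from size 1
to `max_panel_size` (default 15) is evaluated as a union rule: a sample is
panel-positive if positive for at least one panel antigen. Cross-reactive
families are constrained to at most one member per panel (the three
interferon-alpha antigens form one family, the lambda interferon another);
the constraint is enforced during enumeration rather than by post-hoc
filtering — the result set is identical and the enumeration cheaper.

For a binary union classifier the ROC has a single interior point, and its
trapezoidal area equals the balanced accuracy
$(\text{sensitivity} + \text{specificity})/2$; that is the panel "AUC"
used for ranking. Ties are broken toward smaller panels (parsimony —
added antigens beyond a point contribute no sensitivity), then
lexicographically so the ranking is total and reproducible.

Internally each sample's positivity pattern is encoded as a bitmask and
all panels are scored with one pattern-by-mask product, so the full
32,767-panel space of 15 antigens evaluates in well under a second. A
guard (default 25 retained antigens) refuses clearly oversized searches
and points at the prefilter. An independent loop-based brute-force
evaluator in the test suite confirms the bitmask path on every instance
up to 10 antigens.

## Radioligand binding assay

The antibody index is
$((\bar{c}_{\text{sample}} - \bar{c}_{\text{neg}}) / (\bar{c}_{\text{pos}} - \bar{c}_{\text{neg}})) \times 100$
on well means (duplicate wells are averaged first, as the formula is
defined on mean cpm). Indices are not clipped: values below 0 or above
100 are informative. Equal control means are a degenerate-assay error.
Positivity is an index strictly above the blood-donor mean + 3 SD. The
index is invariant to shifting and rescaling all cpm jointly, which the
suite asserts as a property.

## Clinical associations and profile structure

Fisher's exact test (two-sided, summing hypergeometric probabilities no
larger than the observed table's, delegated to `stats::fisher.test` and
cross-checked against a from-scratch enumeration oracle in the tests)
relates antigen positivity to clinical features. The built-in features —
bronchiolitis obliterans, thymoma, follicular lymphoma — are evaluated
over PNP cases only, matching the stratified questions they answer;
samples with undefined features are excluded and counted in a message. A
zero-margin table carries no information and returns p = 1 with a
degenerate flag. Raw p-values are the headline numbers (no correction is
applied in the source analyses); a Benjamini–Hochberg column is emitted by
`association_grid()` for transparency.

The neoplasm proportion table reports, per neoplasm category with at
least two patients, the fraction of patients with signal above 1000
fluorescence units per antigen.

PCA uses `stats::prcomp` on log10(signal + 1), centered and unit-scaled
per antigen: intensities span orders of magnitude and without the log a
handful of extreme titers dominates every component; the transform is not
stated in the source analyses, so a `raw_centered` alternative is exposed.
Antigens that are constant after transformation are left unscaled (they
carry no information either way). Per-component squared-loading shares
identify top contributors. A constant matrix degenerates to zero variance
explained with a warning rather than an error.

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
ground truth; it emulates the *structure* of the study data, not its
microscopic detail.

Background signals are log-normal (`meanlog = log(100)`, `sdlog = 0.5` by
default) — serological MFI distributions are right-skewed and strictly
positive. Planted positives multiply the background by an effect factor
(default 50 in the study-sized spec), keeping positives positive on the
log scale used for PCA. Microarray duplicate spots perturb the latent
signal multiplicatively with an exact-mean log-normal at coefficient of
variation `duplicate_cv` (default 0.1), so `duplicate_cv = 0` reproduces
the latent signal exactly. All generators are deterministic given the
spec and seed.

`study_bead_spec()` is the study-sized default: group sizes
84/19/20/20/14/30/38/105, a 15-antigen panel, planted PNP prevalences at
the validated rates (SERPINB3 and A2ML1 53%, SERPINB4 40%, TGM1 17%, SFN
15%, cytokines around 8–10% overall), a 4-patient thymoma subgroup
carrying the cytokine autoantibodies (the alpha interferons, IFNL2, and
interleukins 12/22/23; IFNA1 at 3/4), a 17-patient bronchiolitis
obliterans subgroup with SERPINB3 at 14/17, and the reported neoplasm
distribution. The three rates not individually reported (PKP1, PADI3,
ADH7) are set once to 10%, 2% and 2% — modest values consistent with
their description as infrequent. SERPINB3's base rate outside the
bronchiolitis subgroup is 45.5%, so the subgroup rule mixes back to 53%
overall. No distributional parameters for raw signals are published;
the noise defaults are calibration choices, not estimates from deposited
data.

What the generator does *not* model: spatial array artifacts, plate and
batch effects beyond duplicate CV, antigen cross-correlation outside the
planted subgroup structure, and the correlation between real
autoantibody titers across antigens in the same patient (planting is
independent per antigen given the subgroup). Passing calibrations
therefore demonstrate that the statistics recover structure *of this
kind*; they do not certify performance on real cohorts, where positives
co-occur more strongly and the union-panel sensitivity is accordingly
lower than independent planting produces.

## Calibration conditions and problem sizes

The test suite runs fixed-seed calibrations at sizes chosen to finish in
minutes on one CPU:

- Bead recovery: the study-sized cohort (330 samples × 15 antigens),
  20 seeds for the parameter-recovery checks and 5 for the module tests.
  With 50-fold effects over `sdlog = 0.5` background and the 5-SD/500-MFI
  cutoff, planted positives are recovered at ≥ 95% sensitivity with ≤ 1%
  healthy-control false positives, and per-antigen recovered prevalences
  sit within three binomial SDs of the planted rates.
- Discovery screen: 32 samples × ~2,000 antigens with 21 planted shared
  reactivities, 6 seeds. The planted effects are 100-fold at 80%
  prevalence — the regime of genuine, saturating autoantibody
  reactivities shared by most cases. This is deliberate: as described
  above, joint quantile normalization compresses case-exclusive signals
  by roughly the case fraction, so borderline 20–30-fold effects with
  low shared prevalence are *not* reliably recovered at the 2.5
  threshold, and the k = 1 repertoire is honest about classifying
  reactivities carried by two or three patients as weakly shared. At
  full array scale the control-tail inflation term additionally shrinks
  with (reactivities)/(array size).
- Fisher oracle equivalence: every 2×2 table with total n ≤ 40, reduced
  by the row-swap/column-swap/transpose symmetries under which the
  conditional p-value is invariant (the invariance itself is asserted on
  a sample), about 18,700 tables.
- Panel search: full 15-antigen enumeration (32,767 panels) plus
  loop-based brute-force agreement on 8- and 10-antigen instances.

## Known limitations

- The pooling of samples assayed in both discovery and replication is
  recorded in the metadata (`cohort` column) but not automatically
  de-duplicated; each analysis takes explicit id sets, so the caller
  decides.
- The leave-k-out repertoire uses mean-based enrichment after exclusion;
  reactivities shared by exactly k + 1 patients near the threshold are
  classified conservatively (see the compression discussion above).
- Panel operating characteristics are in-sample: no cross-validation or
  optimism correction is performed, matching the source design. Treat
  the reported sensitivity/specificity as descriptive, not predictive.
- The family constraint handles cross-reactivity by exclusion (at most
  one member); it does not model partial cross-reactivity strengths.
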