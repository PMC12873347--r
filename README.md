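# pnpsero

Statistics for discovering and validating autoantibodies in paraneoplastic
pemphigus (PNP), a severe cancer-associated autoimmune blistering disease.
Serological studies of PNP follow a two-step design: a proteome-wide
**discovery screen** on protein microarrays (thousands of full-length human
proteins, duplicate spots) in a small case–control set, followed by
**validation** of candidate autoantigens on a multiplex bead array (median
fluorescence intensity, MFI) in an extended cohort of blistering-disease,
cancer, and healthy-control groups. `pnpsero` implements the statistics of
both phases as composable, tibble-in/tibble-out functions, plus the
downstream panel optimization, radioligand confirmation, and
clinical-association profiling — and ships a synthetic cohort generator
with planted ground truth so the whole pipeline is testable end to end.

## The statistics at its core

**Discovery screen.** Duplicate spots are collapsed per protein as
`Signal_sample = max(duplicate 1, duplicate 2)`, arrays are quantile
normalized, and each protein is scored by case–control enrichment

```
log2 FC = log2( mu_cases / mu_controls )
```

with `mu` the arithmetic mean of the per-sample signals. Proteins with
`|log2 FC| >= 2.5` (five- to six-fold enrichment) count toward the
repertoire. Because a single extreme patient can push a protein over the
threshold, *shared* reactivities are estimated by a leave-k-out analysis:
for each protein, the k case samples with the strongest signal are dropped
before recomputing the enrichment, so surviving hits are carried by at
least k + 1 patients.

**Validation.** A sample is seropositive for an antigen when its MFI
strictly exceeds `max(mean_HC + 5·SD_HC, 500)`, the healthy-control-derived
cutoff with a 500-MFI floor. Seroprevalence, false-discovery summaries
(`FP / (FP + TP)` over the non-case groups), and per-antigen rank-based AUC
follow from the positivity matrix.

**Panel search.** All `n! / ((n−r)! r!)` subsets of the validated antigens
(r = 1 … 15) are scored as union-rule classifiers — panel-positive means
positive for at least one panel antigen — under the constraint of at most
one type I interferon and one lambda interferon per panel (cross-reactive
families). Panels are ranked by the balanced single-threshold AUC
`(sensitivity + specificity) / 2`, smaller panels first on ties.

**Confirmation and profiling.** The radioligand binding assay reports an
antibody index `((cpm_sample − cpm_neg) / (cpm_pos − cpm_neg)) × 100` with
positivity above the blood-donor mean + 3 SD; clinical associations
(bronchiolitis obliterans, thymoma, follicular lymphoma) use two-sided
Fisher's exact tests on the positivity calls; and profile structure is
summarized by PCA of log-transformed signal intensities.

## Worked example

A study-sized synthetic cohort (group sizes 84 PNP / 19 PV / 20 PF / 20 BP /
14 EBA / 30 Ap200P / 38 CA / 105 HC; 15-antigen bead panel with planted
seroprevalences, a thymoma subgroup carrying cytokine autoantibodies, and a
bronchiolitis-obliterans subgroup enriched for SERPINB3):

```r
library(pnpsero)

sim    <- simulate_bead_cohort(study_bead_spec(seed = 42))
cohort <- join_metadata(sim$signal, sim$meta)
cohort
#> # Annotated cohort: 330 samples, 15 antigens (bead assay)
#>   groups: Ap200P=30, BP=20, CA=38, EBA=14, HC=105, PF=20, PNP=84, PV=19

hc  <- group_ids(cohort, "HC")
pnp <- group_ids(cohort, "PNP")
non <- setdiff(sim$signal$sample_id, pnp)

cutoffs <- compute_cutoffs(sim$signal, hc_ids = hc)   # mean + 5 SD, floored at 500
calls   <- call_positives(sim$signal, cutoffs)

prevalence(calls, pnp, "SERPINB3")
#>   antigen_id count total percent
#> 1 SERPINB3      39    84      46
```

39 of the 84 PNP sera exceed the SERPINB3 cutoff (46%, one binomial draw
around the planted 53%); a single positive among the 246 non-PNP samples
gives a false-discovery rate of 1/40:

```r
false_discovery_rate(calls, pnp, non, "SERPINB3")
#>   antigen_id  tp  fp   fdr fdr_percent
#> 1 SERPINB3    39   1 0.025           3

screen <- marker_screen(sim$signal, pnp, non)         # AUC > 0.50 prefilter
search <- exhaustive_search(calls, screen, study_antigen_meta(), pnp, non)
glance(search)
#>   n_evaluated best_panel              best_size best_sensitivity best_specificity best_auc
#> 1         767 SERPINB3+SERPINB4+...           7            0.869            0.988    0.928
```

The exhaustive search scored 767 family-legal panels of the 9 retained
antigens; the best 7-antigen union rule detects 86.9% of PNP cases while
calling 1.2% of non-cases positive. Clinical association recovers the
planted bronchiolitis-obliterans link:

```r
fisher_association(calls, sim$meta, "SERPINB3", "bronchiolitis_obliterans")
#> # Fisher's exact association: SERPINB3 ~ bronchiolitis_obliterans
#>          positivity
#> feature   positive negative
#>   present       14        3
#>   absent        25       42
#>   two-sided p = 0.001045

pca <- pca_profiles(sim$signal)
top_contributors(pca, component = 1, n = 3)
#>   antigen_id contribution loading
#> 1 A2ML1              28.8  -0.537
#> 2 SERPINB3           24.9  -0.499
#> 3 SERPINB4           19.6  -0.442
```

Each result has `tidy()`/`glance()` methods and a plot builder
(`plot_enrichment()`, `plot_prevalence()`, `plot_proportion_heatmap()`,
`autoplot()` on PCA objects, `plot_scree()`, `plot_panel_sizes()`).

The discovery-phase functions follow the same pattern on duplicate-spot
long tables: `collapse_duplicates()` → `quantile_normalize()` →
`fold_change()` → `repertoire_size()` / `leave_k_out_repertoire()`, with
`simulate_microarray()` providing planted-truth input. See the methods
vignette (`vignettes/pnpsero-methods.Rmd`) for the model, parameter, and
calibration details.

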