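# mvibench

Peritumoral CT radiomics benchmarking and model fusion for microvascular
invasion (MVI) prediction — on fully synthetic, ground-truth-known data.

## The problem

MVI — tumor cells invading small vessels, detectable only at pathology —
is a key prognostic factor in hepatocellular carcinoma, and a large
radiomics literature asks whether it can be predicted preoperatively from
multi-phase contrast CT. Three design questions dominate that literature:

1. **Which CT phase** (early/late arterial, portal venous, equilibrium)
   carries the signal, alone or concatenated?
2. **How far beyond the tumor margin** does the predictive peritumoral
   signal extend?
3. **Which selector x classifier pipeline** finds it, and does fusing the
   top models beat the best single one?

`mvibench` implements the full answer machinery — synthetic four-phase
phantoms, barrier-aware peritumoral region construction at physical
distances, a 94-feature radiomics catalogue (first-order, GLCM, GLSZM,
GLRLM, NGTDM, GLDM), a 15-selector x 10-classifier x 15-phase-combination
x 15-region benchmark grid (33,750 configurations) under leakage-free
stratified ten-fold cross-validation, and top-3 model fusion by plurality
vote (PV) and accuracy-weighted fusion (WF) with net reclassification
improvement (NRI) comparisons.

Because the cohorts are synthetic with known ground truth, every claim the
pipeline makes is testable: inject no effect and the benchmark must report
chance; inject an effect in one phase within a known extent and the
benchmark must recover both. The test suite does exactly that. See the
methods vignette (`vignettes/mvibench-methods.Rmd`) for the model and all
numerical conventions.

## Worked example

A reduced study: 24 patients, an intensity + heterogeneity effect injected
in the portal venous phase (PVP, combo label `Fpha3`) within 6 mm of the
tumor margin; the grid crosses 2 selectors, 2 classifiers, 2 phase
combinations and 4 regions.

```r
library(mvibench)

cfg <- run_config(
  spec = cohort_spec(n_patients = 24, prevalence = 0.5,
                     volume_shape = c(32, 32, 32),
                     tumor_radius_mm = c(3.5, 4.5),
                     effect_intensity = 40, effect_heterogeneity = 0.3,
                     effect_phase = "PVP", effect_extent_mm = 6,
                     noise_sd = 15, seed = 7),
  distances = c(2, 4, 6),
  selectors = c("t_score", "mim"),
  classifiers = c("lda", "logistic"),
  combos = c("Fpha1", "Fpha3"),
  regions = c("V_tc", "V_tc+V_pt(2)", "V_tc+V_pt(4)", "V_tc+V_pt(6)"),
  n_train = 18, k_features = 5, n_folds = 6, seed = 7)

res <- run_study(cfg)
res$summary$best
#> # A tibble: 1 × 4
#>   phase_combo region_class mean_auc n_configs
#>   <chr>       <chr>           <dbl>     <int>
#> 1 Fpha3       V_tc+V_pt           1        12
```

The benchmark recovers the injected design: the best setting is the PVP
phase (`Fpha3`) with a tumor-core-plus-peritumoral region, and the
cross-validated AUC rises with ring distance before dropping once the
ring outgrows the 6 mm effect (dilution by unaffected tissue at this
small cohort size):

```r
res$summary$distance_trend
#> # A tibble: 3 × 4
#>   region_class distance mean_auc n_configs
#>   <chr>           <dbl>    <dbl>     <int>
#> 1 V_tc+V_pt           2    0.846         8
#> 2 V_tc+V_pt           4    0.852         8
#> 3 V_tc+V_pt           6    0.740         8

res$fusion$metrics
#> # A tibble: 5 × 6
#>   model                           kind     auc   acc   sen   spe
#>   <chr>                           <chr>  <dbl> <dbl> <dbl> <dbl>
#> 1 Fpha3|V_tc+V_pt(4)|mim|lda      member     1     1     1     1
#> 2 Fpha3|V_tc+V_pt(4)|mim|logistic member     1     1     1     1
#> 3 Fpha3|V_tc+V_pt(4)|t_score|lda  member     1     1     1     1
#> 4 PV                              fusion     1     1     1     1
#> 5 WF                              fusion     1     1     1     1
```

(The perfect test-set metrics reflect the deliberately strong injected
effect and the 6-case test split, not typical real-data performance.)
The most frequently selected features across high-AUC configurations are
the PVP first-order intensity statistics, as expected for an additive
intensity effect:

```r
head(res$census, 3)
#> # A tibble: 3 × 3
#>   feature                     count percentage
#>   <chr>                       <int>      <dbl>
#> 1 PVP_firstorder_90Percentile    62      12.2
#> 2 PVP_firstorder_Mean            49       9.61
#> 3 PVP_firstorder_Median          46       9.02
```

Plot helpers (`ggplot2`): `autoplot(res$summary)`,
`plot_distance_trend(res$summary)`, `plot_nri_matrix(res$fusion$nri)`,
`autoplot(res$fusion)`, `plot_feature_census(res$census)`.

Lower-level entry points compose the same way the pipeline does:
`generate_cohort()` → `build_region_set()` / `expand_region()` →
`radiomic_features()` / `extract_cohort()` → `tenfold_cv()` /
`run_benchmark()` → `fuse_top_models()`; NIfTI I/O via `write_cohort()`
and `read_case()`.

## License

MIT (see `LICENSE`).
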