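# metabostate

Health-state prediction from untargeted metabolomics feature tables, with
honest accounting of what univariate significance filtering gains and
loses.

Untargeted LC/GC-MS case/control studies produce tables of thousands of
features — (m/z, retention time, intensity) triplets — and conventionally
keep only those passing a Mann-Whitney U + Benjamini-Hochberg filter
(Q < 0.05) before training a classifier. `metabostate` implements the full
comparative pipeline around that choice:

* **Preprocessing** — prevalence filter, floor-at-1 + binary log
  transform, and per-batch *percentile normalization*: each sample's value
  becomes the mean-rank percentile of its log-intensity within the batch's
  control distribution for that feature.
* **Leakage-safe feature regimes** — all features; significant-only and
  top-k-significant with Q-values recomputed inside each outer training
  fold; non-significant-only (complete-data significance); and
  non-significant with isotope/adduct satellites removed.
* **Isotope/adduct explanation** — a non-significant feature is a putative
  satellite of a significant one when retention times are < 15 s apart and
  the mass difference lies in one of the mode's windows (1×¹³C
  [0.994, 1.012], 2×¹³C [1.998, 2.016]; positive: Na⁺ [21.975, 21.985],
  K⁺ [37.954, 37.962]; negative: Cl⁻ [35.969, 35.985], −H₂O−H
  [18.006, 18.016] Da).
* **Evaluation** — L1-regularized logistic regression under stratified
  5-fold outer / 3-fold inner nested cross-validation (C ∈ {2, 5, 20, 50,
  100}, inner selection by ROC-AUC), repeated over 30 independent data
  shuffles; mean/SD/95% CI of AUC, balanced accuracy, MCC, sensitivity,
  specificity, precision, and averaged sparse coefficients. An empty
  feature set records AUC exactly 0.5; sub-0.5 test AUCs are kept.
* **Synthetic data with ground truth** — a generator that plants markers
  (closed-form single-marker Bayes AUC `pnorm(delta/(sigma*sqrt(2)))`),
  correlated isotope/adduct satellites at window offsets, diffuse weak
  signal, batch effects and missing values, so recall, calibration and
  leakage can be measured against known structure.

## Worked example

```r
library(metabostate)

cfg <- generator_config(n_controls = 40, n_cases = 40, n_features = 120,
                        n_markers = 3, marker_effect = 2,
                        n_satellites_per_marker = 2, satellite_noise_sd = 5,
                        seed = 42)
gen <- generate_table(cfg)
gen$truth
#> <ground_truth> 3 markers, 6 satellite links, 0 diffuse features
#>   theoretical single-marker AUC: 0.9214

norm <- percentile_normalize(floor_and_log(prevalence_filter(gen$table)))
sig  <- significance_on_training_fold(norm)
sum(sig$significant)
#> [1] 5

explain_features(norm, sig, mode = "positive")
#> <explanation_map> 5 links, 5 explained features (4.3% of non-significant)

res <- nested_cv_l1lr(norm, cv_protocol(n_shuffles = 5, seed = 1))
res
#> <evaluation_result> mean AUC 0.961 +/- 0.009 (SD over 5 shuffles), 95% CI half-width 0.005
#>   nonzero averaged coefficients: 97 of 120 features
```

Three of the planted markers reach Q < 0.05 (plus two satellites); five of
the six noisy satellites are recovered by the mass-window/retention-time
annotation; and the cross-validated model, trained on *all* 120 features,
beats the single-marker Bayes bound of 0.921 by combining the three
markers (mean AUC 0.961 over five shuffles).

The scripts under `analysis/` run the full story on stored synthetic
studies — `01_simulate.R` through `05_parameter_recovery.R` — writing
tables beneath `results/`: regime comparisons with delta-AUCs, top-k
sweeps, satellite-removal effects, and the calibration curve of CV AUC
against the closed-form Bayes AUC.

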