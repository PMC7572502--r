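---
title: "Health-state prediction from untargeted metabolomics feature tables: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metabostate methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Untargeted LC- or GC-MS metabolomics reduces a biofluid sample to a table
of *features* — (mass-to-charge ratio, retention time, intensity) triplets
produced by peak detection. Case/control studies conventionally shrink this
table to the handful of features that pass a univariate significance filter
(Mann-Whitney U with Benjamini-Hochberg FDR control, Q < 0.05) before any
classifier sees it. `metabostate` implements the opposing workflow: train
sparse L1-regularized logistic regression on *all* features under a
leakage-safe nested cross-validation, quantify what significance filtering
discards, and account for how much "non-significant" signal is really
isotope/adduct bookkeeping of the significant features.

Because the original repository studies are not bundled, every claim the
package makes is exercised on a synthetic generator with planted, known
structure; the generator is first-class, tested code, not a fixture.

## Preprocessing

1. **Prevalence filter.** Features detected (raw intensity >= 1) in at most
   5% of samples are dropped; `minFrac`-style extraction thresholds make
   rarer features unreliable.
2. **Floor and binary log.** Missing and sub-1 intensities are set to 1,
   then `log2` is applied, so absent peaks are exactly 0. The transform is
   guarded by a provenance flag: applying it twice is *not* idempotent
   (`log2` of a log value above 1 changes again), so the second call errors
   instead of silently corrupting the scale.
3. **Percentile normalization.** Within each batch, every sample's value
   for a feature becomes the percentile of that value within the batch's
   *control* distribution for the feature. Batches are normalized
   separately and re-combined; without batch labels the table is one batch.

### Conventions the percentile step pins down

The cited normalization strategy does not specify tie handling, so the
package adopts the mean-rank convention
`100 * (#controls below + 0.5 * #controls equal) / #controls`:

* values below every control map to 0, above every control to 100;
* a control scored against an all-tied control set maps to 50;
* a control sample is left **in** its own reference set. With distinct
  values the self-percentiles of the controls then average exactly 50 per
  feature and batch, a property the tests assert at 1e-9;
* the output depends on ranks only, so a strictly increasing per-feature
  transform of raw intensities leaves it bit-identical (also asserted).

A consequence worth knowing: because cases are ranked against controls
only, a finite control sample that happens to sit low for some feature
shifts *all* case percentiles for that feature up — in training and test
folds alike, since normalization precedes cross-validation (as in the
workflow this package reproduces). On null data this inflates nothing *in
expectation* (a 10-dataset check of the full engine on pure noise averaged
AUC 0.507) but it does add dataset-level variance to null AUCs. The
within-fold selection machinery is unaffected: the leakage null below
stays inside [0.45, 0.55].

## Significance and feature regimes

`mwu_test()` is two-sided; the exact null distribution is used when both
groups have at most 8 untied observations (the tests verify this branch
against full enumeration of rank assignments for all group sizes up to 6),
otherwise the normal approximation with tie and continuity correction. A
fully tied feature carries no information and returns p = 1. Q-values come
from the Benjamini-Hochberg step-up (verified against a brute-force oracle
to 1e-12); Q < 0.05 defines "significant".

Five regimes are compared:

| regime | significance source |
|---|---|
| `all` | none |
| `significant_only` | recomputed on each outer training fold |
| `top_k_significant` (k = 5, 10, 50, 100) | recomputed on each outer training fold |
| `nonsignificant_only` | complete data set, before CV |
| `nonsignificant_no_satellites` | complete data set + explanation map |

The asymmetry — within-fold for the significant regimes, complete-data for
the non-significant ones — mirrors the workflow being reproduced and is
kept deliberately. When fewer than k features are significant, the top-k
regime uses just those; ties on Q break lexicographically by feature id so
results are reproducible. An empty selection is legal and triggers the
degenerate convention below.

## Isotope/adduct explanation

Significant features are assumed to be [M−H]⁻ or [M+H]⁺ ions. Any other
feature is explained as a putative isotope or adduct of a significant
parent when the retention times are strictly less than 15 s apart and the
mass difference child − parent falls inside one of the mode's windows
(both modes: 1×¹³C [0.994, 1.012] and 2×¹³C [1.998, 2.016] Da; positive
additionally Na⁺ [21.975, 21.985] and K⁺ [37.954, 37.962]; negative Cl⁻
[35.969, 35.985] and water loss [18.006, 18.016]). Only positive offsets
are tested — the listed species are all heavier than the assumed ion — and
a zero mass difference never links. Window bounds are inclusive at the
printed precision (a 1e-9 Da guard keeps binary floating point from
excluding exact bounds); the windows within a mode are disjoint, asserted
at registry construction. Children are restricted to non-significant
features, matching how the map is used (fraction of non-significant
features explained; removal ahead of the `nonsignificant_no_satellites`
regime); `children = "all"` is available for diagnostics. A child may be
explained by several parents; every link is kept but the child counts once.

## Evaluation engine

Stratified 5-fold outer / 3-fold inner nested cross-validation; the inner
loop picks the inverse-regularization strength C from {2, 5, 20, 50, 100}
by ROC-AUC (first grid value on ties); the model refits on the outer
training fold and is scored on the held-out fold. The whole protocol runs
on `n_shuffles` independent permutations of the data (30 by default);
shuffle *i* seeds its own RNG stream with `seed + i`, so runs are
bit-reproducible and no global RNG state is touched.

Decisions the surrounding description leaves open, fixed here:

* **C-to-lambda mapping.** C is on the sklearn scale (summed log-loss plus
  `(1/C)·||w||₁`); glmnet minimizes mean loss plus `λ·||w||₁`, so
  `λ = 1/(C·n_train)`. Features enter unstandardized, as percentile scores
  in [0, 100]. Convergence follows glmnet's coordinate-descent defaults.
* **Per-shuffle AUC** is the mean of outer-fold test AUCs (not pooled
  predictions); the reported SD is over shuffle means.
* **95% CI half-width** is `1.96·SD/√(avg outer-test-fold size)` — the
  average *test* count is used as the effective sample size to widen the
  interval for small studies.
* **Hard-label metrics** (balanced accuracy, MCC, sensitivity, specificity,
  precision) use the 0.5 probability threshold; MCC is 0 when its
  denominator vanishes; precision is undefined (NaN) with no positive
  predictions and such folds are dropped from its average.
* **Sub-0.5 test AUCs are retained** — overfit folds are data, not errors.
* **Degenerate convention.** A feature set that is empty (after a regime,
  or within a fold after selection) records AUC exactly 0.5 with no model
  trained.

The harness is classifier-agnostic (`evaluate_classifier()`); only
`"l1lr"` is registered, and other standard names fail with an explicit
not-implemented error rather than a silent fallback.

## The synthetic generator

The generator works on the log2 scale because the pipeline's first real
step is the binary log: effects become additive. Per feature, a baseline is
drawn uniformly in [8, 24] (typical detector log-counts) and samples get
Gaussian noise (`noise_sd`, default 1 — on a log2 scale this is a
several-fold coefficient of variation, ordinary for untargeted
intensities). On top of that:

* **Markers** add `marker_effect` to cases. The closed form
  `theoretical_auc(delta, sigma) = pnorm(delta/(sigma*sqrt(2)))` gives the
  Bayes-optimal single-marker AUC; the generated data's strongest-marker
  empirical AUC matches it within ±0.01 at 5000/class.
* **Satellites** copy the parent marker's per-sample log-intensity, minus a
  uniform dimming constant in [1, 3] log2 units, plus
  `satellite_noise_sd` Gaussian noise (default `0.1·noise_sd`, giving
  parent correlation above 0.9). Sharing the parent's draw — rather than
  redrawing the class shift independently — is what makes satellite
  removal a real information deletion. Satellite m/z sits strictly inside
  the named window relative to the parent; retention time within
  `rt_jitter_max_s` (default 14 s, inside the 15 s gate).
* **Diffuse signal** adds `diffuse_effect` (random sign) to a fraction of
  background features.
* **Batches** add per-batch, per-feature Gaussian offsets in log space —
  multiplicative on the raw scale — and samples are dealt to batches
  round-robin within class.
* **Missingness** zeroes intensities with probability `missing_rate`, and
  anything below 1 is reported as 0, so the floor-and-log rule is
  genuinely exercised.
* With `avoid_satellite_windows = TRUE` the non-satellite m/z values are
  rejection-sampled so no unplanned pair lands in a window at close
  retention time; planted links are then the only true links, which is
  what makes annotation recall and precision checkable link-by-link.

What it does **not** emulate: chromatographic drift, in-source
fragmentation, realistic isotopologue intensity ratios, heavy-tailed or
multimodal intensity marginals, correlated metabolite modules beyond the
parent-satellite mechanism, and batch effects that alter rank order
nonlinearly. Passing tests therefore demonstrate the *machinery* —
leakage-safety, calibration, accounting — under a clean generative model,
not performance on any real cohort.

## Study conditions used by the automated checks

Problem sizes were chosen to exercise each property at the smallest scale
where it is meaningful: oracle equivalence on 1000 random p-vectors and
all group sizes up to 6; parameter recovery at 150/class with 2000
features (one marker, effects 0-2, 10 shuffles); the leakage null at
40+40 with 200 features and 30 shuffles; satellite accounting at 60/class,
200 features, 3 markers of effect 3 with 6 satellites each at satellite
noise 6 (satellites individually weak, near the significance boundary, yet
collectively informative); regime ordering over 20 diffuse-dominated
datasets (40/class, 150 features, two weak markers of effect 0.5, 30% of
background at ±0.3) with 5 shuffles each.

## A calibration finding worth reading

With a *single* weak marker among 2000 features, the nested-CV AUC falls
well short of the closed-form Bayes AUC at intermediate effect sizes
(≈0.58 measured vs 0.76 theoretical at effect 1). This is not an
implementation artifact: running scikit-learn's L1 logistic regression
with the identical C grid and fold structure on the identical
percentile-normalized table reproduces the package's number to three
decimals. The C grid caps the penalty at `λ = 1/(2n)`, so with p ≫ n the
fitted models keep hundreds of noise features whose accumulated variance
dilutes one weak marker; performance recovers as effects strengthen
(≈0.86 vs 0.92 at effect 2) or as the real multivariate signal grows —
which is precisely the regime the all-features workflow is designed for.
The same dilution caps how much AUC the satellite-removal comparison can
move on concentrated-signal data (measured drop ≈0.14). Both numbers are
recomputed, not asserted, by `scripts/acceptance.R`.

## Known limitations

* Only L1 logistic regression is implemented behind the classifier
  contract; PLS-DA/RF/SVM/kNN/NB are explicit not-implemented errors.
* Batch labels must be supplied; no inference from run order or QC samples.
* Charge state 1 is assumed throughout the annotation; no in-source
  fragmentation, no isotope intensity-ratio plausibility checks.
* Multiclass problems are handled by one-vs-one reduction upstream of the
  binary engine, never natively.
* The replicate-dropping rule is deterministic (first by sorted sample id)
  where the reproduced workflow chose arbitrarily; results on replicated
  designs can therefore differ from any one historical run.
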