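# lungtexture

Windowed texture quantification and classification for edge-enhanced
(propagation-based X-ray phase-contrast) lung projection images of mice,
with a fully seeded synthetic phantom generator so the entire pipeline is
testable without animal data.

High-magnification phase-contrast projections show a fine bright speckle
wherever air-filled alveoli scatter the beam; the speckle's contrast grows
with lung inflation while the mean intensity barely moves. This package
turns that observation into two classification tasks — window-level lung
segmentation and per-mouse ventilation-pressure calling — built from:

* **Preprocessing** — rank-based percentile clipping, exact histogram
  specification (distribution-identical and idempotent), ROI set
  arithmetic.
* **Features** — four feature modes (identity, local-Otsu skeleton,
  gradient magnitude, blurred Laplacian) summarized over 32-px windows at
  stride 16, plus a bandpass log-power sum and a directional-filter
  orientation PDF yielding an orientation angle and a *horizontality*
  score (+1 horizontal, −1 vertical, 0 isotropic): 11 predictors per
  window.
* **Classification** — 95%-purity window labeling, exact class balancing,
  per-mouse z-scoring, 128-tree random forests, leave-one-mouse-out
  cross-validation, plurality votes, confusion probabilities, and
  misclassification–boundary distance analysis.
* **Regional analysis** — fill-holes + size-filter mask post-processing,
  cranial/middle/caudal k-means regions, per-region horizontality,
  Kendall τ-b texture–intensity decorrelation.
* **Phantoms** — seeded generator of 16-bit images with registered masks:
  pressure-dependent rectified speckle, a cranial–caudal orientation
  gradient, rib bands, heart, diaphragm, and per-mouse nuisance variation.

See the methods vignette (`vignettes/methods.Rmd`) for the model, every
parameter with units and rationale, and what the phantoms do and do not
emulate.

## Quick start

```r
library(lungtexture)

# one phantom mouse and its feature table
mouse <- generate_mouse(phantom_spec(pressure = 10, seed = 1))
grid  <- make_window_grid(nrow(mouse$image), ncol(mouse$image))
ft    <- build_feature_table(mouse$image, grid)

# cohort -> labeled features -> leave-one-mouse-out CV
cohort <- generate_cohort(n_mice = 8, pressures = c(6, 8, 10, 12),
                          master_seed = 1)
ds <- cohort_features(cohort, task = "pressure")
cv <- lomo_cv(ds, task = "pressure", seed = 1)
summary(cv)
confusion_probabilities(cv)
```

Disk-based, command-style runs:

```r
cfg <- run_config(output_dir = "raw", n_mice = 8)
cmd_simulate(cfg)                                          # TIFF + masks + JSON
cmd_features(run_config(input_dir = "raw", output_dir = "feat"))   # CSV per image
cmd_classify(run_config(input_dir = "feat", output_dir = "out"))   # cv_report.json
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "lungtexture")
```

The suite covers unit oracles (sort-based quantiles, naive DFT, exhaustive
Otsu, O(n²) Kendall τ), the disk round trip, and an acceptance file
(`tests/testthat/test-acceptance.R`) asserting the analytic quantities and
seeded phantom-cohort properties.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Computes the analytic quantities (window count, magnification, experiment
enumeration) and the property-suite statistics (gain-sweep segmentation
accuracies, pressure confusion probabilities, paired-pressure accuracies,
horizontality endpoints and regional medians, misclassification distances,
histogram-matching KS distance, z-score invariants, Kendall τ checks) on
cohorts seeded from `--seed`, and writes them as JSON.
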