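# hccapa

Organelle-resolved quantification of cytosolic delivery and cytotoxicity
for the **high-content chloroalkane penetration assay (HC CAPA)**, with a
synthetic-microscopy generator that makes every stage testable against
exact ground truth.

## The problem

The CAPA measures how much of a chloroalkane-tagged cargo reaches the
cytosol: delivered cargo covalently blocks intracellular HaloTag–GFP
fusions, and a cell-permeant chloroalkane reporter dye then labels only the
tags left free — so reporter signal *decreases* with delivery. Read out by
automated microscopy instead of flow cytometry, the assay can be quantified
*per cell* and *per organelle*: restricting the reporter measurement to the
organelle that actually carries the HaloTags (mitochondrial network, Golgi)
removes off-target dye signal that whole-cell readouts cannot escape.

This package is for scientists running or modelling such screens. It
implements:

* **Synthetic plates** (`build_plate()`): log-normal per-cell expression,
  Hill-type HaloTag blocking
  `theta(c) = c^h / (c^h + CP50^h)`,
  reporter proportional to `expression * (1 - theta)`, off-target reporter
  puncta, damaged cells (condensed nuclei, fragmented organelles),
  transient-transfection mixtures of non-/normal/over-expressers, and a
  Poisson–Gaussian camera — written as 16-bit multi-page TIFFs plus a
  ground-truth CSV.
* **Segmentation** (`segment_field()`): Otsu + distance-watershed nuclei,
  seeded-propagation cell bodies, per-cell top-hat organelle masks,
  dark-region masks.
* **Per-cell quantification and QC** (`extract_features()`, `apply_qc()`):
  background-subtracted intensities under each mask, damaged-cell
  exclusion calibrated on control wells, and the transient-transfection
  gate (dark-region + minimum-expression criteria).
* **Statistics** (`fit_dose_response()`, `regression_r2()`,
  `toxicity_curve()`, `compare_masks()`): four-parameter logistic
  `S(c) = bottom + (top - bottom) / (1 + (c/CP50)^hill)`
  fitted by Levenberg–Marquardt with CP50/hill in log space and replicate
  SEMs; per-cell GFP-vs-reporter OLS r² as the mask-accuracy metric;
  toxicity as percent of damage-free cells relative to controls; paired
  one-tailed Student's t comparison of masks.
* **Pipeline + CLI** (`run_pipeline()`, `inst/cli/hccapa.R`): simulate →
  segment → quantify → fit → report, with per-stage logging, a run
  manifest, and deterministic reruns.

## Worked example

A full stable-line screen (8 concentrations incl. controls, 6 replicates,
2 fields/well, ~60 cells/field) simulated with a ground-truth CP50 of
7.3 µM and default off-target puncta:

```r
library(hccapa)
cfg <- capa_config()                       # cp50_true = 7.3 uM, 15% damage
lay <- plate_layout(n_replicates = 6, n_fields = 2)
res <- run_pipeline(cfg, "plate_out", mode = "stable", layout = lay, seed = 42)
res$fits$fits$organelle
#> dose-response fit: CP50 = 7.37 +/- 0.39 uM (hill 1.00, top 4.02e+03, bottom 0, 6 replicates)
res$fits$fits$body
#> dose-response fit: CP50 = 7.96 +/- 0.69 uM (hill 0.92, top 2.04e+03, bottom 0, 6 replicates)
res$fits$comparison
#> mask comparison: CP50 whole-cell 7.96 vs organelle 7.37 uM (+8.0%), p = 0.0886 (paired one-tailed t, df 5)
head(res$toxicity, 3)
#>   concentration percent_selected       sem n_replicates
#> 1        0.0000        100.00000 1.5487581            6
#> 2        0.3125         97.26688 1.1254019            6
#> 3        0.6250         98.71383 0.9207602            6
```

Reading the output: the organelle-restricted mask recovers the generator's
CP50 within its replicate SEM, while the whole-cell mask — polluted by the
concentration-independent off-target puncta — overestimates CP50 (lower
apparent potency, here by 8%) and is about half as precise; the paired
one-tailed test quantifies the planned comparison (its p-value varies with
the seed, since the off-target variability that biases the whole-cell mask
also widens its replicate spread). The toxicity curve stays at ~100% of
the control count across the whole concentration range, as expected for a
generator whose damage probability does not depend on concentration.
`plate_out/` holds the images, masks, `cells.csv` (one row per cell),
`qc_summary.*`, `results.json`, `toxicity.csv`, `comparison.json`, plots
and the run manifest.

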