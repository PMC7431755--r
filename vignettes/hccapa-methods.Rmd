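---
title: "Quantifying cytosolic delivery with the high-content CAPA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cytosolic delivery with the high-content CAPA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The assay and what the package computes

The chloroalkane penetration assay (CAPA) reads out cytosolic delivery
through covalent chemistry: cells express a HaloTag fusion (here a
HaloTag–GFP construct anchored to an organelle membrane), a
chloroalkane-tagged cargo that reaches the cytosol blocks a fraction of the
tags, and a subsequently added cell-permeant chloroalkane dye labels only
the tags that remain free. Dye signal therefore *decreases* with delivery.
In its high-content (HC) form the readout is automated fluorescence
microscopy: three channels per field (nuclear stain, GFP, reporter dye),
segmented into per-cell masks, so the reporter can be quantified exactly
where the HaloTags live instead of over whole cells.

`hccapa` implements this pipeline end to end — segmentation, per-cell
feature extraction, quality control, dose–response fitting, toxicity and
mask comparison — together with a synthetic-microscopy generator that
embodies the assay mechanism. The generator exists because every stage can
then be validated against exact ground truth: expression levels, HaloTag
occupancies, damage labels and organelle pixels are all known for every
simulated cell.

## The generative model

Per cell, the generator draws:

* **Expression** $E \sim \mathrm{LogNormal}$, parameterised by its median
  (default 1, arbitrary units) and coefficient of variation (default 0.4,
  a typical per-cell spread for a stable expression line).
* **Occupancy** $\theta(c) = c^h / (c^h + \mathrm{CP_{50}}^h)$, the
  Hill-type fraction of HaloTags blocked at transporter concentration $c$.
  The midpoint CP50 (default 7.3 µM) and slope $h$ (default 1) are
  configuration values; the slope is not pinned down by the assay
  literature, so a non-cooperative default was chosen and exposed.
* **Damage** flag with probability `p_damaged` (default 0.15). Damaged
  cells are rendered with condensed, brighter nuclei (0.35 linear scale,
  1.8× intensity) and a fragmented organelle network — the two
  morphological signs the QC filter is built to catch.
* **Expression class** (transient mode only) from `transient_mix`:
  non-expressers (expression ×0.01), normal expressers, and
  over-expressers (10–25× the median) whose GFP fills the whole cell body,
  leaving no dark region.

Channels are rendered onto a 512×512 px field at 0.65 µm/px with ~60 cells
placed on a jittered grid with a minimum-separation rejection step (cells
overlap at most marginally, as in a subconfluent culture). GFP intensity on
the organelle texture is `gfp_gain × E`; the reporter deposits
`reporter_gain × E × (1 − θ)` on the same texture, so with the camera noise
disabled the mean specific reporter signal per cell is *exactly*
proportional to the free-tag fraction — the invariant the test suite
checks. Mitochondria are drawn as confined random-walk filaments, the Golgi
as a peri-nuclear puncta cluster.

Off-target reporter signal — dye stuck outside the organelle, the bias the
organelle mask exists to remove — is modelled as puncta placed inside the
cell body but outside the organelle texture, with mean amplitude
`offtarget_amplitude × reporter_gain × E` (default 0.15 of the cell's
maximal specific signal). The staining is stochastic, as dye retention is
in practice: the per-cell puncta count is Poisson (mean 6), each punctum's
amplitude carries log-normal jitter (CV 0.35), and a log-normal per-field
scale (CV 0.6) models the strong field-to-field washing variability seen
in stained cultures. The amplitude is deliberately
*concentration-independent*: it adds a pedestal to whole-cell responses,
which is what makes the whole-cell CP50 drift upward — and its
field-to-field variability is what makes the whole-cell estimate *noisier*
— while the organelle-mask CP50 stays put (see the fitting section).

All channels pass a Poisson–Gaussian camera model (shot noise scaled by
`poisson_scale`, Gaussian read noise, constant offset, 16-bit clipping) —
the standard sCMOS approximation. Setting both noise terms to zero gives
bit-exact, analytically checkable renders. Per-field RNG streams are
derived from the master seed, well id, field index and stage name by a
polynomial rolling hash reduced modulo $2^{31}-1$, so plates are
reproducible field by field regardless of generation order.

What the generator does **not** emulate: optical PSF blur and
deconvolution, 3-D structure, cell motion and division, endosomal uptake
intermediates, spectral bleed-through. Passing tests therefore demonstrate
the *analysis* machinery is correct and calibrated on images whose
difficulty is of the right order — not that segmentation would reach the
same accuracy on any particular real microscope.

## Segmentation

The stages mirror standard high-content practice and are deliberately
parameter-light:

* **Nuclei**: Gaussian blur (σ = 2 px), Otsu global threshold, hole
  filling, distance-transform watershed (tolerance 2) to split touching
  nuclei, area gate 40–1500 px².
* **Cell bodies**: seeded Voronoi-style propagation (EBImage `propagate`)
  from the nucleus labels over a smoothed GFP + nuclear landscape,
  restricted to the union of a global foreground (median + 3·MAD of the
  landscape) and a 20 px dilation ring around each nucleus, then clipped to
  34 px from the nucleus centroid. The intensity weighting (`lambda`
  = 1e-4) makes boundaries between a dim and a bright neighbour follow the
  intensity ridge, which keeps a bright over-expresser from bleeding into
  the body of a dark neighbour. Border-touching cells are discarded
  (partial cells bias intensity means) and counted.
* **Organelle mask**: white top-hat (disc 9 px) suppresses the smooth
  cytoplasmic component; within each cell, top-hat values above the cell's
  median + 3·MAD are organelle pixels. The per-cell threshold is capped at
  the field-level median + 3·MAD: in a cell whose body is densely covered
  by filaments the per-cell statistics sit on the texture itself and the
  uncapped rule would return an empty mask.
* **Dark region**: body pixels with GFP at most the background level +
  2 background SDs. Background per channel is the median of pixels outside
  all cell bodies; its SD is the scaled MAD of the same pixels.

Pixels are 1-based (row, col) in the R convention; label images use
4-connectivity, the watershed 8-connectivity. None of these choices claims
to reproduce the original assay software, which is not public; they are
standard choices that the ground-truth tests hold to account.

## Quality control

**Damaged-cell exclusion.** A cell is discarded when its nucleus is
condensed (area < `A_min`), its nuclear intensity is abnormal
(> `I_max`), or its organelle network is fragmented
(components/area > `F_max`). The thresholds are control-relative:
median ± k·MAD (k = 4) of the untreated control wells. Robust statistics
matter here — the controls themselves contain the baseline damaged
fraction, so percentile-based limits would adapt to the damage instead of
excluding it, while median/MAD stay anchored on the healthy mode for any
contamination well below half. The fragmentation limit is different: the
index's healthy spread is multiplicative and its MAD shrinks or swells
with the contamination level, so its limit is a fixed fold change
(40×) over the control median, evaluated only on cells with ≥ 120 px² of
organelle (a dim, sparsely detected network mimics fragmentation). True
fragmentation elevates the index by about two orders of magnitude and the
healthy tail by around 20×, so the 40× limit costs no recall. At the
defaults, a population simulated with 15% damage is flagged at recall 1.00
and a false-positive rate of a few per mille.

**Transfection gate.** In transient transfections only cells with both a
dark (GFP-free) region and clear organelle GFP are analysable:
over-expressers have GFP everywhere (dark fraction < 0.25 → removed) and
non-expressers have no localized signal. The minimum-expression test uses
the per-cell *upper quartile* of organelle GFP rather than the mean — a
single boundary pixel annexed from a bright neighbour can dominate the mean
of an empty cell, while isolated noise detections drag down the median of a
dark-bodied normal expresser; the upper quartile is robust to both. Its
floor is `max(3 × background SD, 0.05 × Q75 of organelle GFP among
dark-passing cells)`: anchoring on the dark-passing subset keeps
over-expressers (whose organelle masks are degenerate — saturated or
near-empty) out of the calibration, and an absolute floor alone cannot
distinguish faint spillover from true expression. With the 20/20/60
non/normal/over mixture this removes ~80% of cells: all non- and
over-expressers, and essentially no normal expressers.

## The quantitative layer

**Per-cell regression.** The reporter is regressed on GFP by OLS over
selected cells, pooled within a condition (the package computes the
pipeline r² on control wells — pooling across transporter concentrations
would mix dose levels into the correlation). r² is the mask-accuracy
metric: GFP is proportional to the HaloTag amount, so any reporter signal
the mask admits that is *not* on HaloTags (off-target puncta, neighbour
spill) degrades the correlation.

**Dose–response.** Per-well responses are the median background-subtracted
reporter mean of selected cells under the chosen mask (medians resist
residual off-target outliers; the aggregation level is configurable). The
descending four-parameter logistic
$S(c) = \mathrm{bottom} + (\mathrm{top} - \mathrm{bottom})\,/\,(1 +
(c/\mathrm{CP_{50}})^{\mathrm{hill}})$
is fitted by Levenberg–Marquardt least squares with CP50 and hill in log
space (tolerance 1e-14, responses scaled to unit maximum so the fit is
exactly scale-equivariant). Untreated wells enter at $c = 0$, where the
model takes the value `top` exactly — the top-asymptote anchor — rather
than as a point on a log axis. A response whose dynamic range is below 3×
the within-concentration noise is flagged non-converged and no CP50 is
reported.

In the pipeline the bottom is fixed at 0: complete HaloTag blocking
abolishes the *specific* reporter signal by the assay mechanism, and with
concentrations reaching only ~3× CP50 the bottom asymptote is never
observed, so a free bottom is both unidentifiable and able to silently
absorb any off-target pedestal. This constraint is what converts a
concentration-independent off-target baseline into the upward whole-cell
CP50 bias the organelle mask corrects — the behaviour the mask-comparison
suite checks. `fit_dose_response()` itself defaults to the free-bottom 4PL
(and recovers noiseless parameters to 1e-6 relative); `fix_bottom` is a
plain argument.

The reported `se_cp50` is the SEM of per-replicate CP50 fits, matching
replicate-wise error bars; the single-fit covariance SE is kept as a
diagnostic (`se_cp50_fit`). The package does not decide which of the two a
given publication used — both are in the output.

**Toxicity.** The percentage of cells passing the damage-free selection,
relative to the mean control-well count, per concentration with replicate
SEM. A non-toxic transporter gives a flat curve at 100%; because the damage
filter is morphological, the same screen that yields CP50 yields this curve
at no extra cost.

**Mask comparison.** Whole-cell vs organelle CP50s are compared by the
paired one-tailed Student's t-test on per-replicate CP50s, with the
direction fixed a priori as whole-cell ≥ organelle (the whole-cell mask
admits off-target signal; this is the planned, single comparison — no
multiplicity correction). Degenerate cases follow documented conventions:
identical pairs give t = 0, p = 0.5; zero-variance nonzero differences
report p at the machine floor with a flag.

## Numerical and design notes

* Problem sizes: the validation suite runs desk-scale experiments — plates
  of 8 concentrations × 6 replicates × 2 fields (~720 cells per
  condition; six replicates stabilise the replicate-SEM comparisons) for
  dose–response recovery, and ≥ 10⁴ cells for the filter-recovery rates,
  where the binomial sampling error is well inside the tolerances being
  checked.
* Determinism: identical configuration + master seed reproduce every
  ground-truth table bit for bit; rendered images add no hidden entropy
  beyond the derived per-field streams.
* Degenerate inputs are contracts, not surprises: a blank nuclear image
  yields zero nuclei; a cell with flat GFP yields an empty organelle mask
  and is flagged, not errored; an empty organelle mask keeps the cell in
  whole-body statistics; flat dose–responses are flagged non-converged.
* Known limitations: no optical PSF or deconvolution, no 3-D, no
  time-lapse or tracking, no endosome-level uptake model, no
  deep-learning segmentation, no Bayesian or mixed-effects dose–response.
  The damaged-cell criteria operationalise "early apoptosis" purely as
  nuclear condensation/brightening plus organelle fragmentation — a proxy,
  not a stain.

## Reproducing the validation numbers

```{r}
library(hccapa)

cfg <- capa_config()                      # the study conditions
lay <- plate_layout(n_replicates = 6, n_fields = 2)
res <- run_pipeline(cfg, "plate_out", mode = "stable", layout = lay, seed = 1)
res$fits$fits$organelle                   # CP50 +/- SEM, organelle mask
res$fits$comparison                       # whole-cell vs organelle masks
res$toxicity
```

`scripts/acceptance.R` re-derives the filter-recovery percentages and the
regression r² values from scratch; the testthat suite covers every
invariant discussed above.
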