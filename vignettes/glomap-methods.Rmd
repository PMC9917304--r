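---
title: "Methods: models, parameters and design choices in glomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in glomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`glomap` analyses wide-field calcium-imaging recordings of odor responses in
the honey bee brain and ships a synthetic-movie generator against which every
stage of the analysis is validated. This vignette documents the underlying
models, the tunable parameters, the numerical choices, and the places where
the design was genuinely open and a decision had to be made.

## The signal model and the processing chain

A recording is a 12-bit movie of 100 frames at 5 Hz; the odorant reaches the
antennae at the 15th frame for 1 s (5 frames). Processing follows a fixed
order, and the order is load-bearing:

1. **ΔF/F.** Per pixel, `100 * (F − F0) / F0`, where `F0` is the mean over
   frames 9–11 — the three frames just before stimulation. A pixel with
   `F0 ≤ 0` is a hard error (it indicates a dead sensor region or a broken
   baseline window), reported with the offending pixel count.
2. **Frame-median correction.** The median pixel value of each frame is
   subtracted from every pixel of that frame. Because lamp fluctuations and
   photobleaching are multiplicative in `F`, they become approximately
   frame-constant additive terms in ΔF/F, and the median of a frame whose
   majority of pixels are non-responding estimates exactly that term. The
   median is taken over the *full frame*, not the mask: the correction
   precedes masking in the chain, and the out-of-structure pixels are
   precisely the ones most likely to carry only the artefact.
3. **Gaussian filtering.** Each frame is convolved with a normalised,
   truncated Gaussian: window 7×7 px for AL recordings, 3×3 px for LH/MB.
   The Gaussian σ is not part of the published recipe; we use
   `σ = (window − 1)/4` so that the window spans ±2σ (a common truncation
   convention), and expose `sigma` for sensitivity checks. Boundaries are
   handled by half-sample reflection, which avoids edge darkening inside
   masks that touch the image border and preserves the frame mean on
   interior-dominated images.
4. **Biphasic amplitude.** The GCaMP6f response is biphasic: a fast rise
   during the stimulus and a long undershoot below baseline. The per-pixel
   amplitude is the mean of frames 19–21 minus the mean of frames 49–51,
   capturing the full swing. The windows are configurable but default to
   the values above, which bracket the positive peak and the trough of the
   default kernel exactly.

Whether the amplitude windows should read the filtered or the unfiltered
ΔF/F movie is not determined by the published description; `glomap` applies
them to the filtered movie (extraction is the last stage), and the
configuration allows `window = 1` to disable smoothing entirely.

Masked reductions follow: response intensity is the arithmetic mean of the
amplitude map over in-mask pixels, and odor similarity is the pixel-wise
Euclidean distance between two maps over in-mask pixels. The distance is the
square root of the summed squared differences — the name "Euclidean" fixes
the formula — with a `squared = TRUE` variant provided for sensitivity
analyses. Per-bee distance matrices are averaged across bees entrywise
without normalising by mask area; this mirrors common practice but means
bees with larger masks contribute larger absolute distances (see
*Limitations*).

## The synthetic generator

The generator exists so that the pipeline can be validated by parameter
recovery without any real recordings. Its forward model is multiplicative:

```
F(x,y,t) = B(x,y) · (1−β)^(t−1) · (1 + A/100 · P(x,y) · k(t)) · (1+η_t) + ε
```

clipped to [0, 4095] and quantised to integers after noise, emulating a
12-bit camera. The multiplicative form is deliberate: ΔF/F then recovers
`A · P · k(t)` exactly in the noiseless limit, which makes the pipeline's
correctness provable rather than approximate.

* **Kernel `k(t)`** — piecewise exponential: zero before onset (frame 15),
  saturating rise to +1 at frame 20, decay into an undershoot reaching its
  depth (default −0.4 of the peak) at frame 50, then exponential recovery
  (τ = 40 frames). The defaults put the positive peak inside frames 19–21
  and the trough inside frames 49–51, i.e. exactly inside the measurement
  windows.
* **Patterns `P(x,y)`** — in AL mode, 23 Gaussian blobs (radius 2 px,
  truncated at 3 radii) on a hexagonal lattice inside an elliptical mask.
  The count of 23 is an arbitrary but plausible glomerular count at this
  magnification. Each blob carries fixed chemical tuning — a preferred
  carbon chain length laid out as a gradient across the field, a preferred
  oxygen moiety (C=O vs C−OH), and a subtype preference — and an odorant's
  blob weights are Gaussian tuning curves in those coordinates (widths 1.0
  carbons, 2.0, 2.5). Pattern distances therefore mirror chemical
  distances: C6 vs C9 patterns are farther apart than C6 vs C7, and chain
  length dominates, so clustering splits short from long chains first.
  Bee-level and presentation-level variability are multiplicative
  log-normal jitters on the blob weights (SD 0.3 and 0.05). LH/MB mode uses
  6 broad bumps (radius 8 px) to produce the smooth low-spatial-frequency
  fields of those neuropils. Patterns are unit Euclidean norm within the
  mask and zero outside it.
* **Amplitudes** — `A = a + b · log10(vapor pressure)`, default `a = 6`,
  `b = 2`, with `A = 0` for controls. `A` is expressed in *mask-mean
  readout units*: the injected pattern is normalised to mean 1 inside the
  mask, so `A` is the expected response intensity the pipeline reads out
  (times the kernel-window contrast ≈ 1.33). With the default vapor
  pressures this spans ≈ 2.7–8.2 % ΔF/F, the range typical of wide-field AL
  recordings. Vapor pressures (mmHg at 25 °C) are literature values
  compiled from standard physico-chemical references — they are constants
  of the analysis, not measurements, and are overridable per panel.
* **Nuisances** — per-frame bleach fraction β = 0.001 (≈10 % over a
  recording), frame-level illumination jitter SD 0.5 %, additive pixel
  noise SD 3 counts at baseline 1000 (0.3 % ΔF/F per pixel and frame). The
  published work reports no noise magnitudes or bleach rates; these are
  free parameters chosen once as plausible for a cooled, 4×4-binned CCD,
  and documented here rather than tuned per experiment.
* **Geometry** — the default simulation frame is 48×64 px. This is smaller
  than a typical binned sensor frame (120×160); it resolves the 23 blobs
  comfortably while keeping whole-cohort simulations (10 bees × 17 stimuli
  × 2 presentations, and 20-seed replications of those) fast enough to run
  routinely. The processing code is size-agnostic and handles full-size
  movies identically. The blob layout is also sized so that the union of
  blob supports covers well under half the frame — the regime in which the
  frame-median correction's "majority background" assumption holds, as it
  does in real recordings where strongly active glomeruli are a minority of
  the field.

The ground truth stores, per bee × stimulus × presentation, the injected
amplitude and the closed-form expected readout
`A · (mean over positive window of bleach-gain × kernel − mean over negative
window)`, so recovery checks compare measurement against an analytic
prediction, not against another run of the pipeline.

What the generator does **not** emulate: motion artefacts, optics/PSF blur,
indicator kinetics beyond the fixed biphasic template, glomerulus
segmentation structure finer than the blob layout, shot-noise scaling with
intensity, and any relationship between structures (AL and LH cohorts are
generated independently). Passing recovery tests therefore demonstrates the
*analysis* is correct under the stated signal model; it does not certify
performance on data violating that model.

## Statistics layer

* **RM-ANOVA** — one-way within-subject ANOVA (bees as subjects, odors as
  the within factor) via `aov` with a subject error stratum; df are the
  uncorrected `(k−1, (k−1)(n−1))`, matching the convention of reporting
  plain df for this design (for 11 bees × 17 stimuli: F on 16, 160 df). A
  Greenhouse–Geisser option exists but is off by default.
* **Dunnett post hoc** — many-to-one comparisons against the air control
  using the ANOVA error mean square and df; adjusted p-values from the
  equicorrelated (ρ = 1/2) multivariate-t distribution, evaluated
  numerically (`mvtnorm::pmvt`, quasi-Monte-Carlo with a fixed internal
  seed so results are reproducible). Two-sided, the conservative default
  since sidedness is not otherwise specified.
* **Wilcoxon matched-pairs** — zero differences dropped, average ranks for
  ties; exact null distribution of V for n ≤ 25 without ties, normal
  approximation with tie correction otherwise.
* **Friedman** — chi-square statistic on within-bee ranks with df = k−1.
  When a published subscripted statistic like "F₁₁" is encountered for this
  test, the subscript is read as these df: Friedman's statistic is
  chi-square distributed, and k−1 is its only df.
* **Mantel test** — Pearson r between upper triangles; p from joint
  row/column permutations of the second matrix with the +1 correction,
  default 9,999 permutations (consistent with p-value floors of 10⁻⁴ in
  this literature), sampled uniformly (the identity permutation is not
  excluded, as in the standard implementations); exhaustive enumeration
  replaces sampling when n! is small enough (default cap 8!).
* **Ward clustering** — `hclust` with `ward.D2` (the Ward criterion on
  Euclidean distances via the squared Lance–Williams update). Published
  analyses using R's `hclust` rarely state which Ward variant was used;
  `ward.D2` is the variant consistent with feeding unsquared Euclidean
  distances, and merge heights are checked for monotonicity.
* **Fisher z** — `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3))`,
  two-sided normal p, for comparing correlations from disjoint groups of
  bees.
* For comparisons where the t-vs-Wilcoxon choice is data-dependent (e.g.
  pheromone responses against a control), `paired_comparison()` runs both
  and reports which one a Shapiro–Wilk check at α = 0.05 recommends.

## Numerical and degenerate-input conventions

* Frame indexing is 1-based inclusive in every user-facing argument
  ("frames 9–11", "the 15th frame"); conversion to index vectors happens in
  exactly one internal helper.
* An exactly null stimulus effect reports F = 0 (guarding against
  floating-point dust from the sums of squares); a fully tied Friedman
  table reports statistic 0; a zero-variance difference vector, an
  all-zero-difference Wilcoxon input, |r| = 1 in the Fisher z test, and
  zero off-diagonal variance in a Mantel input are hard errors, not NaNs.
* Distance-matrix input is symmetrised by averaging when the largest
  asymmetry is ≤ 1e-8 (export rounding), rejected beyond that.
* The illumination correction is idempotent; applying it twice warns,
  because a double application indicates a mis-assembled pipeline.
* Movie I/O is exactly invertible: 16-bit TIFF storage of 12-bit counts
  with a JSON sidecar for metadata; masks are 0/255 PNG with intermediate
  gray values rejected.

## Problem sizes used by the validation suite

The test suite and `scripts/acceptance.R` use 48×64-px movies, cohorts of
2 bees (noiseless forward/inverse checks, every injected amplitude recovered
within 1 %) and 10 bees (noisy recovery and structure recovery), 20 seeded
cohort replicates for the structure-recovery rates, 250 null replicates for
RM-ANOVA calibration and 200 for Mantel calibration (499 permutations each).
These sizes were chosen so the whole validation runs comfortably on a
laptop-class machine; all of them are function arguments and scale up
directly.

## Known limitations

* **Median-correction bias.** Subtracting the frame median removes a small
  amount of signal whenever responding pixels are numerous enough and pixel
  noise broad enough that the median no longer sits on clean background
  (roughly 0.5 σ of the per-pixel ΔF/F noise, growing with the active
  fraction). This is a property of the published correction itself, not of
  this implementation; at the generator's default noise and support
  fraction it attenuates recovered amplitudes by ≈ 1 %. Analyses of
  structures whose activation covers most of the field (e.g. smooth LH
  fields) should expect a larger constant offset.
* **Mask-area dependence.** Euclidean distances grow with the number of
  in-mask pixels; cross-bee averaging does not normalise for mask size.
  Comparisons across structures should use the per-group mean matrices, as
  the groups are disjoint bees.
* The generator's noise is Gaussian and intensity-independent; real sCMOS/
  CCD noise is partly Poissonian.
* Supplementary spreadsheets from published studies vary in internal
  layout; XLSX import therefore requires an explicit layout mapping, and
  only long CSV is treated as a canonical interchange format.
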