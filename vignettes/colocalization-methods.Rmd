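---
title: "Quantifying punctate colocalization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying punctate colocalization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icaloc)
```

## The measurement problem

Dendritic RNA-binding proteins concentrate in micron-scale puncta, and
establishing that those puncta co-occur with ribosomes or mRNAs requires
statistics that are robust to the things that make visual merge images
misleading: unequal channel brightness, diffuse background, and the fact
that most dendritic pixels carry no signal at all. `icaloc` implements
the intensity-correlation-analysis family of measures over an ROI traced
along a dendrite, plus the particle-level summary ("what fraction of
protein clusters contain covarying signal?") and the geometric scoring
of cluster positions against traced spine perimeters.

No single coefficient is reliable alone — Pearson's Rr is driven by the
bright pixels, Mander's M1/M2 by signal support, and the ICQ by the
*sign* pattern of covariation — so the package always computes all four
on the same pixel set and reports them together.

## Pipeline and conventions

The fixed preprocessing order is: optional 16→8-bit conversion (linear
min–max rescale, round half up; a constant image maps to zero), then
background subtraction with threshold `mean + k_sd * SD` over a
user-drawn background polygon. Both steps are optional via arguments,
but their order is not configurable: conversion first, as the analysis
was historically run on 8-bit data.

Conventions fixed throughout the package:

* 0-based pixel coordinates, `x` = column, `y` = row; the pixel stored
  at matrix position `[r, c]` has center `(c-1, r-1)`.
* Pixel-in-polygon: pixel *center* inside the polygon, boundary
  inclusive (even–odd rule). This matches the semantics of manually
  traced perimeters, where a point on the drawn outline belongs to the
  structure.
* Polyline ROIs cover every pixel whose center lies within
  `line_width_px / 2` of the path; default width 1 px, configurable
  (the width used when tracing a dendrite is an acquisition-side choice
  the file format does not record).
* Background SD is the sample (n−1) standard deviation.
* Particle labeling is 8-connected (the particle-analysis convention);
  `min_area_px = 4` by default to suppress single-pixel noise. Both are
  recorded in every `cluster_set`.

## Coefficient definitions and edge rules

With paired ROI intensities \(A_i, B_i\) and ROI means
\(\bar A, \bar B\):

* \(R_r\): product-moment correlation. Undefined (an error, never a
  silent 0) for a constant channel.
* \(M_1 = \sum A_i [B_i > 0] / \sum A_i\), \(M_2\) symmetric. The
  overlap threshold is "> 0" on *background-subtracted* intensities:
  subtraction already defines signal support, so no further threshold is
  introduced. Undefined for an all-zero channel.
* \(\mathrm{ICQ} = \#\{i : (A_i-\bar A)(B_i-\bar B) > 0\}/N - 0.5\).
  Products exactly zero count in \(N\) but never in the numerator
  (strict reading of "positive product"). All ROI pixels enter \(N\),
  including 0,0 pixels — the ICQ denominator is "the total number of
  pixels"; the 0,0-pixel issue is handled only in the positive-PDM
  display mask, not in the quotient.
* PDM image: per-pixel \((A_i-\bar A)(B_i-\bar B)\) over the ROI, means
  taken over the ROI pixels only (the analysis is per dendritic
  segment, not per field). Its positive *mask* is restricted to pixels
  where **both** channels exceed their means: the below-mean
  "(−×−)" pixels are mostly 0,0 background and would otherwise flood
  the particle count.
* `% colocalized clusters`: a channel-A cluster counts as colocalized
  when its pixel set overlaps ≥ 1 pixel of a positive-PDM particle —
  pixel overlap rather than centroid containment, the closest reading
  of "clusters containing colocalized signal".

Spine scoring: a cluster is *at a spine* when its centroid falls inside
the traced total perimeter (centroid rule, chosen for determinism;
any-pixel overlap is easy to compute from a `cluster_set` if wanted);
inside the head polygon → `head`, inside total but outside head →
`base_neck`, inside a stubby spine (no traced head) → `all`. The `all`
category is reported as its own fraction, never double-counted into
head and base–neck — published head + base–neck fractions that do not
sum to 100% imply exactly such a residual category. Overlapping
perimeters are flagged with a warning and resolved to the nearest
polygon centroid. The geometry is traced from the membrane channel
alone, so the scoring functions never read the cluster channel's
intensities — the blinding is structural.

## Statistics

* `bootstrap_ci()`: percentile bootstrap of the mean over per-cell
  observations, resampled with `boot::boot`. Percentile rather than BCa:
  it is the simplest defensible choice, its bounds provably stay inside
  the observed range, and the method is isolated behind one function if
  a different interval is ever wanted. Default 10,000 resamples with a
  logged seed.
* `per_culture_se()`: observations are averaged within each independent
  culture first; SE = SD(culture means)/√k with (n−1) normalization;
  a single culture yields `NA` ("N/A" in tables).
* `summarize_coefficients()`: dendrites are aggregated to per-cell means
  before the bootstrap (at least two dendrites per cell are typically
  traced); bootstrapping over dendrites instead would understate
  between-cell variance. The per-cell aggregation is the default; users
  can pass per-dendrite rows with a dendrite-level id to get the
  alternative.
* `densitometry_normalize()`: band/loading-control ratio per timepoint,
  expressed as a percentage of the earliest timepoint (reference = 100
  exactly).

## The synthetic-scene generator

`generate_punctate_pair()` emulates the imaging regime the statistics
are used in: two channels of diffraction-limited puncta along a
dendrite path, rendered as isotropic 2-D Gaussians (spot and PSF sigmas
add in quadrature — the standard diffraction-limited approximation, and
analytically checkable), a constant background, optional Poisson photon
noise, Gaussian read noise, and round-half-up integer quantization
(matching integer camera output). Defaults and what they emulate:

* `pixel_size_um = 0.11`: typical 60×/1.25 NA sampling. Source images
  rarely state calibration, so every µm-based default is a convention,
  and all are overridable in `scene_params()`.
* `cluster_density_per_um = 0.67`: the observed dendritic cluster
  density for this class of RNA-binding protein (≈ 0.67 ± 0.25
  clusters/µm).
* `coloc_fraction = 0.7`: roughly the observed fraction of protein
  clusters containing ribosomal signal.
* Co-positioned partners are offset by a uniform draw from a 1 px disc
  (a sub-resolution offset); amplitudes are normal, truncated at 1.
* Ground truth is kept exact by construction: channel-A centers keep a
  hard-core separation of `2 * min_separation_px` (the count stays
  Poisson; positions are redrawn on conflict) and non-paired B clusters
  stay ≥ `min_separation_px` from every A center, so the fraction of A
  clusters with a B cluster within 2 px equals `coloc_fraction`
  exactly.

`generate_spine_scenario()` plants cluster centroids with known
categories in a synthetic traced geometry (straight shaft, alternating
rectangular spine perimeters with head polygons at the tip; stubby
spines shorter and headless), spanning the realistic tracing regime of
30–80 spines over 30–70 µm.

What the generator deliberately does **not** emulate: 3-D stacks,
spectral bleed-through, chromatic offset, spatially varying background,
cluster mobility, and irregular hand-traced spine outlines. Passing the
recovery tests therefore shows the *estimators* are correct on images
matching their assumptions — it does not certify performance on real
tissue, where background structure and tracing variability add error
the synthetic scenes do not contain.

## Validation regimes and problem sizes

Two scene configurations back the test suite, chosen for what each
quantity measures:

* **Sparse, well-separated, high SNR** (0.12 clusters/µm,
  `min_separation_px = 5`, amplitude 180 on background 5, 64×448 px):
  used for parameter recovery of `% colocalized clusters` and for
  cluster-detection ground truth. At realistic density (0.67/µm),
  independent spots along the same path overlap by chance so often that
  the `f = 0` estimate reflects scene crowding rather than estimator
  error; the sparse regime isolates the estimator. Across
  `f ∈ {0, 0.25, 0.5, 0.75, 1}` (10 seeds each) the mean estimate is
  monotone in `f` and within ±10 points of `100 f`.
* **Default density** (the realistic regime): used for the monotone
  response of Rr and ICQ to `f` through the full workflow
  (background-subtracted line ROI). Note that on *sparse*
  background-subtracted ROIs the ICQ sits high regardless of `f`,
  because the many 0,0 pixels below both means contribute positive
  products — a known property of the quotient, and the reason the
  positive-PDM mask excludes below-mean pixels.

Other numerical choices: coefficient implementations are fuzz-checked
against brute-force references to 1e-12 on ≤ 64-pixel inputs; the ICQ
null (independent uniform noise, 50 pairs of 256×256 channels) averages
to 0 within ±0.01; bootstrap coverage is checked with 500 replicate
datasets of n = 38 cells (999 resamples per interval — enough for a
stable percentile at the 2.5% tails while keeping the simulation
inexpensive; the user-facing default stays at 10,000), expecting 93–97%
empirical coverage for the nominal 95% interval. Scene sizes in the
suite (≈ 64–96 px tall, ≈ 450–512 px wide) were chosen as the smallest
fields that hold a 44–55 µm dendritic segment at 0.11 µm/px.

## Known limitations

* Costes randomization and thresholded Mander's (tM1/tM2) are out of
  scope, as are rolling-ball background subtraction and ImageJ `.roi`
  binary parsing (the package defines its own plain-text ROI schema).
* Touching clusters are not watershed-split; at realistic densities
  merged particles bias cluster counts low.
* The ICQ's sensitivity to the zero-inflated background (above) means
  per-ROI ICQ values from sparse dendrites should be compared only
  across ROIs with similar signal occupancy.
* Exact thresholds used historically for binarizing PDM images are not
  standardized; `positive_pdm_particles()` defaults to the positive
  mask itself (threshold at 0) and exposes Otsu as the alternative, so
  sensitivity to this choice can be reported rather than guessed.
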