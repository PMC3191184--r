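# icaloc

Intensity-correlation colocalization analysis for punctate fluorescence
images of dendrites.

RNA-binding proteins such as the Fragile-X-related proteins form discrete
clusters (puncta) along dendrites, and a central experimental question is
whether those clusters co-occur with ribosomes, mRNAs or synaptic markers
imaged in a second channel. Visual overlap is subjective and sensitive to
channel brightness, so the field quantifies colocalization with
pixel-intensity statistics computed over a region of interest (ROI) traced
along the dendrite. `icaloc` implements that workflow end to end for
two-channel micrographs, together with a ground-truthed synthetic-image
generator so every stage can be validated without microscopy data. It is
aimed at cell biologists and image analysts quantifying punctate
colocalization, and at method developers who need a testable reference
implementation.

## The statistics

For paired pixel intensities \(A_i, B_i\) (\(i = 1..N\)) under the ROI,
with means \(\bar A, \bar B\):

* **Pearson's coefficient** \(R_r = \frac{\sum (A_i-\bar A)(B_i-\bar B)}
  {\sqrt{\sum (A_i-\bar A)^2 \sum (B_i-\bar B)^2}}\); ranges −1 to 1,
  values ≥ 0.5 conventionally read as colocalization.
* **Mander's coefficients** \(M_1 = \sum_i A_i [B_i > 0] / \sum_i A_i\)
  and symmetrically \(M_2\); the fraction of one channel's intensity at
  pixels where the other has signal (intensities are
  background-subtracted, so 0 means "no signal"); range 0 to 1.
* **ICQ**, the intensity correlation quotient: each pixel's *product of
  the differences from the mean* is \(\mathrm{PDM}_i = (A_i-\bar A)
  (B_i-\bar B)\); the ICQ is the fraction of pixels with
  \(\mathrm{PDM}_i > 0\) minus 0.5. It ranges from −0.5 (segregated
  staining) through ≈ 0 (random) to +0.5 (perfect covariation).
* **PDM image and % colocalized clusters**: the positive-PDM pixels
  (restricted to pixels above both channel means) are binarized and
  counted as particles (8-connected, size-filtered); a protein cluster
  "contains colocalized signal" when its pixel set overlaps a
  positive-PDM particle, and the summary statistic is
  100 × colocalized / total clusters.

Upstream of the coefficients: 16→8-bit conversion (linear min–max) and
background subtraction at threshold `mean + k·SD` of a user-drawn
background ROI (k = 2 for immunostaining, 0.5 for in situ
hybridization). Downstream: cluster centroids are scored against traced
dendritic-spine perimeter polygons (shaft / spine head / base–neck /
stubby-"all"), and results are summarized with percentile-bootstrap
confidence intervals over cells and per-culture standard errors.

## Worked example

```r
library(icaloc)

## a synthetic two-channel scene: 70% of channel-A clusters carry a
## co-positioned channel-B cluster
params <- scene_params(coloc_fraction = 0.7, seed = 42)
scene  <- generate_punctate_pair(params)
scene
#> <synthetic_scene> 96x512 px, 44 A-clusters, 37 B-clusters, 31 pairs (f = 0.7)

out <- analyze_scene(scene, k_sd = 2)
out$result
#> <coloc_result> Rr = 0.641 [colocalized], M1 = 0.702, M2 = 0.849, ICQ = 0.412 (N = 9140 px)
out$percent_colocalized
#> [1] 77.14286
```

The four coefficients agree: the channels are substantially colocalized
(Rr ≥ 0.5 triggers the conventional "colocalized" flag; ICQ 0.41 is near
its +0.5 ceiling because the background-subtracted dendrite is dominated
by covarying puncta), and the particle-based estimate — 77% of the 35
detected channel-A clusters overlap a positive-PDM particle — recovers
the planted 70% fraction within sampling error.

Spine scoring against a planted geometry:

```r
sp <- generate_spine_scenario(40, 50, stubby_fraction = 0.2,
  cluster_plan = c(shaft = 20, head = 2, base_neck = 7, all = 1), seed = 42)
summarize_spine_localization(sp$truth_cluster_centroids, sp$geometry)
#> <spine_localization_summary> 30 clusters over 40 spines
#>   density: 0.600 clusters/um; spines with cluster: 20%
#>   shaft 66.7% / spine 33.3%; within spines: head 20, base/neck 70, all 10
```

Bootstrap CI over per-cell measurements:

```r
bootstrap_ci(c(61, 75, 68, 72, 80, 66) / 100, n_reps = 10000, seed = 1)
#> <bootstrap_ci> 0.7033 (95% CI 0.6567-0.7533; n = 6, 10000 resamples)
```

See `vignettes/colocalization-methods.Rmd` for the model, parameter and
design documentation.

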