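---
title: "Striatal DAT SPECT texture analysis: model, phantom and statistical battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Striatal DAT SPECT texture analysis: model, phantom and statistical battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dopamine-transporter (DAT) SPECT images the density of presynaptic
dopaminergic terminals in the striatum. In Parkinson's disease (PD) these
terminals degenerate — earlier and more strongly in the putamen than in the
caudate — and the loss within each structure is spatially uneven, with
pronounced rostrocaudal gradients. Conventional quantification reduces each
region of interest (ROI) to its mean tracer concentration divided by a
nonspecific reference region (occipital cortex), a distribution-volume-ratio
(DVR)-like number. That single number discards all within-ROI spatial
information, and within a patient population it correlates poorly with
clinical severity.

`striatex` implements the alternative: characterize the *spatial pattern* of
uptake inside each ROI with Haralick texture features computed from a masked
three-dimensional gray-level co-occurrence matrix (GLCM), and test whether
those features correlate with motor severity (UPDRS-III), disease duration
(from diagnosis and from first symptom) and cognition (MoCA), under proper
multiple-testing control and with a stepwise multivariate model that includes
age.

## The texture model

For one ROI the pipeline is:

1. **Quantization.** In-mask intensities are linearly binned into `Q = 32`
   levels between the in-mask minimum and maximum:
   `level(x) = min(Q, floor((v(x) - vmin)/(vmax - vmin) * Q) + 1)`.
   Min–max binning makes every downstream feature exactly invariant under
   positive affine intensity transforms of the image, so texture carries
   information *beyond* mean uptake by construction. A constant ROI maps to
   level 1 everywhere.
2. **Co-occurrence.** The 26-voxel neighborhood contains 13 direction pairs
   up to central symmetry. For each of the 13 offsets at distance 1 voxel,
   ordered level pairs are counted over voxel pairs with *both* endpoints
   in-mask; each count matrix is symmetrized by adding its transpose, the 13
   matrices are averaged, and the average is normalized to a joint
   probability matrix `p(i,j)`.
3. **Features.** Thirteen scalar statistics of `p`: energy, entropy (base
   2), correlation, contrast, variance, sum mean, agreement (Cohen's kappa
   of the diagonal), cluster shade, cluster tendency (prominence, exponent
   4), homogeneity (inverse difference, `1/(1+|i-j|)`), max probability,
   inverse variance and dissimilarity. Exact formulas are in
   `?haralick_features`.

Several feature variants circulate in the radiomics literature. Where the
choice is genuinely contested we fixed a default and exposed a switch:
homogeneity uses the inverse-difference form (squared-difference available
via `homogeneity_form`), cluster tendency uses exponent 4
(`cluster_tendency_exponent = 2` available), variance is centered on the
row-marginal mean, and quantization is per-ROI min–max. Raw counts are
averaged across directions before the single normalization. `Q` and the
offset distance are recorded in every output because inverse variance in
particular is sensitive to them.

Degenerate inputs are handled explicitly: a single-voxel ROI has no voxel
pair in any direction and produces an error that cohort runs convert to
all-NA features (flagged, and excluded by complete-case analysis); a
constant ROI gives the closed-form feature values (energy 1, entropy 0,
contrast 0, homogeneity 1, correlation 0 by the zero-variance rule,
agreement 1 by the chance-agreement rule).

## Conventional quantification

`mean_roi_uptake()` and `normalize_to_reference()` produce the DVR-like
ratio (the plain ratio, not ratio − 1). Because PD affects the two
hemispheres asymmetrically, analyses separate the more and less affected
side: the more affected side is operationalized as the hemisphere with the
*lower* normalized putamen mean (ties to left), and the same label is
applied to the caudate. The laterality index `|R-L| / ((R+L)/2)` summarizes
asymmetry; normalization cancels in the ratio, so raw and normalized means
give the identical index.

## The synthetic phantom cohort

The study design this package validates against used 141 subjects (85 PD,
56 healthy controls) from an access-controlled database; no images can ship
with the package. The `phantom` module therefore generates a synthetic
cohort with the statistical structure the analysis assumes, so every
downstream stage is testable end to end.

**Geometry.** A 64 × 64 × 48 grid at 2 mm isotropic spacing carries two
mirrored ellipsoid pairs — caudate ≈ 1.4 cm³, putamen ≈ 4 cm³ — placed
symmetrically about the mid-sagittal plane, plus a posterior occipital slab
as reference. Masks are exact mirror images, so healthy phantoms are
left-right symmetric by construction.

**Uptake model.** Each subject has a latent severity `s` (0 for controls,
Uniform(0.1, 1) for patients) and a log-normal striatal uptake scale (12%
SD) representing between-subject biological variability. Striatal intensity
is

```
u(x) = scale * side * [ B (1 - L_r k_r s)  +  A_r (1 - e_side k_r s) ramp(x) ] ,
```

where `B = 100` is healthy specific uptake over a background/reference level
of 50; `k_r` is the region's severity response (putamen 1.5 - capped at
effective severity 1 - caudate 1); `L_r` the mean-loss depth (putamen 0.5,
caudate 0.05); `side = 1 - 0.3 s` on the more affected putamen and 1
elsewhere; and `ramp(x)` is a fixed zero-mean rostrocaudal gradient of
amplitude `A_r` (2.5%/mm of `B` across each structure's length) that
*erodes* with severity (`e = 0.85` on the more affected side, 0.6 on the
less). Gaussian voxel noise (SD 15) is added and the volume smoothed with a
6 mm FWHM isotropic Gaussian, the standard post-reconstruction filter.

**Why an eroding gradient rather than a growing one?** Min–max quantization
stretches whatever intensity variation exists in the ROI to the full gray
scale, so texture features respond to the *ratio* of structured variation to
the noise floor, not to absolute amplitude. A healthy structure carries a
strong intrinsic rostrocaudal gradient; as severity erases that structured
contrast while acquisition noise stays constant, the quantized ROI becomes
relatively noisier — entropy, contrast and dissimilarity rise, homogeneity
falls. This reproduces the empirically observed direction of the
texture-severity correlations. The ramp is zero-mean, so caudate *mean*
uptake stays essentially flat in severity (only the weak 5% mean-loss term
and the 12% biological scatter move it), reproducing the null conventional
caudate result; the putamen's deep mean loss reproduces the strong negative
uptake-severity relation that is only visible when controls anchor the
healthy end of the range.

**Clinical scores.** UPDRS-III = 5 + 45 s + N(0,6) (controls |N(1,1)|),
disease duration from diagnosis = 60 s + N(0,8) months, duration from
symptoms adds |N(12,6)| months, MoCA = 28 − 6 s + N(0,1.5) clipped to
[0,30], age ~ N(61,9) independent of severity. These coefficients are
invented calibration — the source study reports no generative model — chosen
once so that severity explains most score variance at n = 85 (r(severity,
UPDRS-III) ≈ 0.9), giving the pipeline a recoverable signal. Disease
duration scales are likewise invented and flagged as such.

**What the phantom does not emulate.** Ellipsoids, not anatomy; additive
Gaussian noise on reconstructed images, not Poisson projection noise,
scatter or attenuation; a single smooth gradient, not patchy dorsoventral
loss; the affected side fixed to the left (a `randomize_side` flag exists).
Passing tests on the phantom therefore demonstrate that the *pipeline*
recovers planted structure of realistic size and noise — not that texture
features are validated biomarkers on real images.

## Statistical battery

Per clinical measure, the 14-metric family (conventional normalized uptake
plus 13 texture features) is Pearson-correlated against the measure
(two-sided p from the t distribution on n − 2 df; complete cases per
measure). The Benjamini–Hochberg step-up procedure is applied across the 14
tests at α = 0.05: order the p-values, find the largest k with
`P(k) ≤ (k/m) α`, declare the k smallest significant. The FDR family is per
clinical measure, matching the per-column structure of the reported
univariate table; pooling across measures is the stricter alternative and
can be applied by calling `bh_fdr()` on the stacked p-values.

The multivariate step fits stepwise ordinary least squares with intercept:
forward entry of the smallest-partial-p candidate below 0.10, backward
removal of the largest-partial-p predictor above 0.05, alternating; age is
always a candidate. Entry order, tie-breaking (smaller p, then name) and
the iteration cap are fixed for determinism. When a candidate's partial p
sits between the two thresholds it can cycle in and out; selection then
stops at the post-removal model (so every retained predictor always
satisfies the removal threshold) and the result is marked `cycled`. This
recurrence rule is the standard resolution of the enter/remove threshold
gap; note that with ~10 null candidates the 0.10/0.05 thresholds admit at
least one spurious predictor in roughly a third of runs — an inherent
property of p-value-driven stepwise selection at these levels, visible in
the package's own recovery simulations.

## Numerical choices

* Smoothing: separable discrete Gaussian, `sigma = FWHM / (2 sqrt(2 ln 2))`
  converted per axis to voxels; kernel radius 4σ; zero-flux (renormalized)
  boundary so constants are preserved exactly.
* Resampling: trilinear interpolation under a pull-back rigid map
  (`x_mov = R x_tgt + t`), out-of-field voxels 0. Masks are never
  interpolated; analysis assumes masks already live on the analysis grid.
* Quantization boundaries: the in-mask maximum is clamped to level Q.
* GLCM: counts accumulate in doubles; normalization is a single division,
  so row/column sums are symmetric to machine precision.
* Problem sizes in the shipped tests and acceptance script: the full
  141-subject cohort at 64 × 64 × 48 (the study's group sizes), 50 random
  5³ volumes and 200 random 8 × 8 matrices for oracle comparisons, 100
  seeds for recovery and permutation runs — sizes at which every check is
  stable yet the whole suite completes in minutes on one core.

## Known limitations

* The phantom's clinical-score generator is a calibration device, not an
  epidemiological model; effect sizes on real data will differ.
* Texture features from ~170-voxel caudate ROIs at 2 mm are high-variance;
  the pipeline relies on cohort-level correlation, not per-subject
  precision.
* Registration estimation, attenuation correction, partial-volume
  correction and kinetic modeling are out of scope; masks and co-registered
  volumes are inputs.
* Stepwise p-value selection is implemented as specified for fidelity, with
  its known false-entry behaviour; penalized or information-criterion
  selection would be the modern alternative.
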