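# striatex

Texture analysis of striatal dopamine-transporter (DAT) SPECT uptake, for
researchers studying imaging biomarkers of Parkinson's disease (PD)
severity and progression.

## The problem and the method

DAT SPECT images dopaminergic terminal density in the striatum.
Conventional quantification reduces each region of interest (ROI) — left
and right caudate and putamen — to its mean tracer concentration divided by
an occipital reference, a distribution-volume-ratio-like value
`DVR = mean(ROI) / mean(reference)`. That number separates patients from
controls, but within a patient population it correlates poorly with
clinical severity: dopaminergic loss is spatially uneven (strong
rostrocaudal gradients), and the mean discards exactly that structure.

`striatex` quantifies the within-ROI spatial pattern instead. For each
masked region it builds a 3D gray-level co-occurrence matrix (GLCM): in-mask
intensities are min–max quantized to Q = 32 levels, ordered level pairs are
counted over the 13 unit-neighborhood directions (distance 1 voxel, both
endpoints in-mask), symmetrized, averaged across directions and normalized
to a joint probability matrix p(i, j). Thirteen Haralick statistics of p —
energy, entropy, correlation, contrast, variance, sum mean, agreement
(Cohen's kappa), cluster shade, cluster tendency, homogeneity, max
probability, inverse variance, dissimilarity — summarize uptake
heterogeneity. Because quantization is per-ROI min–max, every feature is
invariant under positive affine intensity transforms: texture carries
information beyond mean uptake by construction.

The statistical battery mirrors the standard severity-correlation design:
per clinical measure (UPDRS-III motor score, disease duration from
diagnosis and from first symptom, MoCA cognition), Pearson correlations of
the 14-metric family (conventional uptake + 13 texture features), the
Benjamini–Hochberg step-up FDR across the family at α = 0.05
(`k* = max{k : P(k) ≤ (k/m) α}`), and stepwise multivariate linear
regression (entry p < 0.10, removal p > 0.05) with age as covariate.
Analyses separate the more and less affected hemisphere, operationalized as
the side with the lower normalized putamen mean; the laterality index
`|R−L|/((R+L)/2)` summarizes asymmetry.

Because the clinical image data this design targets are access-controlled,
the package ships a synthetic phantom cohort generator (85 patients + 56
controls by default) producing NIfTI-compatible volumes with mirrored
striatal ellipsoids, severity-linked uptake structure, additive noise and
6 mm FWHM post-reconstruction smoothing, plus clinical scores tied to a
latent severity — so the whole pipeline is testable end to end with known
ground truth. See the methods vignette
(`vignettes/striatal-texture-methods.Rmd`) for the generative model and its
design rationale.

## Worked example

The analysis is organised as numbered drivers over the package functions:

```sh
Rscript analysis/01_simulate_cohort.R    # clinical table        -> results/
Rscript analysis/02_extract_features.R   # image metrics         -> results/
Rscript analysis/03_associations.R       # correlation battery   -> results/
Rscript analysis/04_figures.R            # scatter plots         -> results/figures/
```

With the default seed, `03_associations.R` prints:

```
Conventional benchmark (normalized mean putamen uptake vs UPDRS-III):
  HC+PD: r = -0.92, p = 1.2e-59 (n = 141)
  PD only: r = -0.84, p = 1.4e-23 (n = 85)
  Caudate PD only: r = -0.15, p = 0.17 -> no correlation

More-affected caudate, PD only (full table in results/report.txt):
  updrs3           FDR-significant: entropy, correlation, contrast, variance,
                   homogeneity, inverse_variance, dissimilarity
  ...
```

Reading: mean putamen uptake correlates strongly with motor severity when
healthy controls anchor the upper end of the range, but the caudate mean
carries no severity signal within patients — whereas caudate *texture*
does: entropy, contrast and dissimilarity rise with severity and
homogeneity falls (positive/negative r, all surviving FDR), because
progressive loss erodes the structured uptake gradient relative to the
constant noise floor. The same computation in library form:

```r
library(striatex)
params   <- phantom_params(seed = 1)
clinical <- simulate_clinical(params, n_pd = 85, n_hc = 56)
features <- cohort_features(params, clinical = clinical)
res <- analyze_measure(features, clinical, "updrs3",
                       region = "caudate", side = "more", subset = "PD")
res[res$fdr_significant %in% TRUE, c("metric", "r", "p")]
```

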