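---
title: "Multiscale mammographic texture features and risk scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale mammographic texture features and risk scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mammotex)
```

This vignette is the package's own account of its methods: the
segmentation and feature models, the statistical selection procedure, the
synthetic-data design, the numerical choices, and what the package's
validation does and does not demonstrate.

## The problem

Percent mammographic density (PMD) — the fraction of the breast area
occupied by radiologically dense tissue — is a strong breast cancer risk
factor, but it is a single number. The hypothesis behind this package is
that the *texture* of the parenchymal pattern carries risk information
beyond the dense-area fraction. The package therefore (i) delineates the
breast, (ii) computes a fixed 470-entry bank of texture descriptors over
the delineated region, (iii) selects a stable subset by bootstrap stepwise
logistic regression on a training half of a matched case-control cohort,
and (iv) scores the validation half on a 0–100 scale, reporting the AUC
and the odds ratio per standard deviation (OR/SD) of the score, raw and
adjusted for epidemiologic covariates.

## Breast delineation

Four deterministic steps (`delineate_breast()`):

1. *Border-stripe removal.* Scanner artifacts appear as saturated stripes
   along image borders. Any complete row/column within 5% of an edge in
   which more than 80% of pixels have gray `>= 250` is zeroed
   (`margin_frac = 0.05`, `bright_frac = 0.8`; these are pinned for
   reproducibility and configurable).
2. *Otsu thresholding.* The threshold `t in 0..255` minimizing the
   within-class variance of `{<= t}` vs `{> t}`; foreground is `> t`.
   Classical Otsu is implemented; a constant image is an error. Ties are
   broken toward the smallest `t`. The test suite checks the result
   against exhaustive search over all 256 candidates.
3. *Morphological opening* with the discrete disk
   `{(i,j): i^2 + j^2 <= r^2}`, default radius 5 px (1 mm at the default
   0.02 cm/px spacing) — large enough to delete label edges and speckle,
   small enough not to blunt the breast contour. Pixels beyond the image
   border count as background. Opening can only remove foreground; this
   is asserted on every call.
4. *Largest connected component* under 8-connectivity (standard for blob
   extraction); everything else — film labels, residual artifacts — is
   erased. Ties in area go to the component appearing first in
   column-major scan order.

Manually corrected masks can be supplied via `read_mask_png()` with
provenance `"corrected"`; the package deliberately contains no interactive
editor.

## The feature bank

All texture features are computed strictly inside the mask; pixel pairs,
runs and regions never cross the mask boundary, and the wavelet crop
replaces off-mask pixels with the mean interior gray value, so no feature
can depend on the background. Group totals: 76 moment-based + 86
form-based + 130 statistical + 108 structural + 70 spectral = 470.

**Quantization.** All second-order statistics use 16 gray categories,
`level = floor(gray/16)` — the same binning as the histogram features. A
uniform choice keeps the coarse-scale co-occurrence matrices well
populated.

**Multiscale rule.** The GLCM, SDH, SGF and run-length families are also
computed at 0.5 cm and 1.0 cm resolution: non-overlapping square blocks
(the generator guarantees an integer number of pixels per block) are
reduced to the mean gray value of their masked pixels; blocks under 50%
mask coverage are dropped; block means are re-quantized to 16 levels.
Block means — not subsampling — implement the "coarser resolution"
semantics and stay mask-aware.

**Statistical group (130).** 16 histogram frequencies (full resolution
only); 13 Haralick features of the GLCM and 25 SDH features at each of
the three scales. Displacements are pinned to distance 1 in the four
directions 0°, 45°, 90°, 135°, pooled into a single symmetric matrix per
scale (both pair orders counted). Logs are base 2 with `0·log 0 = 0`.
Two conventions are worth stating: sum variance is centred on the sum
average (the use of sum entropy as the centring constant in older
transcriptions is a known typo), and difference variance is the variance
of the folded `|i−j|` histogram. The 25 SDH features are 12 direct
statistics (mean, variance, skewness, kurtosis, energy, entropy of the
sum and of the difference histogram) plus 13 estimates of the Haralick
features computable from the two histograms; where an exact identity
exists (contrast, sum average/variance/entropy, difference
variance/entropy) the estimate equals the GLCM value, and the two
information measures use the joint reconstructed under the sum/difference
independence assumption. The resulting near-duplicates are intentional —
they are exactly what the `rho > 0.98` preselection later removes.

**Moment group (76).** The four gray-value central moments use population
formulas with skewness and kurtosis defined as 0 for a constant region.
The 16 normalized spatial central moments keep the three constants
`eta00 = 1`, `eta10 = eta01 = 0` so the printed count holds; they are
removed downstream by the zero-variance rule. Zernike moments use
maximum order 12 (the unique order giving 49 index pairs) on the smallest
centroid-centred disk containing the whole mask — this mapping makes a
disk-shaped region exactly fill the unit disk, which is what makes the
orthogonality sanity check (a uniform disk loads only `|A00|`) meaningful.
Magnitudes only are emitted (rotation invariance).

**Form group (86).** Shape scalars use a √2-weighted chain code for the
perimeter; this overestimates smooth contours by ≈ 5%, so the compactness
of a digital disk is ≈ 1.10 rather than 1 — the tests encode that
discretization bias rather than pretend it away. The maximal contour
distance is computed on the convex hull. The six radial-length features
and three Fourier-descriptor band energies (`|k|` in 2–5, 6–16, 17–64 of
the 128-point resampled boundary, DC dropped, scale normalized by the
fundamental) are the unique 6 + 3 split consistent with the printed group
total given the five scalars and 72 binary moments. The bounding box for
rectangularity is axis-aligned.

**Structural group (108).** SGF thresholds the quantized ROI at
`alpha = 1..15`; for each stack and its within-mask complement the number
of 8-connected regions and the area-weighted mean irregularity are
aggregated over `alpha` by maximum, average, distribution mean and
distribution SD. Irregularity is pinned to
`sqrt(pi)·maxdist_centroid/sqrt(A) − 1`, clamped at 0 — exactly 0 for a
continuous disk and computable in one pass per region. Run-length
features are Galloway's five statistics emitted per direction
(4 × 5 = 20); runs break at the mask boundary.

**Spectral group (70).** A separable periodized 3-level pyramid for seven
pinned bases (haar; db2, db3, db4; sym4, sym5; bior2.2 — one 2-tap, three
4–8-tap orthogonal, two least-asymmetric, one biorthogonal), 10 subband
energies each (mean squared coefficient). For the orthogonal bases the
transform conserves the total sum of squares exactly when the crop
dimensions are divisible by 8; other crops are edge-padded first. The
filters are the standard published coefficients; the decomposition is
implemented in the package because no wavelet library is among its
dependencies.

## The selection and scoring pipeline

* **Matched split.** Matched sets — never individuals — are randomized
  50/50 (an odd set count favours training), so the matching survives the
  split intact.
* **Preselection.** Zero-variance columns are dropped, then a later
  catalog column is dropped when its |Spearman| correlation with a
  retained earlier column exceeds 0.98. Preselection and all model
  selection use the training half only.
* **Standardization.** Training columns are centred and scaled before any
  logistic fit. AIC-based selection is invariant to affine rescaling, so
  this is purely a numerical-conditioning choice.
* **Bootstrap stepwise selection.** 500 resamples at study scale (the
  configuration accepts smaller values — results then carry more Monte
  Carlo noise; the package's own validation uses B = 50). Each resample
  draws subjects with replacement (ignoring matched sets, which the
  resampling description does not preserve) and runs a backward
  elimination that repeatedly removes the feature whose removal most
  reduces the AIC. Fits use iteratively reweighted least squares with
  step-halving (monotone log-likelihood), a tiny ridge stabilizer on the
  normal equations, and a likelihood-plateau stop so quasi-separated
  resamples terminate with finite, comparable AICs.
* **One-step candidate scoring.** Evaluating every deletion by a fully
  converged refit is the exact search (`screen_k = Inf`) and what the
  oracle tests verify. At bootstrap scale the package scores all
  candidates per step with a one-step Newton downdate of the shared
  information inverse, evaluates the actual likelihood at that feasible
  point (which can only *overstate* the candidate AIC), and confirms the
  best `screen_k = 3` candidates by converged refits — so every accepted
  removal strictly reduces the true AIC, at a small risk of stopping one
  step early. On test problems the approximate and exact searches select
  near-identical models at roughly 1% of the cost.
* **Finalization.** Features retained in more than 70% of resamples are
  selected. Because strongly correlated features (|rho| > 0.9 on
  training data) substitute for one another across resamples and split
  their votes, each correlated cluster that is *jointly* retained in more
  than 90% of resamples additionally contributes its highest-frequency
  member. Finally every |rho| > 0.9 pair among the kept features loses
  its lower-frequency member, so a cluster is represented at most once.
  The substitution rule is the package's resolution of a genuine
  ambiguity in how a correlated pair's ">90%" qualifier should be read;
  without it, a redundant family of strong features can vanish entirely
  at small cohort sizes while weak but unreplicated noise survives —
  observed directly on synthetic cohorts of 600 subjects.
* **Two stages.** Selection runs first within each of the five feature
  groups, then once more starting from the union of the per-group
  selections; the final set is a subset of that union by construction.
  An empty union is an error at the operation level; the end-to-end
  runner treats it as an intercept-only model (constant score 50, AUC
  0.5), which is the correct degenerate behaviour for a null cohort.
* **Scoring and evaluation.** The final logistic model is fitted on
  training data; validation subjects receive
  `100·plogis(intercept + sum(beta·x))`. The AUC is the Mann–Whitney
  concordance with ties counted ½. OR/SD divides the score by its
  validation SD before the logistic fit; confidence intervals are Wald
  (the conventional symmetric-on-log-scale choice). Adjusted models add
  age + BMI; age + BMI + parity (two indicators for the classes 0, 1–2,
  ≥3) + family history + age at first term pregnancy; and optionally the
  PMD surrogate. Non-convergence is reported per row, never hidden.

## The synthetic cohort

The generator emulates the *statistical* structure the analysis assumes,
not mammographic anatomy. Defaults mirror a 2:1 age-matched case-control
study population: per-arm age (57.5 ± 10.8 vs 57.3 ± 10.6 years),
BMI (26.1 ± 5.0 vs 24.6 ± 3.8 kg/m²), parity class probabilities
(15.5/62.7/21.9% vs 14.3/53.4/32.3%), family history (14.4% vs 19.7%),
age at first term pregnancy (25.2 ± 4.6 vs 25.6 ± 4.4 years) and ever-HRT
(29.8% vs 57.5%). Labels come first (case-control sampling); covariates
are drawn per arm; no causal model connects them. Matching is by
construction: each control's `match_ratio` cases draw their ages from the
case-arm normal truncated to the control's age decade (an alternative
`matching = "independent"` mode draws both arms i.i.d. and errors,
naming the decile, when matching is infeasible — the documented failure
mode).

Images are half-elliptical breasts attached to the left edge (randomized
semi-axes, low-order harmonic boundary perturbation), a smooth Gaussian
random "fatty" field, dense blobs grown to the configured area fraction
(the recorded `pmd_true` equals the achieved fraction to within one
pixel), optional saturated border stripes (top/bottom/right) and a bright
film-label blob disjoint from the breast. The default pixel spacing is
0.02 cm/px so the 0.5/1.0 cm blocks are 25/50 px.

**The planted effect.** `texture_effect = delta` shifts two per-subject
texture parameters by `delta` within-arm standard deviations: the local
micro-texture contrast (film-grain amplitude, 5 ± 1 gray levels) upward
and the fatty-field correlation length (0.12 ± 0.024 cm) downward — cases
have the busier, higher-contrast parenchymal pattern. The two channels
were chosen to have *separable carriers* in the feature bank: the grain
amplitude drives the fine-scale wavelet detail energies and the GLCM
contrast family almost independently of the dense-area fraction, while
both shifts lower the lag-1 spatial correlation, so the correlation
family carries their sum. An earlier design that shifted dense-blob
amplitude and correlation length in the same direction turned out to cap
the achievable case-control separation near AUC 0.76 regardless of the
classifier — too little headroom for the contracted recovery property —
which is why the channels are defined this way. The dense-area fraction
itself is drawn from the same uniform range (5–50%) in both arms, so the
planted signal is orthogonal to the PMD surrogate by design.

**What the generator does not model:** mammographic anatomy (pectoral
muscle, skin line, vasculature), analogue-vs-digital acquisition
differences, HRT or menopause effects on texture, and any covariate →
texture coupling. Passing parameter-recovery tests therefore demonstrates
that the pipeline's machinery is correct and calibrated, not that it
would achieve any particular performance on real mammograms.

## Problem sizes used in validation

The package's own validation runs at deliberately modest sizes chosen to
make the full factorial reproducible on a single CPU: cohorts of 600
subjects (200 matched triplets), 128 × 128 px images at 0.05 cm/px (so
the coarse blocks are 10/20 px), B = 50 bootstrap resamples with
`screen_k = 3`, 10 cohort seeds per effect arm, and 100 replicates for
the null-coverage check. All physical texture parameters are defined in
cm, so the same cohort can be rendered at the default 0.02 cm/px spacing
unchanged.

At these sizes two small-sample phenomena are visible and documented
rather than hidden. First, a bootstrap resample of 300 training subjects
against ~90-feature groups retains large within-resample models
(quasi-separation keeps the in-sample AIC flat), which inflates inclusion
frequencies of pure-noise features; the >70% rule then admits some junk,
which dilutes but does not bias the validation score (the null-cohort AUC
stays at 0.5). Second, vote splitting among correlated carriers — the
motivation for the substitution rule above. Both effects shrink as the
cohort grows.

## Known limitations

* The exact backward search is exponential in nothing but still `O(p)`
  converged refits per step; at bootstrap scale the one-step screen is
  used instead (documented above). Both are available; the tests pin
  their agreement on moderate problems.
* Form features of the synthetic cohort are pure noise by design (the
  breast shape is independent of case status), so the form group
  exercises the selection machinery's specificity, not its sensitivity.
* The coarse 1.0 cm grid on 128 px test images contains only a handful of
  valid blocks; coarse-scale features are computed correctly but are
  noisy at that image size.
* Wald intervals undercover slightly in small, strongly unbalanced
  strata; the null-coverage check (93–99/100) bounds this.
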