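---
title: "Intratumoral and peritumoral radiomics for nodule invasiveness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intratumoral and peritumoral radiomics for nodule invasiveness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periradiomics)
```

## The problem

Subcentimeter lung adenocarcinomas (diameter below 1 cm) are usually
detected by CT screening, and the central clinical question is whether a
nodule is a minimally invasive adenocarcinoma (MIA, invasion of at most
5 mm) or an already invasive adenocarcinoma (IAC). The distinction drives
the choice between surveillance, sublobar resection and lobectomy, but at
this size the classic morphological signs (lobulation, spiculation) are
frequently absent and conventional CT reading has limited discrimination.

`periradiomics` implements a complete, tested pipeline for the radiomics
approach to this problem: quantify the texture of the tumor itself (the
gross tumor volume, GTV), of the tumor plus a 5-mm peritumoral margin
(GPTV), and of the 5-mm peritumoral shell alone (GPR), compress each
region's features into a radiomics score (Radscore) with a stability
filter, a minimum-redundancy maximum-relevance (mRMR) ranking and
cross-validated LASSO logistic regression, and compare the resulting
predictive models against a baseline model built from conventional CT
features (maximum diameter and the vessel convergence sign, VCS).

Because clinical CT cohorts of this kind are not publicly deposited, the
package ships a first-class synthetic cohort generator that reproduces the
statistical structure the analysis assumes, so every stage of the pipeline
is testable end to end.

## Region geometry

The GTV mask is an input (in practice from semi-automatic segmentation with
manual review). The GPTV is obtained by dilating the GTV outward by 5 mm in
*physical* units: a voxel belongs to the dilated region iff its centre lies
within 5 mm Euclidean distance of some GTV voxel centre. This is computed
with an exact Euclidean distance transform (Felzenszwalb-Huttenlocher
separable parabolic envelopes, spacing-aware), not by iterating structuring
elements, so anisotropic voxels are handled exactly and the margin is not
quantized. The GPR is the set difference GPTV minus GTV; the three masks
always satisfy `gtv ⊆ gptv`, `gpr = gptv \ gtv`, `gtv ∩ gpr = ∅`.

When the 5-mm margin would leave the image grid, volumes are padded with
-1024 HU (air) and a warning is raised — dilation is never silently
truncated. Dilation is performed after resampling to the 1-mm isotropic
target grid, so "5 mm" is exact on the working grid. The dilation is
unrestricted Euclidean dilation; it is not geodesically constrained to lung
parenchyma, since mask inputs for subcentimeter nodules rarely touch the
chest wall.

## Preprocessing

Three steps, in order:

1. **Resampling** to 1 × 1 × 1 mm voxels using cubic B-spline
   interpolation with the exact recursive prefilter (pole √3 − 2, mirror
   boundaries). The prefiltered interpolant passes through the input
   samples and reproduces polynomials up to degree 3; masks are resampled
   with nearest-neighbour interpolation and stay strictly binary.
2. **Intensity normalization**: `(x − window_level) / window_width` with
   the lung window (level −600 HU, width 1500 HU). This affine map feeds
   the first-order statistics.
3. **Gray-level discretization** with a fixed bin width of 25 HU,
   anchored at the ROI minimum: `level(x) = floor((x − min)/25) + 1`.

One design choice deserves emphasis: discretization operates on the
original HU values inside each ROI, *not* on the window-normalized
values. A 25-HU bin applied to intensities rescaled into a unit range
would put every voxel of an ROI into a single gray level, which is
degenerate; anchoring at the ROI minimum also makes all texture features
invariant to global HU calibration shifts. Normalization is retained as a
configurable pre-step for the first-order statistics only
(`preprocess_config(normalize_first_order = )`).

## Feature families

Per region, seven families are computed (98 features with the default
configuration; `feature_count()` documents the arithmetic):

* **first-order** (17): moments, percentiles, energy, and histogram
  entropy/uniformity on the 25-HU-bin discretization (log base 2);
* **shape** (10): voxel volume, mesh surface area, sphericity, maximum 3D
  diameter, PCA axis lengths, elongation, flatness;
* **GLCM** (20): co-occurrence statistics for 13 unique 3D directions at
  distance 1, matrices symmetrized (`P + t(P)`), features averaged over
  directions;
* **GLRLM** (16): run-length statistics per direction, averaged;
* **GLSZM** (16): zone statistics over 26-connected equal-level zones;
* **GLDM** (14): dependence counts over the 26-neighbourhood with
  similarity tolerance α = 0; the dependence size index includes the
  centre voxel;
* **NGTDM** (5): coarseness, contrast, busyness, complexity, strength
  from per-level deviations against the mean of available 26-neighbours.

Where the underlying literature leaves conventions open, the standard
image-biomarker conventions are used: averaging over directions,
symmetrized GLCM, 26-connected zones. Degenerate inputs follow documented
conventions — a single-voxel or single-level ROI yields contrast-type
features of 0, correlation 1, joint energy 1, and NGTDM coarseness is
capped at 1e6 when the total deviation is zero.

The raw matrix accumulation (GLCM/GLRLM pair and run scans, zone flood
fill, dependence and neighbourhood counts), the distance transform, the
connected-component labelling and the surface mesh are implemented in
C++ (via Rcpp), as radiomics extractors conventionally are; every family
is verified in the test suite against independent brute-force enumeration
oracles written in plain R.

An optional filter bank (`feature_config(filters = c("wavelet", "log"))`)
adds the eight sub-bands of an undecimated single-level 3D Haar transform
and Laplacian-of-Gaussian images at configurable scales; each derived
image feeds the first-order and texture families again. Feature catalogue
sizes in the thousands, as reported for commercial extractors, are a
configuration outcome of such filter banks; the default configuration
keeps the filters off and documents its own count.

### Surface area

Surface area uses marching tetrahedra on a symmetric 24-tetrahedra cell
decomposition (body centre plus face centres), which removes the diagonal
bias of the classic 6-tetrahedra split. The binary mask is lightly
anti-aliased first (Gaussian, σ = 0.55 voxels; iso-level 0.5): meshing a
raw 0/1 field systematically overestimates the area of curved surfaces
(about +12% for digitized balls with the 24-tet split, about +26% with the
6-tet split), while the anti-aliased mesh is accurate to a few percent at
nodule-relevant radii — a digital ball of radius 8 voxels yields
sphericity above 0.95. For objects so small that the smoothed field never
crosses the iso-level (about one voxel), the voxel-face area is used as a
documented fallback.

## Radscore construction

Three stages, mirroring standard radiomics signature practice:

1. **Stability filter.** Features must achieve an intraclass correlation
   coefficient ICC(2,1) — two-way random effects, absolute agreement,
   single rater — of at least 0.75 across two raters' extractions. The
   synthetic pipeline emulates the second rater by random boundary
   perturbation of the mask (`perturb_mask()`: surface voxels added and
   removed with probability 0.2, largest component kept). The 0.75 cutoff
   is the conventional "good reliability" boundary. The filter uses no
   labels, so it is applied once, outside any cross-validation.
2. **mRMR ranking** (greedy difference scheme, default 30 features kept):
   relevance is the one-way ANOVA F statistic of the feature against the
   class, mapped through `F/(F + n − 2)` — the squared point-biserial
   correlation — so that it shares the [0, 1] scale of the redundancy
   term, the mean absolute Pearson correlation with already-selected
   features. On comparable scales a duplicated feature (redundancy 1) can
   never follow its twin while an informative independent feature exists.
   Ties break by feature name, so selection is order-invariant.
3. **LASSO logistic regression** over a log-spaced λ path with 10-fold
   stratified cross-validation (via `glmnet`), λ chosen at minimum mean CV
   binomial deviance (the `1se` rule is available). Columns are
   standardized internally; coefficients are reported on the original
   feature scale.

The **Radscore** is the signature's predicted probability,
`plogis(intercept + Σ coef · feature)` — a number in [0, 1], consistent
with reporting Radscore group means like 0.40 ± 0.18 versus 0.77 ± 0.18
and probability-scale cutoffs around 0.5–0.6. The linear predictor is
available via `radscore(type = "link")` for workflows that define the
score on the logit scale.

Fold assignment everywhere derives from a hash of the case identifier and
the seed, never from row position, so permuting a cohort's rows changes
nothing.

## Predictive models and evaluation

Four models are compared, deliberately kept in separate frameworks to
avoid collinearity between radiomics and morphology: the CT-features model
(logistic regression on maximum diameter + VCS) and one logistic model per
Radscore (GTV, GPTV, GPR), each using only its own score.

Two performance surfaces are reported and labelled distinctly:

* **apparent** (resubstitution) ROC of the fitted models, which is what
  single-cohort radiomics studies usually print, and
* **out-of-fold** probabilities from stratified 10-fold cross-validation.
  For the Radscore models the *entire* selection chain (mRMR + LASSO) is
  refit inside each training fold (`radscore_cv()`): evaluating a
  full-data Radscore out-of-fold would leak the test labels through the
  signature itself. The label-free stability filter stays outside the
  folds. This nested scheme is the honest analogue of "evaluated via
  10-fold cross-validation".

Evaluation statistics are implemented in the package and cross-checked in
the tests against independent oracles (pair-counting AUC, pROC's DeLong
implementation, hypergeometric enumeration, permutation distributions):

* ROC/AUC with ties counted 1/2 (equivalently the Mann-Whitney U statistic
  over n₁n₀);
* DeLong structural-components variance and paired AUC test;
* AUC confidence intervals by both the DeLong normal approximation and a
  stratified percentile bootstrap (default 2000 replicates), labelled by
  method;
* Youden-optimal cutoffs (ties to the lowest threshold);
* Hosmer-Lemeshow calibration over deciles of risk (ties kept together,
  empty bins merged with a warning), statistic Σ(O−E)²/(E(1−E/n)) with
  g − 2 degrees of freedom;
* decision-curve analysis with net benefit
  `TP/n − (FP/n)·p_t/(1−p_t)`, treat-all and treat-none references, and a
  reported "useful range" — the threshold interval where the model's net
  benefit exceeds both references (our interpretation of defining DCA
  threshold ranges through ROC optimization);
* a pairwise DeLong comparison table across all models.

## Clinical covariate statistics

The univariate clinical layer reproduces the standard two-class cohort
table: Pearson χ² (with the closed form n(ad−bc)²/(r₁r₂c₁c₂) on 2×2
tables), the Yates continuity correction when any expected count falls
below 5, Fisher's exact test below 1, Wald odds ratios
(`exp(log OR ± 1.96·SE)`, Haldane 0.5 correction for zero cells), the
Mann-Whitney U test with tie-corrected normal approximation (exact
enumeration for pooled n ≤ 12), and a Shapiro-Wilk normality gate (α =
0.05 per group) dispatching between the pooled t test and the U test.
Univariable and multivariable logistic regression report OR tables with
Wald 95% intervals.

These closed-form statistics are exactly reproducible from the reference
cohort's published per-class percentages (n = 53 MIA / 89 IAC), which are
shipped as `reference_cohort_counts()`; the test suite pins eight Pearson
and four continuity-corrected χ² statistics and two odds ratios with their
confidence intervals to the printed values. One published 5×2 omnibus
statistic for nodule location is not reproducible by any standard χ²
variant we tried (plain Pearson gives 5.19 against a printed 4.994); the
generic r×c Pearson is provided but no parity is claimed for that row.

## The synthetic cohort generator

`cohort_spec()` defines the study conditions; `simulate_cohort()` renders
them. Defaults emulate the reference cohort: 53 MIA and 89 IAC cases;
diameters drawn from a Beta distribution rescaled to (3, 10] mm whose
parameters are solved numerically so the class medians and IQRs equal
8.00 (2.65) and 9.00 (2.00) mm; subsolid fractions 88.7% / 85.4%; twelve
binary covariates at the reference prevalences (an `exact_counts` mode
reproduces the implied integer counts, e.g. VCS 9/53 vs 40/89); age and
BMI as normals matching the published median/IQR.

Nodules are rendered as randomly rotated superellipsoids (exponent 2.5,
axis ratios 0.8–1) with a smooth random boundary perturbation, in a
lung-like background (HU ~ Normal(−850, 50) clipped to [−1024, −500], plus
a spatially correlated parenchymal field of random amplitude). Subsolid
cores draw voxel intensities from Normal(−450, 60) HU, solid cores from
Normal(−30, 40) HU. The published protocol gives no HU values; these match
conventional lung-window appearance and exercise the stated normalization
range. The rendering scale is calibrated against the measured caliper
diameter (surface-voxel centres plus one mean voxel extent), so the
`max_diameter_mm` covariate is mask-derived and the subcentimeter
constraint (≤ 10 mm, redraw on violation) is enforced exactly; 500 draws
per class reproduce the target medians within 0.5 mm. The default grid is
a 28-mm cube at 1-mm isotropic spacing — just large enough for the largest
nodule plus the 5-mm margin.

Two planted class effects define invasiveness, both scaled by one latent
per-case severity `u ~ Exp(1)`:

* `texture_effect` (default 60 HU): intratumoral heterogeneity — a
  spatially structured high-frequency field of amplitude `60·u` plus a
  densification shift of `0.2·60·u`, added inside the GTV of IAC cases;
* `peritumoral_effect` (default 40 HU): peritumoral remodeling — a smooth
  positive field of amplitude `40·u` confined to a 2.5-mm inner rim of the
  shell (the scale of microscopic invasion), plus vessel-like strands
  (radius 0.5 mm, −100 HU) crossing the boundary with a probability that
  rises with the effect for IAC cases.

Three modelling choices matter here and are deliberate. The exponential
severity keeps every single feature off the AUC ceiling (a fixed-amplitude
shift over a thousand-voxel region would be perfectly separable).
Class-independent per-case nuisance — a global HU calibration offset
(σ = 15 HU) and the random-amplitude parenchymal texture — masks small
mean shifts the way between-patient variability does in real cohorts.
And because one severity drives both effects, the peritumoral signal is a
lower-SNR proxy of the same biology the core expresses directly, which is
what makes the GTV model the strongest and the shell model the weakest —
the qualitative ordering reported for the reference study — rather than an
artifact of independently tunable signals. With both effects at zero and
identical size distributions, the generator is an exact null: the classes
are exchangeable by construction.

What the generator does *not* emulate: photorealistic CT appearance,
scanner/kernel characteristics, geometric rendering of the morphological
signs (lobulation, spiculation and the like are sampled as covariate flags
at the reference prevalences, not drawn into the image), and any
correlation between those flags and the image content. Consequently,
passing tests demonstrate that the pipeline recovers planted effects with
the right ordering and calibrated error rates — not that the specific
published AUC values would be reproduced on clinical data.

## Numerical choices and problem sizes

* Logistic fits: IRLS (`stats::glm`) with deviance tolerance 1e-10, 100
  iterations maximum; separation is flagged from divergent coefficients.
* LASSO: `glmnet` coordinate descent; KKT conditions of the returned
  solution are verified to 1e-6 in the tests.
* B-spline prefilter horizon: truncated at machine precision
  (|z|^k < eps), mirror initialization.
* Distance transform: exact squared distances in double precision; the
  1e20 background sentinel keeps envelope arithmetic exact.
* Tie-breaks: mRMR by feature name; Youden by lowest threshold;
  Hosmer-Lemeshow bins merge ties.
* Property-style tests run at deliberately desk-scale sizes chosen to
  keep the full suite fast while leaving the statistical checks
  well-powered: cohorts of 60–100 cases on 24–28 mm grids, 20 seeds for
  recovery/ordering/null-control claims, 100 random arrays for the
  texture oracles, 1000/300-replicate type-I error simulations.

## Known limitations

* Feature definitions follow the standard conventions but are not a
  certified IBSI reference implementation; the oracle tests pin the
  matrix accumulations and formulas, not an external standard's numbers.
* DICOM series ingestion is not provided (no DICOM reader is available in
  the package's dependency budget); NIfTI is the interchange format.
* The generator's covariate flags are independent of the rendered image;
  analyses that couple morphology flags to texture would need an
  extended generator.
* Scanner harmonization (e.g. ComBat) is out of scope, matching the
  stated limitation of single-scanner protocols.

## A minimal worked run

```{r, eval = FALSE}
spec <- cohort_spec(n_mia = 24, n_iac = 40, seed = 7)
cohort <- simulate_cohort(spec)
study <- run_study(cohort, selection_config(seed = 7), folds = 5)
study$auc_cv          # out-of-fold AUC of GTV/GPTV/GPR/CT models
study$comparison      # pairwise DeLong table
hosmer_lemeshow(study$radscore$GTV, study$labels)
decision_curve(study$radscore$GTV, study$labels)$useful_range
```
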