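# periradiomics

CT radiomics of the intratumoral and peritumoral microenvironment for
predicting the invasiveness of subcentimeter lung adenocarcinomas.

Subcentimeter nodules (< 1 cm) found at CT screening may be minimally
invasive (MIA, invasion ≤ 5 mm) or already invasive adenocarcinomas
(IAC); the distinction drives surveillance-versus-resection decisions,
yet conventional CT reading discriminates poorly at this size.
`periradiomics` implements the full quantitative pipeline for this
problem as a tested, reusable R package:

* **ROI geometry** — from a gross tumor volume (GTV) mask, build the
  gross peritumoral tumor volume (GPTV = GTV dilated outward by 5 mm,
  via an exact spacing-aware Euclidean distance transform) and the gross
  peritumoral region (GPR = GPTV \ GTV);
* **preprocessing** — cubic B-spline resampling to 1 mm isotropic
  voxels, lung-window intensity normalization `(x + 600)/1500`, and
  fixed-bin-width gray-level discretization
  `level(x) = floor((x − min)/25) + 1`;
* **feature extraction** — first-order, shape, GLCM, GLRLM, GLSZM, GLDM
  and NGTDM families implemented from scratch (compiled kernels, R
  formulas), each verified against brute-force enumeration oracles, plus
  an optional wavelet / Laplacian-of-Gaussian filter bank;
* **signature construction** — ICC(2,1) ≥ 0.75 inter-rater stability
  filter, greedy mRMR ranking, LASSO logistic regression with seeded
  10-fold cross-validation; the **Radscore** of a case is the signature's
  predicted probability
  `plogis(β₀ + Σ βᵢ·featureᵢ)`;
* **models and evaluation** — isolated logistic models (CT features =
  max diameter + vessel convergence sign; one model per Radscore),
  apparent and nested out-of-fold ROC, DeLong variance/test
  (structural components), bootstrap AUC intervals, Youden cutoffs,
  Hosmer-Lemeshow calibration, decision-curve analysis
  `NB(p_t) = TP/n − (FP/n)·p_t/(1 − p_t)`, pairwise model comparison;
* **clinical statistics** — χ² (Pearson/Yates/Fisher policy), Wald odds
  ratios, Mann-Whitney U with exact small-sample enumeration,
  Shapiro-Wilk-gated group comparison, univariable/multivariable
  logistic OR tables;
* **synthetic cohorts** — a 3D nodule generator that reproduces the
  reference cohort's structure (53 MIA / 89 IAC; class diameter medians
  8.00 and 9.00 mm on a (3, 10] mm support; covariate prevalences;
  planted intratumoral and peritumoral effects scaled by a latent
  per-case severity), so the whole pipeline is testable without
  clinical data.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
conventions, numerical choices and the generator's assumptions in detail.

## Worked example

```r
library(periradiomics)

spec   <- cohort_spec(n_mia = 24, n_iac = 40, seed = 7)
cohort <- simulate_cohort(spec)
study  <- run_study(cohort, selection_config(seed = 7), folds = 5)
round(study$auc_cv, 3)
#>        GTV       GPTV        GPR CTfeatures
#>      0.817      0.779      0.690      0.674
subset(study$comparison, model_b == "CTfeatures")
#>   model_a    model_b     auc_a     auc_b        z           p
#> 3     GTV CTfeatures 0.9166667 0.7171875 3.026300 0.002475662
#> 5    GPTV CTfeatures 0.8687500 0.7171875 2.541625 0.011033841
#> 6     GPR CTfeatures 0.8385417 0.7171875 1.801539 0.071617930
```

`study$auc_cv` holds honest out-of-fold AUCs (the mRMR + LASSO chain is
refit inside every training fold); `study$auc_apparent` holds the
resubstitution values that single-cohort studies usually report; the
comparison table gives pairwise DeLong z and p on the apparent scores.
On synthetic cohorts with the default planted effects the intratumoral
(GTV) and tumor-plus-margin (GPTV) models are statistically
indistinguishable, both beat the shell-only (GPR) model, and all three
beat the CT-features baseline — the qualitative pattern reported for the
reference cohort.

Clinical-layer statistics are exact and closed-form; for example the
vessel convergence sign table of the reference cohort (9/53 MIA vs 40/89
IAC positive):

```r
vcs <- rbind(c(44, 49), c(9, 40))
pearson_chi2(vcs)$statistic   # 11.493
odds_ratio_wald(vcs)          # OR 3.991 (1.741, 9.151)
```

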