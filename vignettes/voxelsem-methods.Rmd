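---
title: "Two-part latent growth curve models, voxel by voxel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part latent growth curve models, voxel by voxel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Screening questionnaires for alcohol use such as the AUDIT produce
*semicontinuous* longitudinal outcomes. At each measurement occasion a
large fraction of a youth cohort reports no use at all (a structural
zero), while the positive scores among users are approximately
continuous. Fitting one growth curve to the raw scores confounds two
different processes — the *probability of any use* and the *quantity given
use* — and the point mass at zero violates the distributional assumptions
of a linear growth model.

The two-part (semicontinuous) latent growth curve model decomposes the
observed score $y_{it}$ for subject $i$ at occasion $t$ into

* a binary indicator $u_{it} = \mathbf{1}(y_{it} > 0)$, and
* a continuous score $y^{+}_{it} = y_{it}$ defined only when $u_{it} = 1$.

Each part gets its own latent growth curve:

$$
\mathrm{logit}\, P(u_{it} = 1 \mid \eta_i) = I^{d}_i + \lambda_t S^{d}_i,
\qquad
y^{+}_{it} \mid u_{it}=1, \eta_i \sim
  N\!\left(I^{c}_i + \lambda_t S^{c}_i,\ \theta_t\right),
$$

with time scores $\lambda_t$ (default $0, 1, 2$), latent growth factors
$\eta_i = (S^d_i, I^d_i, I^c_i, S^c_i) \sim N(\mu + \Gamma x_i, \Psi)$,
covariates $x_i$, and occasion-specific residual variances $\theta_t$
(optionally constrained equal). A probit link and quadratic growth in
either part are also supported. Cross-part dependence enters through the
latent covariance matrix $\Psi$; its free pattern follows the structural
zeros of its lower Cholesky factor, so the default keeps the within-part
covariances and the adjacent cross-part covariance free.

## Estimation

The marginal likelihood of a subject requires integrating over
$\eta_i$. `voxelsem` exploits the model's conditional linearity: given
the *discrete-part* factors, the continuous part is a linear Gaussian
model, so the continuous factors are marginalized analytically. Only the
discrete-part dimensions (two for linear growth) are integrated
numerically, by prior-scaled Gauss–Hermite quadrature (`n_quad` nodes per
dimension, default 15). The integrand and its analytic gradient are
implemented in compiled C++ (RcppArmadillo), including per-subject score
vectors used for BHHH steps and OPG standard errors.

Free parameters are packed into an unconstrained vector: latent means,
the free entries of the Cholesky factor of $\Psi$ with log-transformed
diagonal, log residual variances, and regression coefficients.
Optimization uses `nlminb` with analytic gradients and multiple jittered
starts; convergence requires both the optimizer's success code and a
small scaled gradient norm.

Missing data are handled by full information maximum likelihood under a
missing-at-random assumption: each subject contributes the likelihood of
exactly the cells observed for them. Scores at occasions with no use are
*structurally* missing — the model treats them as undefined rather than
as zeros, which is the defining feature of the two-part decomposition.

### What the likelihood can and cannot identify

With only three binary occasions the data carry limited information about
the discrete-part variance components. The likelihood surface has a flat
ridge along which larger latent variances trade off against attenuated
means (the familiar $\mu / \sqrt{1 + c^2\sigma^2}$ attenuation of
marginalized logistic models), so individual discrete-part variance
estimates can sit far from the truth at small log-likelihood cost while
the *fitted response-pattern probabilities* remain accurate. Tests and
comparisons based on the likelihood (LRTs, information criteria,
voxelwise Wald tests on regression paths) are unaffected; point
interpretation of `var.Id`/`var.Sd` at three occasions should be
cautious. More occasions, or a probit link with informative priors,
sharpen this corner of the model.

## Model evaluation

`likelihood_ratio_test()` compares nested fits; `fit_indices()` computes
$\chi^2$ against a saturated mean/covariance model of the continuous
part estimated by an EM algorithm under FIML, with RMSEA
($\sqrt{\max(\chi^2 - df, 0)/(df\,n)}$), CFI, SRMR, AIC and BIC.
`compare_models()` chains LRTs across a sequence of nested
specifications. Wald tests on individual parameters use OPG standard
errors; columns of the score matrix that are numerically degenerate
(e.g. a variance on the boundary) are profiled out and reported as `NA`
rather than producing spuriously small standard errors.

## The voxelwise sweep

`run_voxelwise()` enters each voxel of a subject-aligned image set — one
at a time, standardized — as a predictor of a chosen growth factor
(default the continuous slope `Sc`) and refits the model per voxel:

1. A *base fit* without the voxel predictor supplies warm starts and an
   adaptive approximate Hessian shared across voxels.
2. Each voxel is refitted by a chord-Newton iteration with that shared
   Hessian; voxels that fail fall back to BHHH and then to `nlminb`
   (first from the warm start, then from a jittered start whose RNG is
   seeded by the voxel index and restored afterwards).
3. The Wald $z = \hat\beta / \widehat{se}(\hat\beta)$ and two-sided $p$
   are projected back into image space; constant voxels and voxels
   outside the analysis mask are reported as missing.

This per-voxel *refit* is deliberately not replaced by a score test from
the base fit: with a latent-variable outcome the two disagree away from
the null, and the refit keeps the estimates interpretable as effect
sizes.

`threshold_clusters()` applies the familiar neuroimaging cluster-extent
rule: voxels with $p$ below a height threshold (default $0.001$) are
grouped into connected components (6-, 18- or 26-connectivity; positive
and negative effects separately), components with strictly more than
`k_min` voxels (default 100) are retained, and peaks are reported in both
voxel indices and world coordinates through the NIfTI affine. Cluster
tables and manifests are written with fixed formatting so identical runs
are byte-identical.

Cluster-extent thresholding controls family-wise error only
approximately and depends on the smoothness of the underlying maps; the
defaults mirror common practice for exploratory voxelwise screens, not a
calibrated error guarantee.

## Synthetic studies

Because real cohort imaging data are access-restricted, the package ships
a generator that produces cohorts with known ground truth:
`synthetic_config()` fixes the generating growth parameters (defaults at
magnitudes typical of adolescent alcohol-use cohorts: rising use
prevalence, mean log-score growth of about half a point per wave,
moderate negative intercept–slope covariances, a small negative male
effect on the continuous slope, multi-site dummies, monotone attrition),
`generate_trajectories()` draws the behavioural data, and
`generate_brain()` builds smoothed noise volumes with spherical regions
whose intensity tracks a subject's standardized growth factor.
`generate_study()` writes the whole bundle (CSV, NIfTI, ground-truth
JSON) to disk. The acceptance tests use these known-truth studies to
verify parameter recovery, test calibration, planted-effect detection and
null-volume specificity end to end.

## Example

```{r}
library(voxelsem)

cfg <- synthetic_config(n_subjects = 500, n_sites = 1,
                        image_dim = c(10, 10, 10),
                        effect_regions = list(
                          list(center = c(5, 5, 5), radius = 2, beta = 1.5)))
traj <- generate_trajectories(cfg, seed = 1)
data <- two_part_data(traj$data$binary, traj$data$continuous,
                      covariates = traj$data$covariates["sex"],
                      occasion_times = traj$data$occasion_times)

spec <- growth_spec(equal_residuals = TRUE, n_quad = 5)
fit <- fit_twopart(data, spec)
summary(fit)

brain <- generate_brain(cfg, traj$truth, seed = 2)
res <- run_voxelwise(brain, data, spec, base_fit = fit)
threshold_clusters(res, p_threshold = 0.001, k_min = 20)
```

## Limitations

* The MAR assumption of FIML is untestable from the observed data;
  informative dropout tied to unmodelled severity would bias growth
  estimates.
* Discrete-part variance components are weakly identified with three
  occasions (see above).
* The voxelwise model is mass-univariate: each voxel is tested in
  isolation, and spatial structure enters only through the cluster rule.
* Cluster-extent inference is approximate; for confirmatory claims use
  pre-registered regions or permutation-based thresholds.
* Quadrature cost grows as `n_quad^d` in the discrete-part dimension
  `d`; quadratic discrete growth with large `n_quad` is expensive.
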