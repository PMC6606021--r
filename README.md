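# voxelsem

Voxel-wise structural equation modelling of two-part growth trajectories.

Longitudinal substance-use questionnaires such as the AUDIT produce
*semicontinuous* outcomes: many respondents report no use at all, and the
positive scores among users are roughly continuous. A single growth curve
fitted to such data confounds two distinct questions — *whether* a person
uses at each wave, and *how much* given any use. `voxelsem` implements the
two-part (semicontinuous) latent growth curve model that separates them:

- a **binary part** models any use at each occasion through a logistic (or
  probit) latent growth curve with intercept and slope factors `Id`, `Sd`;
- a **continuous part** models the score *given* use through a linear
  growth curve with factors `Ic`, `Sc` and occasion-specific (or
  constrained-equal) residual variances;
- the two parts are linked by latent covariances, and covariates
  (sex, site, total brain volume, …) can load on any growth factor.

The likelihood marginalizes the continuous factors analytically
conditional on the binary-part factors and integrates the remaining
discrete-part dimensions by adaptive Gauss–Hermite quadrature, with
analytic gradients in compiled code. Missing data are handled by full
information maximum likelihood; scores at non-use occasions are treated as
structurally missing.

On top of the single model the package provides a **mass-univariate
driver**: every voxel of a subject-by-voxel image set is entered (one at a
time, standardized) as a predictor of a chosen growth factor, the model is
refitted per voxel with warm starts from the voxel-free base fit, and the
resulting z- and p-maps are thresholded with cluster-extent rules
(p < 0.001, cluster size k > 100 by default, 6/18/26-connectivity).

A synthetic-data generator with known ground truth (`synthetic_config()`,
`generate_study()`) makes the whole pipeline testable without access to
restricted cohort data.

## Worked example

Simulate a cohort of 500 subjects measured at three occasions, with one
spherical brain region whose tissue volume tracks the continuous-part
slope, then run the full pipeline. (Runs in well under a minute.)

```r
library(voxelsem)

cfg <- synthetic_config(n_subjects = 500, n_sites = 1,
                        gamma = c(sex = -0.183),
                        image_dim = c(10, 10, 10),
                        effect_regions = list(
                          list(center = c(5, 5, 5), radius = 2, beta = 1.5)))
traj <- generate_trajectories(cfg, seed = 1)
data <- two_part_data(traj$data$binary, traj$data$continuous,
                      covariates = traj$data$covariates["sex"],
                      occasion_times = traj$data$occasion_times)
data
#> <two_part_data> 500 subjects x 3 occasions
#>   occasion times: 0, 1, 2
#>   observed binary fraction: 1.00, 0.80, 0.70
#>   use prevalence (observed): 0.64, 0.66, 0.75
#>   covariates: sex

spec <- growth_spec(equal_residuals = TRUE, n_quad = 5)
fit <- fit_twopart(data, spec)
fit
#> <twopart_fit>
#>   logLik -2043.328 on 13 free parameters, 500 subjects
#> <two_part_params>
#>   means:
#>     Sd     Id     Ic     Sc
#> 0.2635 0.5230 0.7261 0.4948
#>   latent covariance:
#>         Sd      Id      Ic      Sc
#> Sd  0.0745 -0.0208  0.0000  0.0000
#> Id -0.0208  0.0156  0.0476  0.0000
#> Ic  0.0000  0.0476  0.7013 -0.1584
#> Sc  0.0000  0.0000 -0.1584  0.2925
#>   residual variances: 0.461
#>   regressions:
#>     sex
#> -0.2067
```

`summary(fit)` returns a tibble of estimates, standard errors and Wald
tests; the sex effect on the continuous slope (−0.207, p = 0.004) matches
the generating value of −0.183 within sampling error.

Is there growth in the continuous part at all? Compare against an
intercept-only continuous part by likelihood ratio:

```r
spec_flat <- growth_spec(growth_continuous = "intercept_only",
                         covariate_paths = c(sex = "Ic"),
                         predictor_target = "Ic",
                         equal_residuals = TRUE, n_quad = 5)
fit_flat <- fit_twopart(data, spec_flat, se = FALSE)
likelihood_ratio_test(fit_flat$loglik, fit$loglik,
                      fit$n_free_params - fit_flat$n_free_params)
#> $delta_chi2
#> [1] 115.0658
#> $df
#> [1] 3
#> $p
#> [1] 8.910638e-25

fit_indices(fit, data)
#> chi2 = 1.17, df = 3, RMSEA = 0.000, CFI = 1.000, SRMR = 0.019
#> AIC = 4112.7, BIC = 4166.5 (n = 465)
```

Now the voxelwise sweep and cluster thresholding:

```r
brain <- generate_brain(cfg, traj$truth, seed = 2)
res <- run_voxelwise(brain, data, spec, base_fit = fit)
res
#> <voxel_map_result> target Sc: 1000 voxels, 1000 converged, 0 constant
#>   z range: [-2.56, 12.94]

clus <- threshold_clusters(res, p_threshold = 0.001, k_min = 20)
clus
#> <cluster_table> 1 cluster(s) at p < 0.001, k > 20, 26-connectivity
#>  cluster     sign n_voxels peak_i peak_j peak_k peak_x peak_y peak_z
#>        1 positive       33      7      5      5     12      8      8
#>  peak_z_stat    peak_p
#>        12.94 2.821e-38

dice_coefficient(attr(clus, "labels"), 1, brain$region_masks[[1]])
#> [1] 1
```

The single surviving cluster coincides exactly with the 33-voxel planted
region (Dice = 1).

## Command-line pipeline

Every stage is also available through a CLI with deterministic outputs and
JSON run manifests (installed at `system.file("cli", "voxelsem", package =
"voxelsem")`):

```sh
voxelsem simulate  --out sim --config study.yaml --seed 7
voxelsem fit       --data sim/behaviour.csv --out fit --config study.yaml --seed 7
voxelsem voxelwise --data sim/behaviour.csv --images sim/images.nii.gz \
                   --mask sim/mask.nii.gz --out maps --config study.yaml --seed 7
voxelsem clusters  --maps maps --out clusters --k-min 100
voxelsem evaluate  --data sim/behaviour.csv --out eval --config study.yaml --seed 7
```

A single `--seed` drives all stages through a counter-based per-stage
expansion; identical seed and configuration give byte-identical cluster
tables and manifests.

## AUDIT scoring utilities

`audit_sum_scores()`, `audit_prorate()` (round-to-nearest imputation of
missing items when at least two thirds are present), `audit_severity()`
(standard risk-zone cut-offs) and `severity_table()` prepare raw 10-item
AUDIT questionnaires for modelling; `decompose_two_part()` splits sum
scores into the binary and continuous parts with structural missingness.

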