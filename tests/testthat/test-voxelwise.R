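# One shared small cohort keeps this file fast: a 5x5x5 volume with a
# strong planted effect, analysed with the scaled-down quadrature settings
# used for volume sweeps.
vox_fixture <- local({
  cfg <- synthetic_config(n_subjects = 220, n_sites = 1,
                          gamma = c(sex = -0.183),
                          image_dim = c(5, 5, 5),
                          effect_regions = list(
                            list(center = c(3, 3, 3), radius = 1.5,
                                 beta = 2)))
  traj <- generate_trajectories(cfg, seed = 321)
  data <- two_part_data(traj$data$binary, traj$data$continuous,
                        traj$data$covariates["sex"],
                        traj$data$occasion_times)
  brain <- generate_brain(cfg, traj$truth, seed = 322)
  # one deliberately constant voxel
  brain$data[, 1, 1, 1] <- 7
  spec <- growth_spec(equal_residuals = TRUE, n_quad = 5)
  res <- run_voxelwise(brain, data, spec)
  list(cfg = cfg, data = data, brain = brain, spec = spec, res = res)
})

test_that("the voxel sweep produces aligned, mostly converged maps", {
  res <- vox_fixture$res
  expect_s3_class(res, "voxel_map_result")
  expect_identical(dim(res$z), c(5L, 5L, 5L))
  expect_identical(res$n_voxels, 125L)
  expect_gte(res$n_converged, 120L)
  expect_identical(res$target, "Sc")
  expect_true(res$base_fit$converged)
  # z = estimate / se wherever both exist
  ok <- !is.na(res$estimate) & !is.na(res$se)
  expect_equal(res$z[ok], (res$estimate / res$se)[ok])
  expect_equal(res$p[ok], 2 * pnorm(-abs(res$z[ok])))
})

test_that("constant voxels are flagged and left missing", {
  res <- vox_fixture$res
  expect_true(res$constant[1, 1, 1])
  expect_true(is.na(res$estimate[1, 1, 1]))
  expect_identical(res$n_constant, 1L)
})

test_that("the planted effect yields large positive z inside the region only", {
  res <- vox_fixture$res
  region <- vox_fixture$brain$region_masks[[1]]
  expect_gt(min(res$z[region]), 3)
  outside <- !region & !vox_fixture$res$constant
  expect_lt(median(abs(res$z[outside]), na.rm = TRUE), 2)
})

test_that("voxels outside the analysis mask are untouched", {
  brain <- vox_fixture$brain
  mask <- array(TRUE, c(5, 5, 5))
  mask[, , 5] <- FALSE
  brain$mask <- mask
  res <- run_voxelwise(brain, vox_fixture$data, vox_fixture$spec,
                       base_fit = vox_fixture$res$base_fit)
  expect_true(all(is.na(res$z[, , 5])))
  expect_identical(res$n_voxels, 100L)
})

test_that("misaligned subjects and unconverged base fits are refused", {
  brain <- vox_fixture$brain
  short <- brain
  short$data <- brain$data[1:100, , , , drop = FALSE]
  short$subject_id <- brain$subject_id[1:100]
  expect_error(run_voxelwise(short, vox_fixture$data, vox_fixture$spec),
               "100 subjects")
  bad_base <- vox_fixture$res$base_fit
  bad_base$converged <- FALSE
  expect_error(run_voxelwise(brain, vox_fixture$data, vox_fixture$spec,
                             base_fit = bad_base), "did not converge")
})

test_that("voxelwise estimates agree with a direct single-voxel fit", {
  res <- vox_fixture$res
  v <- c(3, 3, 3)
  x <- vox_fixture$brain$data[, v[1], v[2], v[3]]
  x <- (x - mean(x)) / sd(x)
  direct <- fit_twopart(vox_fixture$data, vox_fixture$spec, voxel = x,
                        se = FALSE, gradient_tol = 1e-4)
  expect_equal(res$estimate[v[1], v[2], v[3]],
               direct$estimates[["gamma.beta_voxel"]], tolerance = 1e-4)
})
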