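test_that("configuration validation catches inconsistent settings", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(attrition = c(1, 0.5)), "per occasion")
  expect_error(synthetic_config(attrition = c(1, 0.5, 1.2)), "retention")
  bad_psi <- voxelsem:::default_psi()
  bad_psi["Id", "Sc"] <- bad_psi["Sc", "Id"] <- 5
  expect_error(synthetic_config(psi = bad_psi), "semidefinite")
  expect_error(synthetic_config(effect_regions = list(
    list(center = c(30, 8, 8), radius = 2, beta = 1))), "outside")
})

test_that("trajectories honor the two-part structure, attrition and covariates", {
  cfg <- synthetic_config(n_subjects = 1500)
  out <- generate_trajectories(cfg, seed = 8)
  d <- out$data
  expect_s3_class(d, "two_part_data")
  expect_identical(dim(d$binary), c(1500L, 3L))
  # structural missingness: continuous observed exactly at observed use
  expect_identical(!is.na(d$continuous), !is.na(d$binary) & d$binary == 1)
  obs <- colMeans(!is.na(d$binary))
  expect_equal(obs, cfg$attrition, tolerance = 0.05)
  expect_true(abs(mean(d$covariates$sex) - 0.54) < 0.05)
  expect_identical(ncol(d$covariates), 3L + 8L)  # sex, age, tbv + 8 site dummies
  # covariate effect shifts the continuous slope draw by about gamma_sex
  fit <- lm(out$truth$eta[, "Sc"] ~ ., data = d$covariates)
  # sampling SE of this coefficient is about 0.024 at n = 1500; allow 3 SE
  expect_lt(abs(coef(fit)[["sex"]] - (-0.183)), 0.08)
  expect_identical(nrow(out$truth$eta), 1500L)
})

test_that("prevalence calibration hits the requested non-use rates", {
  cfg <- calibrate_prevalence(synthetic_config(), 0.48, 0.07)
  expect_equal(plogis(cfg$mu[["Id"]]), 1 - 0.48, tolerance = 1e-10)
  expect_equal(plogis(cfg$mu[["Id"]] + 2 * cfg$mu[["Sd"]]), 1 - 0.07,
               tolerance = 1e-10)
})

test_that("spherical masks count the expected voxels", {
  m <- sphere_mask(c(9, 9, 9), c(5, 5, 5), 1)
  expect_identical(sum(m), 7L)          # center + 6 face neighbours
  expect_true(m[5, 5, 5] && m[4, 5, 5] && !m[4, 4, 5])
  m150 <- sphere_mask(c(16, 16, 16), c(8, 8, 8.5), 3.25)
  expect_identical(sum(m150), 150L)
})

test_that("smoothing preserves constants and reduces roughness", {
  const <- array(3, c(8, 8, 8))
  expect_equal(voxelsem:::smooth3d(const, 1.5), const)
  set.seed(2)
  noise <- array(rnorm(8^3), c(8, 8, 8))
  sm <- voxelsem:::smooth3d(noise, 1.5)
  expect_lt(sd(sm), sd(noise))
  expect_identical(voxelsem:::smooth3d(noise, 0), noise)
})

test_that("planted regions carry the subject's standardized slope", {
  cfg <- synthetic_config(n_subjects = 60, image_dim = c(8, 8, 8),
                          effect_regions = list(
                            list(center = c(4, 4, 4), radius = 2, beta = 3)),
                          noise_sd = 0.1)
  traj <- generate_trajectories(cfg, seed = 5)
  brain <- generate_brain(cfg, traj$truth, seed = 6)
  expect_s3_class(brain, "brain_image_set")
  expect_identical(dim(brain$data), c(60L, 8L, 8L, 8L))
  sc_std <- scale(traj$truth$eta[, "Sc"])[, 1]
  region_mean <- apply(brain$data[, 4, 4, 4, drop = FALSE], 1, mean)
  expect_gt(cor(region_mean, sc_std), 0.8)
  far_vox <- brain$data[, 1, 8, 1]
  expect_lt(abs(cor(far_vox, sc_std)), 0.35)
})

test_that("a study bundle is written with consistent ground truth", {
  dir <- tempfile("study")
  cfg <- synthetic_config(n_subjects = 25, image_dim = c(6, 6, 6),
                          effect_regions = list(
                            list(center = c(3, 3, 3), radius = 1.5, beta = 1)))
  res <- generate_study(cfg, dir, seed = 900)
  expect_true(all(file.exists(res$behaviour, res$image, res$mask, res$truth)))
  d <- read_two_part_csv(res$behaviour)
  expect_identical(nrow(d$binary), 25L)
  tr <- jsonlite::read_json(res$truth)
  expect_equal(tr$mu$Id, 0.568)
  expect_equal(tr$seed, 900)
  expect_identical(length(tr$effect_regions[[1]]$voxels),
                   sum(sphere_mask(c(6, 6, 6), c(3, 3, 3), 1.5)))
  imgs <- read_brain_images(res$image, mask_path = res$mask)
  expect_identical(dim(imgs$data), c(25L, 6L, 6L, 6L))
  expect_true(all(imgs$mask))
})
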