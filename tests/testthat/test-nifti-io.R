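test_that("brain image sets validate their geometry", {
  dat <- array(rnorm(5 * 4 * 4 * 3), c(5, 4, 4, 3))
  s <- brain_image_set(dat)
  expect_identical(s$subject_id, as.character(1:5))
  expect_true(all(s$mask))
  expect_error(brain_image_set(dat[1, , , ]), "4-D")
  expect_error(brain_image_set(dat, affine = diag(3)), "4 x 4")
  expect_error(brain_image_set(dat, mask = array(TRUE, c(2, 2, 2))),
               "mask dimensions")
  expect_error(brain_image_set(dat, subject_id = "a"), "one entry per volume")
})

test_that("NIfTI round trip preserves volumes, mask and affine", {
  set.seed(99)
  dat <- array(rnorm(6 * 5 * 4 * 3), c(6, 5, 4, 3))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-5, -4, -3)
  mask <- array(runif(5 * 4 * 3) > 0.3, c(5, 4, 3))
  s <- brain_image_set(dat, aff, mask)
  f <- tempfile(fileext = ".nii.gz"); fm <- tempfile(fileext = ".nii.gz")
  write_brain_images(s, f, fm)
  r <- read_brain_images(f, mask_path = fm)
  expect_equal(r$data, dat, tolerance = 1e-6)
  expect_equal(r$affine, aff, tolerance = 1e-5, ignore_attr = TRUE)
  expect_identical(unname(r$mask), unname(mask))
})

test_that("misaligned inputs are rejected", {
  dims <- c(4, 4, 4)
  v1 <- RNifti::asNifti(array(rnorm(64), dims))
  s2 <- brain_image_set(array(rnorm(64), c(1, dims)),
                        affine = diag(c(3, 3, 3, 1)))
  f1 <- tempfile(fileext = ".nii.gz"); f2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(v1, f1)
  write_brain_images(s2, f2)
  expect_error(read_brain_images(c(f1, f2)), "affine mismatch")
  fm <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(2, 2, 2))), fm)
  expect_error(read_brain_images(f1, mask_path = fm), "mask dimensions")
})

test_that("voxel statistic maps are written with missing voxels as zero", {
  dims <- c(4, 4, 4)
  res <- structure(list(
    estimate = array(1.5, dims), se = array(0.5, dims),
    z = array(3, dims), p = array(0.0027, dims),
    affine = diag(4)), class = "voxel_map_result")
  res$z[1, 1, 1] <- NA
  dir <- tempfile("maps")
  paths <- write_voxel_maps(res, dir, what = c("z", "p"))
  expect_identical(sort(names(paths)), c("p", "z"))
  zin <- RNifti::readNifti(paths[["z"]])
  expect_equal(zin[1, 1, 1], 0)
  expect_equal(zin[2, 2, 2], 3, tolerance = 1e-6)
})
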