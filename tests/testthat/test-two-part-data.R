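test_that("structural invariants of the two-part container are enforced", {
  b <- matrix(c(1, 0, NA, 1), 2, 2)
  y <- matrix(c(2, NA, NA, 3), 2, 2)
  expect_s3_class(two_part_data(b, y), "two_part_data")
  bad <- y; bad[2, 1] <- 4       # continuous observed where binary == 0
  expect_error(two_part_data(b, bad), "non-use")
  bad2 <- y; bad2[1, 2] <- 4     # continuous observed where binary missing
  expect_error(two_part_data(b, bad2), "binary is missing")
  expect_error(two_part_data(matrix(2, 2, 2), y), "0, 1 or NA")
  expect_error(two_part_data(b, y[, 1, drop = FALSE]), "identical dimensions")
  expect_error(two_part_data(b, y, covariates = data.frame(x = 1)),
               "one row per subject")
})

test_that("decomposition splits zeros from positive scores and keeps missingness", {
  sums <- tibble::tibble(
    subject_id = c("a", "a", "a", "b", "b"),
    occasion = c(0, 1, 2, 0, 2),
    sum_score = c(0L, 3L, 5L, 2L, 0L))
  d <- decompose_two_part(sums)
  expect_identical(dim(d$binary), c(2L, 3L))
  expect_identical(d$binary["a", ], c(occ0 = 0, occ1 = 1, occ2 = 1))
  expect_identical(d$continuous["a", ], c(occ0 = NA_real_, occ1 = 3, occ2 = 5))
  expect_true(is.na(d$binary["b", 2]))     # occasion never measured
  expect_identical(unname(d$binary["b", 3]), 0)
  dup <- rbind(sums, sums[1, ])
  expect_error(decompose_two_part(dup), "duplicate")
})

test_that("covariates are joined by subject identifier", {
  sums <- tibble::tibble(subject_id = c("b", "a"), occasion = 0,
                         sum_score = c(1L, 0L))
  covs <- data.frame(subject_id = c("a", "b"), sex = c(0, 1))
  d <- decompose_two_part(sums, covariates = covs)
  expect_identical(d$covariates$sex, c(1, 0))  # subject order b, a
  expect_error(decompose_two_part(sums, covariates = covs[1, ]),
               "missing for subject")
})

test_that("CSV round trip preserves the dataset", {
  set.seed(11)
  cfg <- synthetic_config(n_subjects = 40, n_sites = 2)
  d <- generate_trajectories(cfg)$data
  path <- tempfile(fileext = ".csv")
  write_two_part_csv(d, path)
  d2 <- read_two_part_csv(path)
  expect_equal(unname(d2$binary), unname(d$binary))
  expect_equal(unname(d2$continuous), unname(d$continuous))
  expect_equal(d2$occasion_times, d$occasion_times)
  expect_equal(d2$covariates$sex, d$covariates$sex)
})

test_that("log transform acts on observed continuous scores only", {
  b <- matrix(c(1, 1, 0, 1), 2, 2)
  y <- matrix(c(2, 4, NA, 8), 2, 2)
  lt <- log_transform_two_part(two_part_data(b, y))
  expect_equal(lt$continuous[1, 1], log(2))
  expect_true(is.na(lt$continuous[1, 2]))
  expect_identical(lt$binary, two_part_data(b, y)$binary)
})
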