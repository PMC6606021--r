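test_that("connected components agree with an independent flood fill", {
  set.seed(77)
  for (conn in c(6, 18, 26)) {
    vol <- array(runif(14 * 12 * 10) < 0.35, c(14, 12, 10))
    lab <- label_components(vol, conn)
    ref <- flood_label(vol, conn)
    expect_true(same_partition(lab, ref),
                label = paste("connectivity", conn))
    expect_identical(lab != 0L, unname(vol))
  }
})

test_that("labels are deterministic and background stays zero", {
  vol <- array(FALSE, c(4, 4, 4))
  vol[1:2, 1, 1] <- TRUE
  vol[4, 4, 4] <- TRUE
  lab <- label_components(vol, 6)
  expect_identical(sort(unique(as.integer(lab))), c(0L, 1L, 2L))
  expect_error(label_components(vol, 10), "connectivity")
  expect_error(label_components(array(TRUE, c(2, 2)), 6), "3-D")
})

test_that("voxel-to-world transform applies the affine as given", {
  expect_equal(drop(world_coordinates(c(3, 4, 5), diag(4))), c(3, 4, 5))
  aff <- diag(c(2, 2, 2, 1))
  aff[1:3, 4] <- c(-10, -20, -30)
  expect_equal(drop(world_coordinates(c(1, 2, 3), aff)), c(-8, -16, -24))
  xyz <- world_coordinates(rbind(c(0, 0, 0), c(1, 1, 1)), aff)
  expect_identical(dim(xyz), c(2L, 3L))
  expect_error(world_coordinates(c(1, 1, 1), diag(3)), "4 x 4")
  expect_error(world_coordinates(c(1, 1, 1), matrix(0, 4, 4)), "singular")
})

test_that("cluster tables carry peaks in voxel and world space", {
  dims <- c(12, 12, 12)
  z <- array(0, dims); p <- array(1, dims)
  z[3:7, 3:7, 3:7] <- 4
  z[5, 5, 5] <- 9                      # the peak
  p[3:7, 3:7, 3:7] <- 1e-6
  aff <- diag(c(2, 2, 2, 1))
  tab <- threshold_clusters(list(z = z, p = p, affine = aff),
                            p_threshold = 0.001, k_min = 10)
  expect_identical(nrow(tab), 1L)
  expect_identical(c(tab$peak_i, tab$peak_j, tab$peak_k), c(5L, 5L, 5L))
  # NIfTI affines address 0-based voxels: array index 5 is voxel 4
  expect_equal(c(tab$peak_x, tab$peak_y, tab$peak_z), c(8, 8, 8))
  expect_equal(tab$peak_z_stat, 9)
  lab <- attr(tab, "labels")
  expect_identical(sum(lab == 1L), 125L)
})

test_that("positive and negative effects never share a cluster", {
  dims <- c(10, 6, 6)
  z <- array(0, dims); p <- array(1, dims)
  z[1:4, 1:3, 1:3] <- 5;  p[1:4, 1:3, 1:3] <- 1e-5
  z[5:8, 1:3, 1:3] <- -5; p[5:8, 1:3, 1:3] <- 1e-5  # touching block, other sign
  tab <- threshold_clusters(list(z = z, p = p, affine = diag(4)),
                            p_threshold = 0.001, k_min = 5)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$sign, c("positive", "negative"))
})

test_that("an empty cluster table has the full schema", {
  z <- array(0, c(5, 5, 5)); p <- array(1, c(5, 5, 5))
  tab <- threshold_clusters(list(z = z, p = p, affine = diag(4)))
  expect_identical(nrow(tab), 0L)
  expect_true(all(c("cluster", "sign", "n_voxels", "peak_x", "peak_z_stat",
                    "peak_p") %in% names(tab)))
  path <- tempfile(fileext = ".csv")
  write_cluster_table(tab, path)
  expect_identical(nrow(read.csv(path)), 0L)
})

test_that("dice coefficient matches its definition", {
  lab <- array(0L, c(4, 4, 4))
  lab[1:2, 1:2, 1] <- 1L
  ref <- array(FALSE, c(4, 4, 4))
  ref[1:2, 1:4, 1] <- TRUE
  expect_equal(dice_coefficient(lab, 1L, ref), 2 * 4 / (4 + 8))
  expect_true(is.na(dice_coefficient(array(0L, c(2, 2, 2)), 1L,
                                     array(FALSE, c(2, 2, 2)))))
})
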