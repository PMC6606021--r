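test_that("Gauss-Hermite rules integrate normal moments exactly", {
  g <- voxelsem:::gh_grid(15, 2)
  expect_equal(sum(g$w), 1, tolerance = 1e-12)
  expect_equal(colSums(g$w * sqrt(2) * g$Z), c(0, 0), tolerance = 1e-12)
  expect_equal(colSums(g$w * 2 * g$Z^2), c(1, 1), tolerance = 1e-12)
  g0 <- voxelsem:::gh_grid(15, 0)
  expect_identical(dim(g0$Z), c(1L, 0L))
  expect_equal(g0$w, 1)
})

test_that("the marginal likelihood responds sensibly to parameter quality", {
  toy <- random_toy_case(seed = 991, q = 4)
  ll <- marginal_loglik(toy$params, toy$data, toy$spec)
  expect_true(is.finite(ll))
  worse <- toy$params
  worse$mu <- worse$mu + 5
  expect_lt(marginal_loglik(worse, toy$data, toy$spec), ll)
})

test_that("quadrature resolution is converged at the default node count", {
  toy <- random_toy_case(seed = 992, q = 4)
  s15 <- toy$spec
  s31 <- growth_spec(growth_discrete = s15$growth_discrete,
                     growth_continuous = s15$growth_continuous,
                     link = s15$link,
                     covariate_paths = s15$covariate_paths, n_quad = 31)
  expect_lt(abs(marginal_loglik(toy$params, toy$data, s15) -
                  marginal_loglik(toy$params, toy$data, s31)), 1e-7)
})

test_that("implied moments follow the growth structure", {
  f <- c("Sd", "Id", "Ic", "Sc")
  psi <- diag(c(0.1, 0.2, 0.6, 0.2)); dimnames(psi) <- list(f, f)
  psi["Ic", "Sc"] <- psi["Sc", "Ic"] <- -0.05
  p <- two_part_params(c(Sd = 0.1, Id = 0.5, Ic = 1, Sc = 0.4),
                       psi, theta = 0.5)
  m <- implied_moments(p, growth_spec())
  expect_equal(m$mean, 1 + 0.4 * (0:2))
  Lam <- cbind(1, 0:2)
  expect_equal(m$cov,
               Lam %*% psi[c("Ic", "Sc"), c("Ic", "Sc")] %*% t(Lam) +
                 diag(0.5, 3))
})

test_that("subjects with no observations contribute nothing", {
  b <- matrix(c(1, NA, 1, NA, 0, NA), 2, 3)
  y <- matrix(c(2, NA, 1.5, NA, NA, NA), 2, 3)
  d <- two_part_data(b, y)
  d1 <- two_part_data(b[1, , drop = FALSE], y[1, , drop = FALSE])
  f <- c("Sd", "Id", "Ic", "Sc")
  psi <- diag(c(0.1, 0.2, 0.5, 0.1)); dimnames(psi) <- list(f, f)
  p <- two_part_params(setNames(c(0.2, 0.5, 1, 0.3), f), psi,
                       theta = c(0.5, 0.5, 0.5))
  s <- growth_spec()
  expect_equal(marginal_loglik(p, d, s), marginal_loglik(p, d1, s))
})

test_that("wald test matches the normal reference", {
  w <- wald_test(1.96, 1)
  expect_equal(w$z, 1.96)
  expect_equal(w$p, 2 * pnorm(-1.96))
  expect_error(wald_test(1, 0), "positive")
})
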