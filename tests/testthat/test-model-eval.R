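test_that("likelihood-ratio test computes, clips and warns correctly", {
  lr <- likelihood_ratio_test(-110, -100, 3)
  expect_equal(lr$delta_chi2, 20)
  expect_equal(lr$p, pchisq(20, 3, lower.tail = FALSE))
  expect_warning(lr2 <- likelihood_ratio_test(-99.9, -100, 2), "clipping")
  expect_equal(lr2$delta_chi2, 0)
  expect_equal(lr2$delta_chi2_signed, -0.2)
  expect_equal(lr2$p, 1)
  expect_error(likelihood_ratio_test(-1, -1, 0), "positive")
})

test_that("rmsea is zero when chi-square does not exceed its df", {
  expect_equal(rmsea(50, 65, 1000), 0)
  expect_gt(rmsea(100, 65, 1000), 0)
})

test_that("cfi is clipped into the unit interval and handles a perfect model", {
  expect_equal(cfi(60, 65, 900, 78), 1)
  expect_equal(cfi(65, 65, 65, 78), 1)
  v <- cfi(200, 65, 900, 78)
  expect_true(v > 0 && v < 1)
  expect_equal(v, 1 - (200 - 65) / (900 - 78))
})

test_that("srmr matches a hand-computed standardized residual", {
  S <- diag(2); Sig <- diag(2)
  Sig[1, 2] <- Sig[2, 1] <- 0.5
  # residuals over the lower triangle incl. diagonal: 0, -0.5, 0
  expect_equal(srmr(S, Sig), sqrt(0.25 / 3))
  obs <- list(mean = c(1, 1), cov = S)
  imp <- list(mean = c(0, 1), cov = Sig)
  expect_equal(srmr(obs, imp), sqrt((0.25 + 1) / 5))
  expect_equal(srmr(obs, imp, include_means = FALSE), sqrt(0.25 / 3))
})

test_that("information criteria penalize parameters as defined", {
  ic <- information_criteria(-100, 5, 200)
  expect_equal(ic$aic, 210)
  expect_equal(ic$bic, 200 + 5 * log(200))
})

test_that("EM moments under missingness match mvtnorm-based likelihood maximization", {
  set.seed(5)
  n <- 400
  Sig <- matrix(c(1, 0.5, 0.3, 0.5, 1.2, 0.4, 0.3, 0.4, 0.9), 3, 3)
  Y <- MASS::mvrnorm(n, c(0, 1, 2), Sig)
  # complete data: EM must equal the closed-form MLE (divisor n)
  m <- voxelsem:::mvn_fiml_moments(Y)
  expect_equal(m$mean, colMeans(Y), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(m$cov, cov(Y) * (n - 1) / n, tolerance = 1e-5,
               ignore_attr = TRUE)
  # with MCAR holes: EM moments must attain a higher FIML likelihood than
  # naive complete-case moments
  Ym <- Y
  Ym[sample(length(Ym), 200)] <- NA
  Ym <- Ym[rowSums(!is.na(Ym)) > 0, ]
  mm <- voxelsem:::mvn_fiml_moments(Ym)
  cc <- Ym[complete.cases(Ym), ]
  ll_em <- voxelsem:::mvn_fiml_loglik(Ym, mm$mean, mm$cov)
  ll_cc <- voxelsem:::mvn_fiml_loglik(Ym, colMeans(cc),
                                      cov(cc) * (nrow(cc) - 1) / nrow(cc))
  expect_gt(ll_em, ll_cc)
  # the FIML likelihood evaluator agrees with the mvtnorm oracle
  expect_equal(ll_em, mvn_loglik_rows(Ym, mm$mean, mm$cov),
               tolerance = 1e-8)
})

test_that("fit indices of a well-specified continuous growth model look healthy", {
  d <- sim_growth_cohort(600, seed = 42)
  fit <- fit_twopart(d, growth_spec(parts = "continuous"), se = FALSE)
  fi <- fit_indices(fit, d)
  expect_true(fi$df > 0)
  expect_lt(fi$rmsea, 0.08)
  expect_gt(fi$cfi, 0.9)
  expect_lt(fi$srmr, 0.08)
  expect_equal(fi$n, 600)
})

test_that("model comparison table chains likelihood-ratio tests", {
  d <- sim_growth_cohort(400, seed = 43)
  f0 <- fit_twopart(d, growth_spec(parts = "continuous",
                                   growth_continuous = "intercept_only"),
                    se = FALSE)
  f1 <- fit_twopart(d, growth_spec(parts = "continuous"), se = FALSE)
  tab <- compare_models(list(flat = f0, linear = f1))
  expect_identical(tab$model, c("flat", "linear"))
  expect_true(is.na(tab$delta_chi2[1]))
  expect_equal(tab$delta_chi2[2], 2 * (f1$loglik - f0$loglik))
  expect_lt(tab$p[2], 1e-10)  # the cohort has a real slope
})
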