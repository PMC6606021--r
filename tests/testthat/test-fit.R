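test_that("the unconstrained parameterization round-trips", {
  spec <- growth_spec(equal_residuals = FALSE)
  lay <- voxelsem:::model_layout(spec, c("sex"))
  mu <- c(0.2, 0.5, 0.7, 0.4)
  L <- diag(c(0.3, 0.25, 0.8, 0.4))
  L[2, 1] <- -0.1; L[4, 3] <- -0.2; L[3, 2] <- 0.15
  theta <- c(0.4, 0.5, 0.6)
  gamma <- c(-0.2)
  xi <- voxelsem:::pack_xi(mu, L, theta, gamma, lay)
  expect_identical(names(xi), voxelsem:::xi_names(lay))
  st <- voxelsem:::unpack_xi(xi, lay, 3)
  expect_equal(unname(st$mu), mu)
  expect_equal(st$L, L)
  expect_equal(st$theta, theta)
  expect_equal(unname(st$gamma), gamma)

  spec_eq <- growth_spec(equal_residuals = TRUE)
  lay_eq <- voxelsem:::model_layout(spec_eq)
  xi_eq <- voxelsem:::pack_xi(mu, L, 0.5, numeric(0), lay_eq)
  st_eq <- voxelsem:::unpack_xi(xi_eq, lay_eq, 3)
  expect_equal(st_eq$theta, rep(0.5, 3))
})

test_that("the analytic gradient matches numerical differentiation", {
  toy <- random_toy_case(seed = 881, q = 4)
  prep <- voxelsem:::tp_prepare(toy$data, toy$spec)
  st <- voxelsem:::tp_structured(toy$params, prep, toy$spec)
  xi <- voxelsem:::pack_xi(st$mu, st$L, st$theta, st$gamma, prep$layout)
  obj <- voxelsem:::make_objective(prep, toy$spec)
  g_num <- numDeriv::grad(obj$loglik_only, xi)
  expect_equal(unname(obj$grad_only(xi)), g_num, tolerance = 1e-6)
})

test_that("per-subject scores sum to the analytic gradient", {
  toy <- random_toy_case(seed = 882, q = 4)
  prep <- voxelsem:::tp_prepare(toy$data, toy$spec)
  st <- voxelsem:::tp_structured(toy$params, prep, toy$spec)
  xi <- voxelsem:::pack_xi(st$mu, st$L, st$theta, st$gamma, prep$layout)
  S <- voxelsem:::score_matrix_xi(xi, prep, toy$spec)
  obj <- voxelsem:::make_objective(prep, toy$spec)
  expect_equal(unname(colSums(S)), unname(obj$grad_only(xi)),
               tolerance = 1e-8)
  expect_identical(colnames(S), voxelsem:::xi_names(prep$layout))
})

test_that("a continuous growth model is fitted consistently at moderate N", {
  d <- sim_growth_cohort(800, seed = 552)
  fit <- fit_twopart(d, growth_spec(parts = "continuous"), se = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["mean.Ic"]] - 0.693), 0.12)
  expect_lt(abs(fit$estimates[["mean.Sc"]] - 0.498), 0.10)
  expect_lt(abs(fit$estimates[["var.Ic"]] - 0.618), 0.20)
  expect_false(is.null(fit$se))
  expect_true(all(fit$se[c("mean.Ic", "mean.Sc")] > 0))
  sm <- summary(fit)
  expect_true(all(c("term", "estimate", "se", "z", "p") %in% names(sm)))
  expect_true(sm$p[sm$term == "mean.Ic"] < 0.001)
})

test_that("a small two-part fit converges and reports a voxel coefficient", {
  cfg <- synthetic_config(n_subjects = 300, n_sites = 1,
                          gamma = c(sex = -0.183))
  traj <- generate_trajectories(cfg, seed = 97)
  d <- two_part_data(traj$data$binary, traj$data$continuous,
                     traj$data$covariates["sex"],
                     traj$data$occasion_times)
  spec <- growth_spec(equal_residuals = TRUE, n_quad = 7)
  sc_std <- scale(traj$truth$eta[, "Sc"])[, 1]
  vox <- 0.8 * sc_std + rnorm(length(sc_std), 0, 0.6)
  fit <- fit_twopart(d, spec, voxel = vox, se = FALSE,
                     gradient_tol = 1e-4)
  expect_true(fit$converged)
  expect_true("beta_voxel" %in% names(fit$params$gamma))
  expect_gt(fit$estimates[["gamma.beta_voxel"]], 0)
  # logLik / coef accessors
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_identical(coef(fit), fit$estimates)
})

test_that("warm-started scored optimizers agree with the reference optimizer", {
  d <- sim_growth_cohort(300, seed = 553)
  spec <- growth_spec(parts = "continuous", equal_residuals = TRUE)
  prep <- voxelsem:::tp_prepare(d, spec)
  xi0 <- voxelsem:::auto_init_xi(prep, spec)
  ref <- voxelsem:::fit_xi(prep, spec, xi0)
  bh <- voxelsem:::fit_xi_bhhh(prep, spec, ref$xi + 0.05)
  expect_false(is.null(bh))
  expect_equal(bh$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(bh$xi), unname(ref$xi), tolerance = 1e-3)
  obj <- voxelsem:::make_objective(prep, spec)
  H <- numDeriv::jacobian(function(z) -obj$grad_only(z), ref$xi,
                          method = "simple")
  H_env <- new.env(); H_env$chol <- chol((H + t(H)) / 2)
  ch <- voxelsem:::fit_xi_chord(prep, spec, ref$xi + 0.05, H_env)
  expect_false(is.null(ch))
  expect_equal(ch$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("degenerate score directions are profiled out of the OPG covariance", {
  S <- cbind(a = rnorm(50), b = rnorm(50), c = rep(0, 50))
  V <- voxelsem:::opg_from_scores(S)
  expect_true(all(is.na(V[, "c"])))
  expect_true(all(is.finite(diag(V)[c("a", "b")])))
})
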