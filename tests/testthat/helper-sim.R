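# Small simulators used across the suite. Where independence from the
# package's own generator matters (oracle and calibration tests), data are
# built directly here rather than through synthetic_config().

# One-part normal growth cohort coded as a two_part_data with universal use.
# intercept_only = TRUE draws a flat truth (no slope factor at all).
sim_growth_cohort <- function(n, seed, intercept_only = FALSE,
                              mu = c(Ic = 0.693, Sc = 0.498),
                              var_ic = 0.618, var_sc = 0.218,
                              cov_icsc = -0.078, theta = 0.5,
                              times = 0:2) {
  set.seed(seed)
  T_ <- length(times)
  ic <- rnorm(n, mu[["Ic"]], sqrt(var_ic))
  if (intercept_only) {
    sc <- rep(0, n)
  } else {
    cond_var <- var_sc - cov_icsc^2 / var_ic
    sc <- mu[["Sc"]] + cov_icsc / var_ic * (ic - mu[["Ic"]]) +
      rnorm(n, 0, sqrt(cond_var))
  }
  y <- sapply(times, function(t) ic + t * sc + rnorm(n, 0, sqrt(theta)))
  two_part_data(matrix(1, n, T_), y, NULL, times)
}

# Tiny randomized two-part dataset + parameters + spec for the
# brute-force quadrature oracle. q is the total latent dimension.
random_toy_case <- function(seed, q = 4) {
  set.seed(seed)
  n <- sample(4:8, 1)
  T_ <- 3
  growth_d <- if (q >= 4 || (q == 3 && runif(1) < 0.5)) "linear" else
    "intercept_only"
  growth_c <- if (q >= 4 || (q == 3 && growth_d == "intercept_only"))
    "linear" else "intercept_only"
  with_cov <- runif(1) < 0.6
  cov_target <- if (growth_c == "linear") "Sc" else "Ic"
  spec <- growth_spec(growth_discrete = growth_d,
                      growth_continuous = growth_c,
                      link = sample(c("logit", "probit"), 1),
                      covariate_paths = if (with_cov)
                        c(x = cov_target) else NULL,
                      # oracle comparisons need both sides converged: 41
                      # nodes per discrete dimension puts the marginal
                      # likelihood's own quadrature error well below the
                      # 1e-6 comparison tolerance for every random draw
                      n_quad = 41)
  lay <- voxelsem:::model_layout(spec)
  f <- lay$factors
  qq <- lay$q
  A <- matrix(rnorm(qq * qq, 0, 0.3), qq, qq)
  psi <- A %*% t(A) + diag(runif(qq, 0.05, 0.4))
  dimnames(psi) <- list(f, f)
  mu <- setNames(runif(qq, -0.5, 1), f)
  theta <- runif(T_, 0.3, 0.9)
  x <- rnorm(n)
  gamma <- if (with_cov) c(x = runif(1, -0.5, 0.5)) else numeric(0)
  # latent draws -> semicontinuous outcomes
  eta <- MASS::mvrnorm(n, mu, psi)
  if (with_cov) {
    tgt <- match(cov_target, f)
    eta[, tgt] <- eta[, tgt] + gamma[["x"]] * x
  }
  Lam_d <- lay$Lam_d
  Lam_c <- lay$Lam_c
  linkinv <- if (spec$link == "probit") pnorm else plogis
  b <- cont <- matrix(NA_real_, n, T_)
  for (t in seq_len(T_)) {
    pr <- linkinv(drop(Lam_d[t, , drop = FALSE] %*%
                         t(eta[, seq_len(lay$qd), drop = FALSE])))
    b[, t] <- rbinom(n, 1, pr)
    yc <- drop(Lam_c[t, , drop = FALSE] %*%
                 t(eta[, lay$qd + seq_len(lay$qc), drop = FALSE])) +
      rnorm(n, 0, sqrt(theta[t]))
    cont[, t] <- ifelse(b[, t] == 1, yc, NA_real_)
    gone <- runif(n) < 0.15
    b[gone, t] <- NA_real_
    cont[gone, t] <- NA_real_
  }
  covs <- if (with_cov) data.frame(x = x) else NULL
  data <- two_part_data(b, cont, covs, spec$time_scores)
  params <- two_part_params(mu = mu, psi = psi, theta = theta, gamma = gamma)
  list(data = data, params = params, spec = spec)
}
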