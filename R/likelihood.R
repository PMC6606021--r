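# ---- internal: assemble C++ inputs for a dataset/spec pair ------------------

tp_prepare <- function(data, spec, voxel = NULL) {
  stopifnot(inherits(data, "two_part_data"), inherits(spec, "growth_spec"))
  if (ncol(data$binary) != spec$n_occasions) {
    stop("data has ", ncol(data$binary), " occasions but spec declares ",
         spec$n_occasions)
  }
  cov_names <- if (is.null(data$covariates)) character(0) else
    names(data$covariates)
  layout <- model_layout(spec, cov_names, voxel = !is.null(voxel))
  check_identified(spec, layout)
  n <- nrow(data$binary)
  X <- if (length(cov_names)) {
    m <- as.matrix(data$covariates)
    if (!is.numeric(m)) stop("covariates must be numeric (dummy-code factors)")
    m
  } else matrix(0, n, 0)
  if (!is.null(voxel)) {
    if (length(voxel) != n) stop("voxel predictor length must equal n subjects")
    X <- cbind(X, voxel)
  }
  Yb <- data$binary
  Yc <- data$continuous
  if (spec$parts == "continuous") Yb <- matrix(NA_real_, n, spec$n_occasions)
  if (spec$parts == "discrete") Yc <- matrix(NA_real_, n, spec$n_occasions)
  grid <- gh_grid(spec$n_quad, layout$qd)
  list(layout = layout, X = X, Yb = Yb, Yc = Yc, grid = grid,
       n = n, T = spec$n_occasions)
}

# structured params -> (mu, L, theta, gamma) in internal layout order
tp_structured <- function(params, prep, spec) {
  layout <- prep$layout
  mu <- params$mu[layout$factors]
  if (anyNA(mu)) stop("params$mu must name all factors: ",
                      paste(layout$factors, collapse = ", "))
  psi <- params$psi[layout$factors, layout$factors, drop = FALSE]
  L <- chol_psd(psi)
  theta <- params$theta
  if (layout$n_theta > 0L) {
    if (length(theta) == 1L) theta <- rep(theta, spec$n_occasions)
    if (length(theta) != spec$n_occasions) {
      stop("theta must have length 1 or n_occasions")
    }
  } else theta <- numeric(0)
  gamma <- setNames(numeric(length(layout$cov_names)), layout$cov_names)
  if (length(params$gamma)) {
    nm <- intersect(names(params$gamma), names(gamma))
    gamma[nm] <- params$gamma[nm]
    if ("beta_voxel" %in% names(params$gamma) && ".voxel" %in% names(gamma)) {
      gamma[".voxel"] <- params$gamma[["beta_voxel"]]
    }
  }
  list(mu = as.numeric(mu), L = L, theta = theta, gamma = as.numeric(gamma))
}

tp_call <- function(st, prep, want_grad = FALSE) {
  lay <- prep$layout
  cpp_tp_eval(st$mu, st$L, st$theta, st$gamma, lay$qd,
              prep$Yb, prep$Yc, prep$X, lay$path_idx,
              lay$Lam_d, lay$Lam_c, lay$link_code,
              prep$grid$Z, prep$grid$w, want_grad)
}

#' Marginal log-likelihood of the two-part growth model
#'
#' Integrates the latent growth factors out of the joint
#' Bernoulli-times-normal observation model: the continuous-part latents are
#' marginalized in closed form conditional on the discrete-part latents, and
#' the discrete-part latents are integrated by prior-scaled Gauss-Hermite
#' quadrature (`spec$n_quad` nodes per dimension). Missing binary cells drop
#' their Bernoulli factor and missing continuous cells (including structural
#' missingness at non-use occasions) drop their normal factor, the
#' missing-at-random treatment. Subjects with no observed cells contribute
#' zero.
#'
#' @param params a [two_part_params()] object.
#' @param data a [two_part_data()] object.
#' @param spec a [growth_spec()].
#' @param voxel optional numeric per-subject predictor entering the mean of
#'   `spec$predictor_target` with coefficient `params$gamma["beta_voxel"]`.
#' @return log-likelihood (scalar); `-Inf` when the parameter point is
#'   infeasible (e.g. a singular implied covariance).
#' @export
marginal_loglik <- function(params, data, spec, voxel = NULL) {
  prep <- tp_prepare(data, spec, voxel)
  st <- tp_structured(params, prep, spec)
  res <- tp_call(st, prep, want_grad = FALSE)
  if (!isTRUE(res$ok)) return(-Inf)
  res$loglik
}

#' Brute-force reference log-likelihood
#'
#' Evaluates the same marginal likelihood by tensor-product Gauss-Hermite
#' quadrature jointly over ALL latent factors, with no analytic
#' factorization. The grid for each subject is centered at the posterior
#' mode of the full integrand and scaled by its curvature (found
#' numerically, without reusing any of the analytic machinery), which is
#' required for the rule to converge on the slowly decaying binary-part
#' factors. Exponentially expensive; intended as an independent
#' verification oracle on toy datasets only.
#'
#' @inheritParams marginal_loglik
#' @param n_nodes quadrature nodes per latent dimension (at least 20).
#' @return log-likelihood (scalar).
#' @export
loglik_bruteforce <- function(params, data, spec, voxel = NULL, n_nodes = 40) {
  prep <- tp_prepare(data, spec, voxel)
  lay <- prep$layout
  if (prep$n > 10) stop("brute-force oracle is restricted to <= 10 subjects")
  if (lay$q > 4) stop("brute-force oracle supports at most 4 latent dimensions")
  if (n_nodes < 20) stop("too few quadrature nodes for a reference evaluation")
  st <- tp_structured(params, prep, spec)
  if (any(diag(st$L) <= 0)) {
    stop("brute-force oracle requires a positive-definite latent covariance")
  }
  r <- gh_rule(n_nodes)
  q <- lay$q
  # subject mean offsets
  O <- matrix(0, prep$n, q)
  for (j in seq_along(lay$path_idx)) {
    O[, lay$path_idx[j] + 1L] <- O[, lay$path_idx[j] + 1L] +
      st$gamma[j] * prep$X[, j]
  }
  prior_logdet <- sum(log(diag(st$L)))
  idx_grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_nodes)), q)))
  Ktot <- nrow(idx_grid)
  chunk <- 200000L
  total <- 0
  for (i in seq_len(prep$n)) {
    yb <- prep$Yb[i, ]; yc <- prep$Yc[i, ]
    ob <- which(!is.na(yb)); oc <- which(!is.na(yc))
    if (length(ob) == 0L && length(oc) == 0L) next
    m_i <- st$mu + O[i, ]
    # joint log density of (eta, observed data) at rows of eta-matrix E
    log_integrand <- function(E) {
      U <- forwardsolve(st$L, t(E) - m_i)
      lk <- -0.5 * colSums(U^2) - prior_logdet - q / 2 * log(2 * pi)
      if (lay$qd > 0 && length(ob)) {
        A <- E[, seq_len(lay$qd), drop = FALSE] %*%
          t(lay$Lam_d[ob, , drop = FALSE])
        for (jj in seq_along(ob)) {
          a <- A[, jj]
          if (lay$link_code == 0L) {
            lk <- lk + if (yb[ob[jj]] > 0.5) plogis(a, log.p = TRUE) else
              plogis(-a, log.p = TRUE)
          } else {
            lk <- lk + pnorm(a, log.p = TRUE,
                             lower.tail = yb[ob[jj]] > 0.5)
          }
        }
      }
      if (lay$qc > 0 && length(oc)) {
        Mu <- E[, lay$qd + seq_len(lay$qc), drop = FALSE] %*%
          t(lay$Lam_c[oc, , drop = FALSE])
        for (jj in seq_along(oc)) {
          lk <- lk + dnorm(yc[oc[jj]], Mu[, jj], sqrt(st$theta[oc[jj]]),
                           log = TRUE)
        }
      }
      lk
    }
    # center and scale the grid at the posterior mode of the integrand
    opt <- stats::optim(m_i,
                        function(e) -log_integrand(matrix(e, 1L)),
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500, reltol = 1e-14))
    H <- (opt$hessian + t(opt$hessian)) / 2
    C <- tryCatch(t(chol(solve(H))), error = function(e) st$L)
    scale_logdet <- sum(log(diag(C))) + q / 2 * log(2)
    pieces <- numeric(0)
    for (start in seq(1L, Ktot, by = chunk)) {
      rows <- start:min(start + chunk - 1L, Ktot)
      Zc <- matrix(r$x[idx_grid[rows, , drop = FALSE]], ncol = q)
      logw <- rowSums(matrix(log(r$w)[idx_grid[rows, , drop = FALSE]],
                             ncol = q)) + rowSums(Zc^2)
      E <- sweep(sqrt(2) * Zc %*% t(C), 2, opt$par, "+")
      lk <- logw + log_integrand(E)
      mx <- max(lk)
      pieces <- c(pieces, if (is.finite(mx))
        mx + log(sum(exp(lk - mx))) else -Inf)
    }
    mx <- max(pieces)
    total <- total + scale_logdet + mx + log(sum(exp(pieces - mx)))
  }
  total
}

#' Model-implied moments of the continuous indicators
#'
#' Mean `Lambda_c mu_c` (plus the covariate contribution at supplied
#' covariate means, if any) and covariance
#' `Lambda_c Psi_cc Lambda_c' + diag(theta)`.
#'
#' @inheritParams marginal_loglik
#' @param covariate_means optional named numeric vector of covariate means;
#'   their regression contributions shift the implied mean.
#' @return list with elements `mean` and `cov`.
#' @export
implied_moments <- function(params, spec, covariate_means = NULL) {
  layout <- model_layout(spec, names(covariate_means) %||% character(0))
  if (layout$qc == 0L) stop("model has no continuous part")
  cf <- layout$factors[layout$qd + seq_len(layout$qc)]
  mu_c <- params$mu[cf]
  if (!is.null(covariate_means)) {
    for (j in seq_along(covariate_means)) {
      f <- layout$path_idx[j] + 1L
      if (f > layout$qd) {
        mu_c[f - layout$qd] <- mu_c[f - layout$qd] +
          params$gamma[[names(covariate_means)[j]]] * covariate_means[[j]]
      }
    }
  }
  Lam <- layout$Lam_c
  psi_cc <- params$psi[cf, cf, drop = FALSE]
  theta <- params$theta
  if (length(theta) == 1L) theta <- rep(theta, spec$n_occasions)
  list(mean = as.numeric(Lam %*% mu_c),
       cov = Lam %*% psi_cc %*% t(Lam) + diag(theta, spec$n_occasions))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wald test for a single parameter
#'
#' @param estimate point estimate.
#' @param se standard error (positive).
#' @return list with `z` and two-sided `p`.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stop("standard error must be positive")
  z <- estimate / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}
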