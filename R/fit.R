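# ---- internal optimization machinery ----------------------------------------

# closure caching the most recent (xi, value, gradient) so that nlminb's
# separate objective/gradient calls cost one likelihood evaluation
make_objective <- function(prep, spec) {
  lay <- prep$layout
  cache <- new.env(parent = emptyenv())
  cache$xi <- NULL
  evaluate <- function(xi) {
    st <- unpack_xi(xi, lay, spec$n_occasions)
    res <- tp_call(st, prep, want_grad = TRUE)
    if (!isTRUE(res$ok) || !is.finite(res$loglik)) {
      cache$xi <- xi; cache$f <- 1e10; cache$g <- rep(0, length(xi))
      return(invisible(NULL))
    }
    g <- chain_xi_grad(list(dmu = res$dmu, dL = res$dL,
                            dtheta = res$dtheta, dgamma = res$dgamma),
                       st, lay)
    cache$xi <- xi; cache$f <- -res$loglik; cache$g <- -g
    invisible(NULL)
  }
  list(
    fn = function(xi) {
      if (is.null(cache$xi) || !identical(xi, cache$xi)) evaluate(xi)
      cache$f
    },
    gr = function(xi) {
      if (is.null(cache$xi) || !identical(xi, cache$xi)) evaluate(xi)
      cache$g
    },
    loglik_only = function(xi) {
      st <- unpack_xi(xi, lay, spec$n_occasions)
      res <- tp_call(st, prep, want_grad = FALSE)
      if (!isTRUE(res$ok)) return(-Inf)
      res$loglik
    },
    grad_only = function(xi) {
      st <- unpack_xi(xi, lay, spec$n_occasions)
      res <- tp_call(st, prep, want_grad = TRUE)
      if (!isTRUE(res$ok)) return(rep(NA_real_, length(xi)))
      chain_xi_grad(list(dmu = res$dmu, dL = res$dL,
                         dtheta = res$dtheta, dgamma = res$dgamma),
                    st, lay)
    })
}

# moment-based starting values
auto_init_xi <- function(prep, spec) {
  lay <- prep$layout
  T_ <- spec$n_occasions
  q <- lay$q
  mu <- rep(0, q); psi_diag <- rep(0.2, q)
  L <- diag(sqrt(psi_diag), q)
  theta <- rep(1, if (lay$n_theta) T_ else 0)
  if (lay$qd > 0) {
    p_t <- pmin(pmax(colMeans(prep$Yb == 1, na.rm = TRUE), 0.02), 0.98)
    p_t[is.na(p_t)] <- 0.5
    eta_t <- if (spec$link == "probit") qnorm(p_t) else qlogis(p_t)
    co <- tryCatch(qr.solve(lay$Lam_d, eta_t), error = function(e) rep(0, lay$qd))
    mu[seq_len(lay$qd)] <- co
    psi_diag[seq_len(lay$qd)] <- 0.3
  }
  if (lay$qc > 0) {
    m_t <- colMeans(prep$Yc, na.rm = TRUE)
    v_t <- apply(prep$Yc, 2, var, na.rm = TRUE)
    m_t[is.na(m_t)] <- 0; v_t[is.na(v_t) | v_t <= 0] <- 1
    co <- tryCatch(qr.solve(lay$Lam_c, m_t), error = function(e) rep(0, lay$qc))
    mu[lay$qd + seq_len(lay$qc)] <- co
    psi_diag[lay$qd + 1L] <- max(0.05, 0.5 * mean(v_t))    # intercept factor
    if (lay$qc > 1) psi_diag[lay$qd + 2L] <- max(0.02, 0.1 * mean(v_t))
    if (lay$qc > 2) psi_diag[lay$qd + 3L] <- 0.02
    theta <- pmax(0.5 * v_t, 0.05)
    if (lay$n_theta == 1L) theta <- rep(mean(theta), T_)
  }
  L <- diag(sqrt(psi_diag), q)
  gamma <- rep(0, length(lay$cov_names))
  pack_xi(mu, L, if (lay$n_theta) theta else numeric(0), gamma, lay)
}

fit_xi <- function(prep, spec, xi0, max_iter = 500) {
  obj <- make_objective(prep, spec)
  opt <- nlminb(xi0, obj$fn, obj$gr,
                control = list(iter.max = max_iter, eval.max = 4 * max_iter))
  g <- obj$grad_only(opt$par)
  gnorm <- if (anyNA(g)) Inf else max(abs(g))
  list(xi = opt$par, loglik = -opt$objective,
       nlminb_convergence = opt$convergence, gradient_norm = gnorm,
       message = opt$message)
}

# structured coefficient vector (natural scale) from xi; used for reporting
# and for the delta method
structured_vector <- function(xi, lay, n_occasions) {
  st <- unpack_xi(xi, lay, n_occasions)
  psi <- st$L %*% t(st$L)
  f <- lay$factors
  out <- setNames(st$mu, paste0("mean.", f))
  for (s in seq_len(lay$q)) for (r in s:lay$q) {
    if (lay$Lmask[r, s] || r == s) {
      nm <- if (r == s) paste0("var.", f[r]) else paste0("cov.", f[r], "_", f[s])
      out[nm] <- psi[r, s]
    }
  }
  if (lay$n_theta == 1L) {
    out["theta"] <- st$theta[1L]
  } else if (lay$n_theta > 1L) {
    out[paste0("theta.t", seq_len(lay$n_theta))] <-
      st$theta[seq_len(lay$n_theta)]
  }
  if (length(st$gamma)) {
    out[paste0("gamma.", sub("^\\.voxel$", "beta_voxel", names(st$gamma)))] <-
      st$gamma
  }
  out
}

#' Fit the two-part latent growth curve model by maximum likelihood
#'
#' Quasi-Newton maximization of [marginal_loglik()] on an unconstrained
#' parameterization (log-Cholesky for the latent covariance, log residual
#' variances), with multi-start protection: the moment-based automatic start
#' plus `n_starts - 1` jittered restarts, keeping the best log-likelihood.
#' The optimization is deterministic given `seed`.
#'
#' @param data a [two_part_data()] object.
#' @param spec a [growth_spec()].
#' @param init `"auto"` for moment-based starting values, or a
#'   [two_part_params()] object.
#' @param voxel optional per-subject predictor of `spec$predictor_target`
#'   (its coefficient is reported as `beta_voxel`).
#' @param n_starts number of optimization starts (first is unjittered).
#' @param jitter relative jitter of the extra starts.
#' @param seed RNG seed for the jittered starts.
#' @param se compute standard errors from the observed information.
#' @param max_iter optimizer iteration cap.
#' @param gradient_tol per-subject gradient tolerance declaring convergence.
#' @return object of class `twopart_fit`: estimates ([two_part_params()]),
#'   `loglik`, `converged`, `n_subjects_used`, `n_free_params`, `se`,
#'   `gradient_norm`, and the internal parameter vector.
#' @export
fit_twopart <- function(data, spec, init = "auto", voxel = NULL,
                        n_starts = 3, jitter = 0.1, seed = 20190702,
                        se = TRUE, max_iter = 500, gradient_tol = 1e-5) {
  prep <- tp_prepare(data, spec, voxel)
  lay <- prep$layout
  if (identical(init, "auto")) {
    xi0 <- auto_init_xi(prep, spec)
  } else {
    st <- tp_structured(init, prep, spec)
    xi0 <- pack_xi(st$mu, st$L,
                   if (lay$n_theta == 1L) st$theta[1L] else st$theta,
                   st$gamma, lay)
  }
  starts <- list(xi0)
  if (n_starts > 1) {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (s in seq_len(n_starts - 1)) {
      starts[[s + 1L]] <- xi0 + rnorm(length(xi0)) * jitter * pmax(abs(xi0), 0.5)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  best <- NULL
  for (xs in starts) {
    res <- tryCatch(fit_xi(prep, spec, xs, max_iter), error = function(e) NULL)
    if (is.null(res) || !is.finite(res$loglik)) next
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, loglik = NA_real_, converged = FALSE,
                          n_subjects_used = prep$n,
                          n_free_params = length(xi0), se = NULL,
                          gradient_norm = Inf, spec = spec,
                          message = "no start converged"),
                     class = "twopart_fit"))
  }
  n_used <- sum(rowSums(!is.na(prep$Yb)) + rowSums(!is.na(prep$Yc)) > 0)
  converged <- best$nlminb_convergence == 0 &&
    best$gradient_norm < gradient_tol * max(1, prep$n)
  st <- unpack_xi(best$xi, lay, spec$n_occasions)
  psi <- st$L %*% t(st$L)
  dimnames(psi) <- list(lay$factors, lay$factors)
  gamma <- st$gamma
  names(gamma) <- sub("^\\.voxel$", "beta_voxel", names(gamma))
  params <- two_part_params(
    mu = setNames(st$mu, lay$factors), psi = psi,
    theta = if (lay$n_theta == 1L) st$theta[1L] else st$theta,
    gamma = gamma)
  fit <- structure(list(params = params, loglik = best$loglik,
                        converged = converged,
                        n_subjects_used = n_used,
                        n_free_params = length(best$xi),
                        se = NULL, gradient_norm = best$gradient_norm,
                        xi = best$xi, spec = spec,
                        estimates = structured_vector(best$xi, lay,
                                                      spec$n_occasions)),
                   class = "twopart_fit")
  if (isTRUE(se) && converged) {
    fit$se <- tryCatch(standard_errors(fit, data, spec, voxel = voxel),
                       error = function(e) { warning(conditionMessage(e)); NULL })
  }
  fit
}

#' Standard errors from the observed information
#'
#' Numerical Hessian of the negative log-likelihood at the maximum (finite
#' differences of the analytic gradient), inverted and mapped to the natural
#' parameter scale (means, variances, covariances, residual variances,
#' regression coefficients) by the delta method.
#'
#' @param fit a converged [fit_twopart()] result.
#' @param data,spec,voxel the data, spec and optional voxel predictor the
#'   model was fitted to.
#' @param method finite-difference scheme passed to
#'   [numDeriv::jacobian()]: `"Richardson"` (accurate) or `"simple"` (fast).
#' @return named vector of standard errors aligned with `fit$estimates`, or
#'   `NULL` (with a warning) when the information matrix is not positive
#'   definite.
#' @export
standard_errors <- function(fit, data, spec, voxel = NULL,
                            method = "Richardson") {
  if (!isTRUE(fit$converged)) stop("standard errors require a converged fit")
  prep <- tp_prepare(data, spec, voxel)
  obj <- make_objective(prep, spec)
  H <- numDeriv::jacobian(function(x) -obj$grad_only(x), fit$xi,
                          method = method)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    warning("observed information is not positive definite; ",
            "standard errors unavailable")
    return(NULL)
  }
  V <- solve(H)
  J <- numDeriv::jacobian(function(x)
    structured_vector(x, prep$layout, spec$n_occasions), fit$xi,
    method = method)
  se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  setNames(se, names(fit$estimates))
}

#' @export
print.twopart_fit <- function(x, ...) {
  cat("<twopart_fit>\n")
  cat(sprintf("  logLik %.3f on %d free parameters, %d subjects%s\n",
              x$loglik, x$n_free_params, x$n_subjects_used,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @export
logLik.twopart_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free_params, class = "logLik")
}

#' @export
coef.twopart_fit <- function(object, ...) object$estimates

#' Coefficient table with Wald tests
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `se`, `z`, `p` (Wald z and
#'   two-sided p only where a standard error is available).
#' @export
summary.twopart_fit <- function(object, ...) {
  est <- object$estimates
  se <- object$se
  out <- tibble::tibble(term = names(est), estimate = as.numeric(est),
                        se = NA_real_, z = NA_real_, p = NA_real_)
  if (!is.null(se)) {
    out$se <- as.numeric(se[out$term])
    okv <- !is.na(out$se) & out$se > 0
    w <- wald_test(out$estimate[okv], out$se[okv])
    out$z[okv] <- w$z
    out$p[okv] <- w$p
  }
  out
}

# Per-subject score matrix on the unconstrained (xi) scale at xi.
# Columns follow xi_names(layout); rows are subjects.
# chain the raw natural-scale per-subject scores (columns: mu, full lower
# triangle of L column-major, theta per occasion, gamma) onto the xi scale
map_scores_xi <- function(S, st, lay, T_) {
  q <- lay$q
  cols <- list(S[, seq_len(q), drop = FALSE])
  pos <- q
  for (s in seq_len(q)) for (r in s:q) {
    pos <- pos + 1L
    if (lay$Lmask[r, s]) {
      col <- S[, pos]
      if (r == s) col <- col * st$L[r, r]
      cols <- c(cols, list(matrix(col)))
    }
  }
  if (lay$n_theta > 0L) {
    Sth <- S[, q + q * (q + 1) / 2 + seq_len(T_), drop = FALSE]
    th <- if (lay$n_theta == 1L) matrix(Sth %*% st$theta[seq_len(T_)]) else
      sweep(Sth, 2, st$theta, "*")
    cols <- c(cols, list(th))
  }
  p <- length(lay$cov_names)
  if (p > 0L) {
    cols <- c(cols, list(S[, ncol(S) - p + seq_len(p), drop = FALSE]))
  }
  do.call(cbind, cols)
}

score_matrix_xi <- function(xi, prep, spec) {
  lay <- prep$layout
  st <- unpack_xi(xi, lay, spec$n_occasions)
  res <- cpp_tp_eval(st$mu, st$L, st$theta, st$gamma, lay$qd,
                     prep$Yb, prep$Yc, prep$X, lay$path_idx,
                     lay$Lam_d, lay$Lam_c, lay$link_code,
                     prep$grid$Z, prep$grid$w,
                     want_grad = FALSE, want_scores = TRUE)
  out <- map_scores_xi(res$scores, st, lay, spec$n_occasions)
  colnames(out) <- xi_names(lay)
  out
}

# Chord-Newton maximization with a shared, prefactored negative-Hessian:
# xi <- xi + solve(H, grad) with step halving. Used for warm-started voxel
# refits, where one numerical Hessian is an excellent preconditioner for
# every voxel; per-voxel work is then a handful of analytic-gradient
# evaluations. `H_env` is an environment holding `chol` so that a Hessian
# refreshed at one voxel's optimum (where curvature is representative of
# all voxel optima) is reused by the rest of the sweep. Returns NULL when
# it fails (callers fall back to fit_xi_bhhh() / fit_xi()).
fit_xi_chord <- function(prep, spec, xi0, H_env, max_iter = 40,
                         tol = 1e-5) {
  H_chol <- H_env$chol
  lay <- prep$layout
  T_ <- spec$n_occasions
  eval_at <- function(xi, grad) {
    st <- unpack_xi(xi, lay, T_)
    if (any(!is.finite(st$L))) return(NULL)
    r <- cpp_tp_eval(st$mu, st$L, st$theta, st$gamma, lay$qd,
                     prep$Yb, prep$Yc, prep$X, lay$path_idx,
                     lay$Lam_d, lay$Lam_c, lay$link_code,
                     prep$grid$Z, prep$grid$w,
                     want_grad = grad, want_scores = FALSE)
    if (!isTRUE(r$ok) || !is.finite(r$loglik)) return(NULL)
    r$st <- st
    r
  }
  grad_xi <- function(r) {
    chain_xi_grad(list(dmu = r$dmu, dL = r$dL, dtheta = r$dtheta,
                       dgamma = r$dgamma), r$st, lay)
  }
  num_hess <- function(xi, g) {
    k <- length(xi)
    H <- matrix(0, k, k)
    for (j in seq_len(k)) {
      h <- 1e-6 * (1 + abs(xi[j]))
      xj <- xi; xj[j] <- xj[j] + h
      rj <- eval_at(xj, TRUE)
      if (is.null(rj)) return(NULL)
      H[, j] <- -(grad_xi(rj) - g) / h
    }
    (H + t(H)) / 2
  }
  cur <- eval_at(xi0, TRUE)
  if (is.null(cur)) return(NULL)
  xi <- xi0
  g <- grad_xi(cur)
  tol_abs <- tol * max(1, prep$n)
  refreshes <- 0L
  last_refresh <- 0L
  g_hist <- rep(Inf, max_iter + 1L)
  for (it in seq_len(max_iter)) {
    gmax <- max(abs(g))
    g_hist[it] <- gmax
    if (gmax < tol_abs) {
      return(list(xi = xi, loglik = cur$loglik, nlminb_convergence = 0L,
                  gradient_norm = gmax, message = "chord converged",
                  scores = NULL))
    }
    # the fixed Hessian has stopped paying off (gradient barely shrinking
    # over the last few steps): refresh it at the current point, after
    # which convergence is locally quadratic
    stalled <- it - last_refresh >= 3 && gmax > 0.5 * g_hist[it - 2L]
    if (stalled && refreshes < 2L) {
      Hn <- num_hess(xi, g)
      Hc <- NULL
      if (!is.null(Hn)) {
        ridge <- 0
        for (r in 1:4) {
          Hc <- tryCatch(chol(Hn + diag(ridge, length(g))),
                         error = function(e) NULL)
          if (!is.null(Hc)) break
          ridge <- max(ridge * 10, 1e-4 * max(abs(diag(Hn))))
        }
      }
      if (is.null(Hc)) return(NULL)
      H_chol <- Hc
      H_env$chol <- Hc
      refreshes <- refreshes + 1L
      last_refresh <- it
    }
    dir <- backsolve(H_chol, backsolve(H_chol, g, transpose = TRUE))
    nrm <- sqrt(sum(dir^2))
    if (nrm > 2) dir <- dir * (2 / nrm)
    step <- 1
    nxt <- NULL
    for (h in 1:10) {
      cand <- eval_at(xi + step * dir, TRUE)
      if (!is.null(cand) && cand$loglik > cur$loglik - 1e-12) {
        nxt <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(nxt)) return(NULL)
    xi <- xi + step * dir
    cur <- nxt
    g <- grad_xi(cur)
  }
  NULL
}

# BHHH (scored quasi-Newton) maximization: Newton steps with the outer
# product of per-subject scores as information matrix, plus step-halving.
# Converges in a handful of iterations from a warm start near the optimum,
# at a fraction of the per-iteration overhead of a general optimizer, which
# is what makes whole-volume voxel sweeps affordable. Returns NULL when it
# fails to converge (callers fall back to fit_xi()).
fit_xi_bhhh <- function(prep, spec, xi0, max_iter = 50, tol = 1e-5) {
  lay <- prep$layout
  T_ <- spec$n_occasions
  eval_at <- function(xi, scores) {
    st <- unpack_xi(xi, lay, T_)
    if (any(!is.finite(st$L)) || any(diag(st$L)[lay$qd + seq_len(lay$qc)] <= 0))
      return(NULL)
    r <- cpp_tp_eval(st$mu, st$L, st$theta, st$gamma, lay$qd,
                     prep$Yb, prep$Yc, prep$X, lay$path_idx,
                     lay$Lam_d, lay$Lam_c, lay$link_code,
                     prep$grid$Z, prep$grid$w,
                     want_grad = FALSE, want_scores = scores)
    if (!isTRUE(r$ok) || !is.finite(r$loglik)) return(NULL)
    r$st <- st
    r
  }
  cur <- eval_at(xi0, TRUE)
  if (is.null(cur)) return(NULL)
  xi <- xi0
  tol_abs <- tol * max(1, prep$n)
  for (it in seq_len(max_iter)) {
    S <- map_scores_xi(cur$scores, cur$st, lay, T_)
    g <- colSums(S)
    if (max(abs(g)) < tol_abs) {
      return(list(xi = xi, loglik = cur$loglik, nlminb_convergence = 0L,
                  gradient_norm = max(abs(g)), message = "bhhh converged",
                  scores = S))
    }
    B <- crossprod(S)
    ridge <- 1e-8 * max(diag(B), 1)
    dir <- tryCatch(solve(B + diag(ridge, length(g)), g),
                    error = function(e) NULL)
    if (is.null(dir) || any(!is.finite(dir))) return(NULL)
    step <- 1
    nxt <- NULL
    for (h in 1:12) {
      cand <- eval_at(xi + step * dir, TRUE)
      if (!is.null(cand) && cand$loglik > cur$loglik - 1e-12) {
        nxt <- cand
        break
      }
      step <- step / 2
    }
    if (is.null(nxt)) return(NULL)
    xi <- xi + step * dir
    cur <- nxt
  }
  NULL
}

# Sandwich-free OPG covariance of xi-hat: inverse of the summed outer
# product of per-subject scores. Cheap (one likelihood pass) and therefore
# the default in mass-univariate voxel fitting. Parameters whose scores are
# numerically degenerate (variance components that collapsed onto the zero
# boundary leave an all-zero score column) are profiled out: their
# rows/columns come back as NA while the remaining block is inverted.
opg_covariance_xi <- function(xi, prep, spec) {
  opg_from_scores(score_matrix_xi(xi, prep, spec))
}

opg_from_scores <- function(S) {
  k <- ncol(S)
  cm <- colMeans(S)
  sds <- sqrt(pmax(colMeans(S * S) - cm * cm, 0))
  active <- sds > 1e-8 * max(sds, 1)
  V <- matrix(NA_real_, k, k, dimnames = list(colnames(S), colnames(S)))
  if (!any(active)) return(NULL)
  B <- crossprod(S[, active, drop = FALSE])
  Va <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Va) || any(diag(Va) <= 0)) return(NULL)
  V[active, active] <- Va
  V
}
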