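#' Structured parameters of the two-part growth model
#'
#' Bundles the latent means, the latent covariance matrix, the continuous
#' residual variances and the covariate regression coefficients. Factor
#' names follow the field convention: `Id`/`Sd` intercept and slope of the
#' discrete (any-use) part, `Ic`/`Sc` of the continuous part, `Qd`/`Qc`
#' quadratic factors when present.
#'
#' @param mu named numeric vector of latent means.
#' @param psi latent covariance matrix with dimnames matching `mu`;
#'   symmetric positive semidefinite.
#' @param theta continuous residual variances (one per occasion, or length 1
#'   when constrained equal). Omit for discrete-only models.
#' @param gamma named numeric vector of covariate coefficients (may be
#'   empty); the voxel coefficient, when present, is named `beta_voxel`.
#' @return object of class `two_part_params`.
#' @export
two_part_params <- function(mu, psi, theta = numeric(0), gamma = numeric(0)) {
  if (is.null(names(mu))) stop("mu must be named by latent factor")
  psi <- as.matrix(psi)
  if (is.null(dimnames(psi))) dimnames(psi) <- list(names(mu), names(mu))
  if (!identical(sort(rownames(psi)), sort(names(mu)))) {
    stop("psi dimnames must match names(mu)")
  }
  psi <- psi[names(mu), names(mu), drop = FALSE]
  if (max(abs(psi - t(psi))) > 1e-10) stop("psi must be symmetric")
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev))) {
    stop("psi is not positive semidefinite (min eigenvalue ", min(ev), ")")
  }
  if (any(theta < 0)) stop("residual variances must be non-negative")
  structure(list(mu = mu, psi = psi, theta = theta, gamma = gamma),
            class = "two_part_params")
}

#' @export
print.two_part_params <- function(x, ...) {
  cat("<two_part_params>\n  means:\n")
  print(round(x$mu, 4))
  cat("  latent covariance:\n")
  print(round(x$psi, 4))
  if (length(x$theta)) cat("  residual variances:",
                           paste(round(x$theta, 4), collapse = ", "), "\n")
  if (length(x$gamma)) { cat("  regressions:\n"); print(round(x$gamma, 4)) }
  invisible(x)
}

# ---- unconstrained parameterization -----------------------------------------
# xi = [ mu (q) | free Cholesky entries of Psi, column-major, log on the
#        diagonal | log theta | gamma ]

xi_names <- function(layout) {
  f <- layout$factors
  ell <- character(0)
  for (s in seq_len(layout$q)) for (r in s:layout$q) {
    if (layout$Lmask[r, s]) {
      ell <- c(ell, if (r == s) paste0("logL.", f[r])
               else paste0("L.", f[r], "_", f[s]))
    }
  }
  th <- if (layout$n_theta == 1L) "logtheta" else
    if (layout$n_theta > 1L) paste0("logtheta.t", seq_len(layout$n_theta)) else
      character(0)
  c(paste0("mean.", f), ell, th,
    if (length(layout$cov_names))
      paste0("gamma.", sub("^\\.voxel$", "beta_voxel", layout$cov_names))
    else character(0))
}

# structured (mu, L, theta, gamma) -> xi
pack_xi <- function(mu, L, theta, gamma, layout) {
  ell <- numeric(0)
  for (s in seq_len(layout$q)) for (r in s:layout$q) {
    if (layout$Lmask[r, s]) {
      ell <- c(ell, if (r == s) log(max(L[r, r], 1e-10)) else L[r, s])
    }
  }
  th <- if (layout$n_theta == 1L) mean(theta) else
    theta[seq_len(layout$n_theta)]
  setNames(c(mu, ell, if (layout$n_theta) log(pmax(th, 1e-10)), gamma),
           xi_names(layout))
}

# xi -> list(mu, L, theta (length T), gamma); theta expanded per occasion
unpack_xi <- function(xi, layout, n_occasions) {
  q <- layout$q
  mu <- xi[seq_len(q)]
  pos <- q
  L <- matrix(0, q, q)
  for (s in seq_len(q)) for (r in s:q) {
    if (layout$Lmask[r, s]) {
      pos <- pos + 1L
      L[r, s] <- if (r == s) exp(xi[pos]) else xi[pos]
    }
  }
  theta <- numeric(0)
  if (layout$n_theta > 0L) {
    theta <- exp(xi[pos + seq_len(layout$n_theta)])
    pos <- pos + layout$n_theta
    if (layout$n_theta == 1L) theta <- rep(theta, n_occasions)
  }
  gamma <- xi[pos + seq_along(layout$cov_names)]
  list(mu = setNames(as.numeric(mu), layout$factors), L = L,
       theta = as.numeric(theta), gamma = setNames(as.numeric(gamma),
                                                   layout$cov_names))
}

# gradient chain: (dmu, dL, dtheta per occasion, dgamma) on natural scale
# -> gradient wrt xi
chain_xi_grad <- function(g, st, layout) {
  dell <- numeric(0)
  for (s in seq_len(layout$q)) for (r in s:layout$q) {
    if (layout$Lmask[r, s]) {
      dell <- c(dell, if (r == s) g$dL[r, s] * st$L[r, s] else g$dL[r, s])
    }
  }
  dth <- numeric(0)
  if (layout$n_theta == 1L) {
    dth <- sum(g$dtheta * st$theta)
  } else if (layout$n_theta > 1L) {
    dth <- g$dtheta * st$theta
  }
  c(g$dmu, dell, dth, g$dgamma)
}

# Cholesky factorization tolerant of zero pivots (positive SEMI-definite
# input), preserving the lower-triangular convention used throughout.
chol_psd <- function(psi, tol = 1e-10) {
  q <- nrow(psi)
  L <- matrix(0, q, q)
  scale <- max(1, max(abs(diag(psi))))
  for (j in seq_len(q)) {
    d <- psi[j, j] - sum(L[j, seq_len(j - 1)]^2)
    if (d > tol * scale) {
      L[j, j] <- sqrt(d)
      for (i in seq_len(q)[-seq_len(j)]) {
        L[i, j] <- (psi[i, j] - sum(L[i, seq_len(j - 1)] * L[j, seq_len(j - 1)])) /
          L[j, j]
      }
    } else if (d > -1e-6 * scale) {
      # zero pivot: the remaining column must vanish too
      for (i in seq_len(q)[-seq_len(j)]) {
        res <- psi[i, j] - sum(L[i, seq_len(j - 1)] * L[j, seq_len(j - 1)])
        if (abs(res) > 1e-6 * scale) stop("psi is not positive semidefinite")
      }
    } else {
      stop("psi is not positive semidefinite")
    }
  }
  L
}

# ---- Gauss-Hermite rules ----------------------------------------------------

# nodes/weights for weight function exp(-x^2): nodes via Golub-Welsch,
# weights via the Christoffel sum w_i = 1 / sum_k p_k(x_i)^2 over the
# orthonormal Hermite polynomials.  The eigenvector-based weights
# sqrt(pi) * v_1i^2 underflow to exact zeros for n >= ~60 because LAPACK
# flushes the tiny first components; the Christoffel form stays positive.
gh_rule <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  x <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  p_prev <- rep(pi^(-0.25), n)
  p_cur <- x * sqrt(2) * p_prev
  chr <- p_prev^2 + p_cur^2
  for (k in seq_len(n - 2)) {
    p_next <- x * sqrt(2 / (k + 1)) * p_cur - sqrt(k / (k + 1)) * p_prev
    chr <- chr + p_next^2
    p_prev <- p_cur
    p_cur <- p_next
  }
  list(x = x, w = 1 / chr)
}

# tensor-product grid over d dimensions; weights normalized so that the
# rule integrates the standard-normal density to one
gh_grid <- function(n, d) {
  if (d == 0L) return(list(Z = matrix(0, 1, 0), w = 1))
  r <- gh_rule(n)
  idx <- do.call(expand.grid, rep(list(seq_len(n)), d))
  Z <- matrix(r$x[as.matrix(idx)], ncol = d)
  logw <- rowSums(matrix(log(r$w)[as.matrix(idx)], ncol = d)) -
    d / 2 * log(pi)
  list(Z = Z, w = exp(logw))
}
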