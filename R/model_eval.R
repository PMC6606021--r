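#' Likelihood-ratio (chi-square difference) test for nested models
#'
#' `delta_chi2 = 2 * (loglik_full - loglik_restricted)`. Numerical noise can
#' make the raw difference slightly negative when the restricted model's
#' optimizer lands marginally higher; the signed value is preserved as a
#' diagnostic (`delta_chi2_signed`) while the test statistic is clipped at
#' zero (giving p = 1).
#'
#' @param loglik_restricted,loglik_full maximized log-likelihoods of the
#'   nested (restricted) and the more general model.
#' @param df_diff difference in free parameters (positive).
#' @return list with `delta_chi2`, `delta_chi2_signed`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(loglik_restricted, loglik_full, df_diff) {
  if (df_diff <= 0) stop("df_diff must be positive")
  raw <- 2 * (loglik_full - loglik_restricted)
  if (raw < 0) {
    warning(sprintf(
      "restricted model attained the higher log-likelihood (delta chi2 = %.3f); clipping to 0",
      raw))
  }
  stat <- max(raw, 0)
  list(delta_chi2 = stat, delta_chi2_signed = raw, df = df_diff,
       p = pchisq(stat, df_diff, lower.tail = FALSE))
}

#' Root mean square error of approximation
#'
#' `sqrt(max(chi2 - df, 0) / (df * n))`; values below 0.08 are conventionally
#' read as acceptable fit.
#'
#' @param chi2 model chi-square.
#' @param df model degrees of freedom (positive).
#' @param n sample size (> 1).
#' @return RMSEA (scalar).
#' @examples
#' rmsea(444, 65, 1814)  # 0.057
#' @export
rmsea <- function(chi2, df, n) {
  stopifnot(df > 0, n > 1)
  sqrt(pmax(chi2 - df, 0) / (df * n))
}

#' Comparative fit index
#'
#' `1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)` against the
#' independence baseline; clipped into `[0, 1]`, with 1 when both
#' noncentrality estimates vanish. Values above 0.90 are conventionally read
#' as good fit.
#'
#' @param chi2_model,df_model model chi-square and degrees of freedom.
#' @param chi2_baseline,df_baseline independence-baseline chi-square and df.
#' @return CFI in `[0, 1]`.
#' @export
cfi <- function(chi2_model, df_model, chi2_baseline, df_baseline) {
  num <- max(chi2_model - df_model, 0)
  den <- max(chi2_baseline - df_baseline, chi2_model - df_model, 0)
  if (den == 0) return(1)
  min(max(1 - num / den, 0), 1)
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized covariance residuals over the lower
#' triangle (including the diagonal), optionally augmented with the
#' standardized mean residuals:
#' `resid_jk = (s_jk - sigma_jk) / sqrt(s_jj * s_kk)`,
#' `resid_j = (m_j - mu_j) / sqrt(s_jj)`.
#'
#' @param observed list with `mean` and `cov` (or a covariance matrix).
#' @param implied same structure as `observed`.
#' @param include_means include the mean residuals (only when both carry
#'   means).
#' @return SRMR (scalar).
#' @export
srmr <- function(observed, implied, include_means = TRUE) {
  get_cov <- function(x) if (is.list(x)) x$cov else x
  get_mean <- function(x) if (is.list(x)) x$mean else NULL
  S <- as.matrix(get_cov(observed)); Sig <- as.matrix(get_cov(implied))
  if (!identical(dim(S), dim(Sig))) stop("moment dimensions differ")
  d <- sqrt(diag(S))
  res <- (S - Sig) / outer(d, d)
  vals <- res[lower.tri(res, diag = TRUE)]
  m_o <- get_mean(observed); m_i <- get_mean(implied)
  if (include_means && !is.null(m_o) && !is.null(m_i)) {
    vals <- c(vals, (m_o - m_i) / d)
  }
  sqrt(mean(vals^2))
}

#' Akaike and Bayesian information criteria
#'
#' @param loglik maximized log-likelihood.
#' @param n_free_params number of free parameters.
#' @param n sample size.
#' @return list with `aic` and `bic`.
#' @export
information_criteria <- function(loglik, n_free_params, n) {
  stopifnot(n > 0)
  list(aic = -2 * loglik + 2 * n_free_params,
       bic = -2 * loglik + n_free_params * log(n))
}

# ---- FIML moments of incomplete multivariate-normal data --------------------

# EM for the saturated MVN model under MAR; diagonal = TRUE constrains the
# covariance to be diagonal (the independence baseline)
mvn_fiml_moments <- function(Y, diagonal = FALSE, max_iter = 500,
                             tol = 1e-8) {
  Y <- as.matrix(Y)
  T_ <- ncol(Y)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  n <- nrow(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  v <- apply(Y, 2, var, na.rm = TRUE)
  v[is.na(v) | v <= 0] <- 1
  Sig <- diag(v, T_)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    S1 <- numeric(T_); S2 <- matrix(0, T_, T_); ll <- 0
    pats <- apply(!is.na(Y), 1, function(z) paste(as.integer(z), collapse = ""))
    for (pt in unique(pats)) {
      rows <- which(pats == pt)
      obs <- which(strsplit(pt, "")[[1]] == "1")
      mis <- setdiff(seq_len(T_), obs)
      Yo <- Y[rows, obs, drop = FALSE]
      So <- Sig[obs, obs, drop = FALSE]
      SoInv <- solve(So)
      ctr <- sweep(Yo, 2, mu[obs])
      ll <- ll - 0.5 * length(rows) *
        (length(obs) * log(2 * pi) + determinant(So)$modulus[1]) -
        0.5 * sum((ctr %*% SoInv) * ctr)
      if (length(mis) == 0) {
        S1[obs] <- S1[obs] + colSums(Yo)
        S2[obs, obs] <- S2[obs, obs] + t(Yo) %*% Yo
      } else {
        B <- Sig[mis, obs, drop = FALSE] %*% SoInv
        Em <- matrix(mu[mis], length(rows), length(mis), byrow = TRUE) +
          ctr %*% t(B)
        Cm <- Sig[mis, mis, drop = FALSE] -
          B %*% Sig[obs, mis, drop = FALSE]
        S1[obs] <- S1[obs] + colSums(Yo)
        S1[mis] <- S1[mis] + colSums(Em)
        S2[obs, obs] <- S2[obs, obs] + t(Yo) %*% Yo
        S2[obs, mis] <- S2[obs, mis] + t(Yo) %*% Em
        S2[mis, obs] <- t(S2[obs, mis, drop = FALSE])
        S2[mis, mis] <- S2[mis, mis] + t(Em) %*% Em + length(rows) * Cm
      }
    }
    mu <- S1 / n
    Sig <- S2 / n - outer(mu, mu)
    Sig <- (Sig + t(Sig)) / 2
    if (diagonal) Sig <- diag(diag(Sig), T_)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mean = mu, cov = Sig, loglik = ll, n = n)
}

# FIML normal log-likelihood of data Y at fixed moments
mvn_fiml_loglik <- function(Y, mu, Sig) {
  Y <- as.matrix(Y)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  pats <- apply(!is.na(Y), 1, function(z) paste(as.integer(z), collapse = ""))
  ll <- 0
  for (pt in unique(pats)) {
    rows <- which(pats == pt)
    obs <- which(strsplit(pt, "")[[1]] == "1")
    So <- Sig[obs, obs, drop = FALSE]
    SoInv <- solve(So)
    ctr <- sweep(Y[rows, obs, drop = FALSE], 2, mu[obs])
    ll <- ll - 0.5 * length(rows) *
      (length(obs) * log(2 * pi) + determinant(So)$modulus[1]) -
      0.5 * sum((ctr %*% SoInv) * ctr)
  }
  ll
}

#' Global fit indices for a fitted two-part growth model
#'
#' Chi-square-based indices for a model estimated with numerical integration
#' have no natural saturated reference, so they are computed from the
#' continuous part alone: the model-implied normal likelihood of the
#' continuous indicators is compared against the unstructured
#' (EM-estimated) saturated moments, and the CFI baseline is the
#' independence model. SRMR compares EM-estimated observed moments with the
#' model-implied moments. The binary part enters likelihood-ratio
#' comparisons only.
#'
#' @param fit a converged [fit_twopart()] result.
#' @param data the [two_part_data()] the model was fitted to.
#' @return list of class `fit_indices` with `chi2`, `df`, `rmsea`, `cfi`,
#'   `srmr`, `aic`, `bic` and the pieces they were computed from.
#' @export
fit_indices <- function(fit, data) {
  spec <- fit$spec
  Y <- data$continuous
  if (spec$parts == "continuous") Y <- data$continuous
  n <- sum(rowSums(!is.na(Y)) > 0)
  sat <- mvn_fiml_moments(Y)
  base <- mvn_fiml_moments(Y, diagonal = TRUE)
  cov_means <- NULL
  if (!is.null(data$covariates) && length(fit$params$gamma)) {
    cov_means <- colMeans(as.matrix(data$covariates))
  }
  imp <- implied_moments(fit$params, spec, covariate_means = cov_means)
  ll_model <- mvn_fiml_loglik(Y, imp$mean, imp$cov)
  T_ <- ncol(Y)
  lay <- model_layout(spec, character(0))
  k_model <- lay$qc + lay$qc * (lay$qc + 1) / 2 + lay$n_theta
  p_star <- T_ * (T_ + 3) / 2
  k_sat <- p_star
  k_base <- 2 * T_
  chi2 <- max(2 * (sat$loglik - ll_model), 0)
  df <- k_sat - k_model
  chi2_b <- max(2 * (sat$loglik - base$loglik), 0)
  df_b <- k_sat - k_base
  ic <- information_criteria(fit$loglik, fit$n_free_params, n)
  structure(list(chi2 = chi2, df = df,
                 rmsea = rmsea(chi2, df, n),
                 cfi = cfi(chi2, df, chi2_b, df_b),
                 srmr = srmr(sat, imp),
                 aic = ic$aic, bic = ic$bic,
                 chi2_baseline = chi2_b, df_baseline = df_b, n = n),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.2f, df = %d, RMSEA = %.3f, CFI = %.3f, SRMR = %.3f\n",
              x$chi2, as.integer(x$df), x$rmsea, x$cfi, x$srmr))
  cat(sprintf("AIC = %.1f, BIC = %.1f (n = %d)\n", x$aic, x$bic, x$n))
  invisible(x)
}

#' Side-by-side comparison of fitted models
#'
#' Builds the standard nested-comparison report: log-likelihood, parameter
#' count, chi-square difference against the previous model in the list,
#' information criteria.
#'
#' @param fits named list of [fit_twopart()] results, ordered from most
#'   restricted to most general.
#' @param n sample size used for the BIC (defaults to the first fit's).
#' @return tibble with one row per model.
#' @export
compare_models <- function(fits, n = NULL) {
  stopifnot(length(fits) >= 1)
  if (is.null(n)) n <- fits[[1]]$n_subjects_used
  out <- tibble::tibble(
    model = names(fits) %||% paste0("model", seq_along(fits)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    k = vapply(fits, function(f) f$n_free_params, numeric(1)),
    delta_chi2 = NA_real_, df = NA_real_, p = NA_real_,
    aic = NA_real_, bic = NA_real_)
  for (i in seq_along(fits)) {
    ic <- information_criteria(out$loglik[i], out$k[i], n)
    out$aic[i] <- ic$aic; out$bic[i] <- ic$bic
    if (i > 1 && out$k[i] > out$k[i - 1]) {
      lr <- likelihood_ratio_test(out$loglik[i - 1], out$loglik[i],
                                  out$k[i] - out$k[i - 1])
      out$delta_chi2[i] <- lr$delta_chi2_signed
      out$df[i] <- lr$df
      out$p[i] <- lr$p
    }
  }
  out
}
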