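#' Declare the structure of a two-part latent growth curve model
#'
#' @param n_occasions number of measurement occasions (the cohort design has 3).
#' @param time_scores slope loadings per occasion, strictly increasing.
#'   Default `0:(n_occasions-1)` (equal-interval coding); pass e.g.
#'   `c(0, 2.6, 4.6)` for per-year slopes on the cohort's age grid.
#' @param growth_discrete,growth_continuous growth order of each part:
#'   `"intercept_only"`, `"linear"` or `"quadratic"`.
#' @param link link for the discrete (any-use) part: `"logit"` or `"probit"`.
#' @param parts `"both"` (the two-part model), `"continuous"` (ordinary
#'   one-part growth model on the continuous indicators, closed form), or
#'   `"discrete"` (growth model on the binary indicators only).
#' @param covariate_paths named character vector mapping covariate column
#'   names to the latent factor they predict (e.g. `c(sex = "Sc")`). The
#'   default `NULL` sends every covariate in the data to the continuous
#'   slope `"Sc"`, the conventional nuisance-adjustment path.
#' @param predictor_target latent factor that a voxel predictor regresses on
#'   in voxel-wise runs: one of `"Sc"`, `"Ic"`, `"Sd"`, `"Id"`.
#' @param equal_residuals constrain the continuous residual variances to be
#'   equal across occasions.
#' @param full_psi free all latent covariances. By default the within-part
#'   covariances Cov(Id,Sd), Cov(Ic,Sc) and the intercept-intercept
#'   covariance Cov(Id,Ic) are free and the remaining cross-part covariances
#'   are fixed to zero.
#' @param n_quad Gauss-Hermite nodes per discrete-part latent dimension.
#' @return object of class `growth_spec`.
#' @export
growth_spec <- function(n_occasions = 3,
                        time_scores = seq_len(n_occasions) - 1,
                        growth_discrete = c("linear", "intercept_only", "quadratic"),
                        growth_continuous = c("linear", "intercept_only", "quadratic"),
                        link = c("logit", "probit"),
                        parts = c("both", "continuous", "discrete"),
                        covariate_paths = NULL,
                        predictor_target = "Sc",
                        equal_residuals = FALSE,
                        full_psi = FALSE,
                        n_quad = 15) {
  growth_discrete <- match.arg(growth_discrete)
  growth_continuous <- match.arg(growth_continuous)
  link <- match.arg(link)
  parts <- match.arg(parts)
  if (length(time_scores) != n_occasions) {
    stop("time_scores must have length n_occasions")
  }
  if (any(diff(time_scores) <= 0)) stop("time_scores must be strictly increasing")
  if ((growth_discrete == "quadratic" || growth_continuous == "quadratic") &&
      n_occasions < 3) {
    stop("a quadratic growth factor requires at least 3 occasions")
  }
  structure(list(n_occasions = n_occasions,
                 time_scores = as.numeric(time_scores),
                 growth_discrete = growth_discrete,
                 growth_continuous = growth_continuous,
                 link = link, parts = parts,
                 covariate_paths = covariate_paths,
                 predictor_target = predictor_target,
                 equal_residuals = equal_residuals,
                 full_psi = full_psi,
                 n_quad = n_quad),
            class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat("<growth_spec>\n")
  cat(sprintf("  occasions: %d, time scores: %s\n", x$n_occasions,
              paste(x$time_scores, collapse = ", ")))
  cat(sprintf("  parts: %s (discrete %s, continuous %s), link: %s\n",
              x$parts, x$growth_discrete, x$growth_continuous, x$link))
  cat(sprintf("  predictor target: %s, quadrature nodes/dim: %d\n",
              x$predictor_target, x$n_quad))
  invisible(x)
}

growth_order_q <- function(order) {
  switch(order, intercept_only = 1L, linear = 2L, quadratic = 3L)
}

# Internal layout of the latent model implied by a growth_spec.
#
# Factor ordering is (Sd, Qd, Id | Ic, Sc, Qc): within the discrete block the
# intercept comes last and within the continuous block it comes first, so
# that the default covariance sparsity (within-part covariances plus the
# intercept-intercept covariance free, all other cross-part covariances
# zero) corresponds exactly to structural zeros of the lower Cholesky
# factor of Psi.
model_layout <- function(spec, covariate_names = character(0),
                         voxel = FALSE) {
  T_ <- spec$n_occasions
  lam <- spec$time_scores
  d_names <- c_names <- character(0)
  Lam_d <- matrix(0, T_, 0); Lam_c <- matrix(0, T_, 0)
  if (spec$parts %in% c("both", "discrete")) {
    qd <- growth_order_q(spec$growth_discrete)
    d_names <- switch(spec$growth_discrete,
                      intercept_only = "Id",
                      linear = c("Sd", "Id"),
                      quadratic = c("Sd", "Qd", "Id"))
    cols <- list(Id = rep(1, T_), Sd = lam, Qd = lam^2)
    Lam_d <- do.call(cbind, cols[d_names])
  }
  if (spec$parts %in% c("both", "continuous")) {
    c_names <- switch(spec$growth_continuous,
                      intercept_only = "Ic",
                      linear = c("Ic", "Sc"),
                      quadratic = c("Ic", "Sc", "Qc"))
    cols <- list(Ic = rep(1, T_), Sc = lam, Qc = lam^2)
    Lam_c <- do.call(cbind, cols[c_names])
  }
  factors <- c(d_names, c_names)
  q <- length(factors); qd <- length(d_names); qc <- length(c_names)
  # Cholesky mask: lower triangle; within-block free, cross-block only
  # (Ic, Id) unless full_psi
  Lmask <- matrix(FALSE, q, q)
  for (r in seq_len(q)) for (s in seq_len(r)) {
    within <- (r <= qd && s <= qd) || (r > qd && s > qd)
    cross_ii <- qd > 0 && qc > 0 &&
      factors[r] == "Ic" && factors[s] == "Id"
    Lmask[r, s] <- within || cross_ii || spec$full_psi
  }
  # covariate paths -> 0-based factor indices for the C++ core
  path_names <- covariate_names
  paths <- spec$covariate_paths
  resolve <- function(nm) {
    tgt <- if (!is.null(paths) && nm %in% names(paths)) paths[[nm]] else "Sc"
    idx <- match(tgt, factors)
    if (is.na(idx)) {
      stop("covariate path target '", tgt, "' is not a factor of this model (",
           paste(factors, collapse = ", "), ")")
    }
    idx - 1L
  }
  path_idx <- vapply(path_names, resolve, integer(1))
  if (voxel) {
    vt <- match(spec$predictor_target, factors)
    if (is.na(vt)) stop("predictor_target '", spec$predictor_target,
                        "' is not a factor of this model")
    path_names <- c(path_names, ".voxel")
    path_idx <- c(path_idx, vt - 1L)
  }
  n_theta <- if (qc > 0) { if (spec$equal_residuals) 1L else T_ } else 0L
  list(factors = factors, qd = qd, qc = qc, q = q,
       Lam_d = Lam_d, Lam_c = Lam_c, Lmask = Lmask,
       cov_names = path_names, path_idx = as.integer(path_idx),
       n_theta = n_theta,
       link_code = if (spec$link == "probit") 1L else 0L)
}

# identifiability guard: each part's parameter count must not exceed the
# number of first/second moments its indicators provide
check_identified <- function(spec, layout) {
  T_ <- spec$n_occasions
  if (layout$qc > 0) {
    k_c <- layout$qc + layout$qc * (layout$qc + 1) / 2 + layout$n_theta
    if (k_c > T_ * (T_ + 3) / 2) {
      stop("continuous part not identified: ", k_c, " parameters but only ",
           T_ * (T_ + 3) / 2, " observed moments; constrain residuals or ",
           "reduce the growth order")
    }
  }
  if (layout$qd > 0) {
    k_d <- layout$qd + layout$qd * (layout$qd + 1) / 2
    if (k_d > 2^T_ - 1) {
      stop("discrete part not identified: ", k_d, " parameters but only ",
           2^T_ - 1, " response-pattern degrees of freedom")
    }
  }
  invisible(TRUE)
}
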