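#' Mass-univariate voxelwise growth modelling
#'
#' Fits the two-part growth model once per in-mask voxel, each time adding
#' that voxel's (by default z-scored) intensity as a predictor of the latent
#' target declared in the model specification (`predictor_target`,
#' continuous slope by
#' default). Every voxel fit is warm-started from a voxel-free base fit with
#' the voxel coefficient at zero, which makes the sweep feasible: the
#' behavioural likelihood surface barely moves between voxels.
#'
#' Per voxel the voxel coefficient's estimate, a score-based (outer product
#' of gradients) standard error, the Wald z and its two-sided normal p are
#' recorded. Voxels with (near-)constant intensity across subjects are
#' skipped and left missing. A voxel that fails to converge is refitted once
#' from a jittered start whose RNG seed is derived from the voxel's linear
#' index, so results do not depend on sweep order; if it still fails the
#' voxel is recorded as non-converged and left missing.
#'
#' @param images a [brain_image_set()]; subjects must be in the same order
#'   as in `data` (checked via subject identifiers when both carry them).
#' @param data a [two_part_data()].
#' @param spec a [growth_spec()].
#' @param standardize z-score each voxel across subjects before fitting
#'   (default `TRUE`), so coefficients are per standard deviation of
#'   intensity.
#' @param base_fit optional precomputed voxel-free [fit_twopart()] result
#'   used for warm starts; fitted internally when omitted.
#' @param jitter relative scale of the perturbation used for the single
#'   retry of non-converged voxels.
#' @param max_iter optimizer iteration cap per voxel.
#' @param gradient_tol per-subject gradient tolerance declaring a voxel fit
#'   converged.
#' @param verbose print progress every 1000 voxels.
#' @return object of class `voxel_map_result`: 3-D arrays `estimate`, `se`,
#'   `z`, `p`, logical arrays `converged` and `constant`, plus the mask,
#'   affine, target name, counts and the base fit.
#' @export
run_voxelwise <- function(images, data, spec, standardize = TRUE,
                          base_fit = NULL, jitter = 0.25, max_iter = 200,
                          gradient_tol = 1e-4, verbose = FALSE) {
  stopifnot(inherits(images, "brain_image_set"),
            inherits(data, "two_part_data"))
  n <- nrow(data$binary)
  if (dim(images$data)[1] != n) {
    stop("images hold ", dim(images$data)[1], " subjects but the ",
         "behavioural data ", n)
  }
  default_ids <- as.character(seq_len(n))
  if (!identical(images$subject_id, default_ids) ||
      !identical(data$subject_id, default_ids)) {
    if (!identical(images$subject_id, data$subject_id)) {
      stop("subject order differs between images and behavioural data")
    }
  }
  if (is.null(base_fit)) {
    base_fit <- fit_twopart(data, spec, se = FALSE)
  }
  if (!isTRUE(base_fit$converged)) {
    stop("the voxel-free base model did not converge; ",
         "fix the base model before the voxel sweep")
  }
  prep <- tp_prepare(data, spec, voxel = rep(0, n))
  vcol <- ncol(prep$X)
  xi0 <- c(base_fit$xi, 0)
  beta_idx <- length(xi0)
  dims <- dim(images$data)[2:4]
  idx <- which(images$mask)
  est <- se <- array(NA_real_, dims)
  converged <- constant <- array(FALSE, dims)
  flat <- matrix(images$data, nrow = n)  # n x (X*Y*Z), column-major voxels
  # One numerical Hessian at the warm start (with a representative voxel
  # column) preconditions the chord-Newton refits of every voxel.
  H_env <- new.env(parent = emptyenv())
  H_env$chol <- NULL
  for (v in idx) {
    x <- flat[, v]
    if (is.finite(sd(x)) && sd(x) > 1e-12) {
      prep$X[, vcol] <- if (standardize) (x - mean(x)) / sd(x) else x
      obj <- make_objective(prep, spec)
      H <- numDeriv::jacobian(function(z) -obj$grad_only(z), xi0,
                              method = "simple")
      H <- (H + t(H)) / 2
      H_env$chol <- tryCatch(chol(H), error = function(e) NULL)
      break
    }
  }
  is_ok <- function(r) {
    !is.null(r) && is.finite(r$loglik) && r$nlminb_convergence == 0 &&
      r$gradient_norm < gradient_tol * max(1, n)
  }
  for (m in seq_along(idx)) {
    v <- idx[m]
    x <- flat[, v]
    sdx <- sd(x)
    if (!is.finite(sdx) || sdx < 1e-12) {
      constant[v] <- TRUE
      next
    }
    if (standardize) x <- (x - mean(x)) / sdx
    prep$X[, vcol] <- x
    res <- if (is.null(H_env$chol)) NULL else
      tryCatch(fit_xi_chord(prep, spec, xi0, H_env, max_iter, gradient_tol),
               error = function(e) NULL)
    ok <- is_ok(res)
    if (!ok) {
      res <- tryCatch(fit_xi_bhhh(prep, spec, xi0, max_iter, gradient_tol),
                      error = function(e) NULL)
      ok <- is_ok(res)
    }
    if (!ok) {
      # scored Newton stalled too: hand the voxel to the general optimizer
      res <- tryCatch(fit_xi(prep, spec, xi0, max_iter),
                      error = function(e) NULL)
      ok <- is_ok(res)
    }
    if (!ok) {
      rs <- get0(".Random.seed", envir = globalenv())
      set.seed(v)
      xs <- xi0 + rnorm(length(xi0), 0, jitter * pmax(abs(xi0), 0.1))
      if (is.null(rs)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", rs, envir = globalenv())
      res <- tryCatch(fit_xi(prep, spec, xs, max_iter),
                      error = function(e) NULL)
      ok <- is_ok(res)
    }
    if (!ok) next
    converged[v] <- TRUE
    est[v] <- res$xi[beta_idx]
    V <- if (is.null(res$scores)) opg_covariance_xi(res$xi, prep, spec) else
      opg_from_scores(res$scores)
    if (!is.null(V)) se[v] <- sqrt(V[beta_idx, beta_idx])
    if (verbose && m %% 1000 == 0) {
      message(sprintf("voxel %d / %d", m, length(idx)))
    }
  }
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  structure(list(estimate = est, se = se, z = z, p = p,
                 converged = converged, constant = constant,
                 mask = images$mask, affine = images$affine,
                 target = spec$predictor_target,
                 n_voxels = length(idx),
                 n_converged = sum(converged),
                 n_constant = sum(constant),
                 base_fit = base_fit, spec = spec),
            class = "voxel_map_result")
}

#' @export
print.voxel_map_result <- function(x, ...) {
  cat(sprintf("<voxel_map_result> target %s: %d voxels, %d converged, %d constant\n",
              x$target, x$n_voxels, x$n_converged, x$n_constant))
  zr <- range(x$z, na.rm = TRUE)
  cat(sprintf("  z range: [%.2f, %.2f]\n", zr[1], zr[2]))
  invisible(x)
}
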