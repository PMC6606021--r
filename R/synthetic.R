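default_psi <- function() {
  f <- c("Id", "Sd", "Ic", "Sc")
  psi <- diag(c(0.090, 0.024, 0.618, 0.218))
  dimnames(psi) <- list(f, f)
  psi["Id", "Sd"] <- psi["Sd", "Id"] <- -0.033
  psi["Ic", "Sc"] <- psi["Sc", "Ic"] <- -0.078
  psi["Id", "Ic"] <- psi["Ic", "Id"] <- 0.124
  psi
}

default_gamma <- function() {
  c(sex = -0.183, age = 0, tbv = 0,
    site_2 = 0.410, site_3 = 0.368, site_4 = 0.517, site_5 = 0.091,
    site_6 = 0.122, site_7 = 0.038, site_8 = 0.079, site_9 = -0.044)
}

#' Configuration of the synthetic study generator
#'
#' Defaults emulate a three-occasion adolescent alcohol-use cohort: latent
#' growth parameters at the magnitudes reported for such cohorts (treated as
#' link-scale quantities for the discrete part, so the generator is
#' magnitude-realistic rather than a reproduction of any particular sample),
#' occasion-level attrition matching observed retention (1794 to 1439 to
#' 1284), 54% males, nine acquisition sites, and per-subject 3-D
#' tissue-volume images built from a smooth Gaussian random field plus
#' spherical regions whose intensity is proportional to the subject's true
#' continuous slope.
#'
#' @param n_subjects cohort size at baseline.
#' @param occasion_times slope loadings of the occasions.
#' @param mu,psi latent means and covariance (factors `Id`, `Sd`, `Ic`, `Sc`).
#' @param residual_variance continuous residual variance per occasion
#'   (scalar or per occasion). Not reported in cohort tables; 0.5 is of the
#'   order of the latent intercept variance.
#' @param gamma covariate effects on the continuous slope.
#' @param link link for the discrete part.
#' @param attrition per-occasion retention probabilities.
#' @param p_male probability of `sex = 1`.
#' @param age_mean,age_sd baseline age distribution (years); ages enter the
#'   model centered.
#' @param n_sites number of acquisition sites (dummy-coded against site 1).
#' @param image_dim 3-D image dimensions in voxels.
#' @param voxel_size isotropic voxel edge (mm), used for the affine.
#' @param effect_regions list of `list(center, radius, beta)` spheres (voxel
#'   units); voxel intensity gains `beta * standardized true slope` inside.
#' @param smoothing_fwhm Gaussian random field smoothness (voxels FWHM).
#' @param noise_sd white-noise standard deviation added on top of the unit
#'   variance smooth field.
#' @param seed RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 1794,
                             occasion_times = 0:2,
                             mu = c(Id = 0.568, Sd = 0.188,
                                    Ic = 0.693, Sc = 0.498),
                             psi = default_psi(),
                             residual_variance = 0.5,
                             gamma = default_gamma(),
                             link = "logit",
                             attrition = c(1, 1439 / 1794, 1284 / 1794),
                             p_male = 0.54,
                             age_mean = 14.4, age_sd = 0.45,
                             n_sites = 9,
                             image_dim = c(16, 16, 16),
                             voxel_size = 2,
                             effect_regions = list(
                               list(center = c(8, 8, 8), radius = 3.35,
                                    beta = 1.5)),
                             smoothing_fwhm = 4,
                             noise_sd = 0.5,
                             seed = 20190702) {
  if (length(attrition) != length(occasion_times)) {
    stop("attrition must give one retention probability per occasion")
  }
  if (any(attrition < 0 | attrition > 1)) stop("retention must be in [0, 1]")
  psi <- as.matrix(psi)
  ev <- eigen(psi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("psi assembled from the config is not positive semidefinite ",
         "(min eigenvalue ", signif(min(ev), 3), ")")
  }
  for (r in effect_regions) {
    if (any(r$center < 1 | r$center > image_dim)) {
      stop("effect region centered outside the image")
    }
  }
  structure(list(n_subjects = n_subjects, occasion_times = occasion_times,
                 mu = mu, psi = psi, residual_variance = residual_variance,
                 gamma = gamma, link = link, attrition = attrition,
                 p_male = p_male, age_mean = age_mean, age_sd = age_sd,
                 n_sites = n_sites, image_dim = image_dim,
                 voxel_size = voxel_size, effect_regions = effect_regions,
                 smoothing_fwhm = smoothing_fwhm, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_config")
}

#' Choose discrete-part means matching target non-use rates
#'
#' Utility for calibrating the generator to observed prevalence: returns
#' `mu` with `Id` and `Sd` replaced so that the population-average non-use
#' probability (ignoring latent variance) hits the supplied first- and
#' last-occasion rates.
#'
#' @param config a [synthetic_config()].
#' @param nonuse_first,nonuse_last target non-use fractions at the first and
#'   last occasion.
#' @return the config with an updated `mu`.
#' @export
calibrate_prevalence <- function(config, nonuse_first, nonuse_last) {
  linkfun <- if (config$link == "probit") qnorm else qlogis
  t1 <- config$occasion_times[1]
  tT <- config$occasion_times[length(config$occasion_times)]
  e1 <- linkfun(1 - nonuse_first); eT <- linkfun(1 - nonuse_last)
  sd_ <- (eT - e1) / (tT - t1)
  config$mu["Sd"] <- sd_
  config$mu["Id"] <- e1 - t1 * sd_
  config
}

#' Simulate two-part growth trajectories with known ground truth
#'
#' Per subject, latent factors are drawn from a multivariate normal with the
#' configured means (the covariate effects shifting the continuous slope)
#' and covariance. Binary use indicators are Bernoulli draws with the linked
#' discrete-part growth curve as success probability; continuous scores are
#' the continuous-part growth curve plus normal residual noise and are
#' emitted only at use occasions. Attrition removes whole occasions
#' completely at random.
#'
#' @param config a [synthetic_config()].
#' @param seed overrides `config$seed` when given.
#' @return list with `data` (a [two_part_data()]) and `truth` (per-subject
#'   latent draws and the generating parameters).
#' @export
generate_trajectories <- function(config, seed = NULL) {
  set.seed(seed %||% config$seed)
  n <- config$n_subjects
  T_ <- length(config$occasion_times)
  lam <- config$occasion_times
  sex <- rbinom(n, 1, config$p_male)
  age <- rnorm(n, 0, config$age_sd)   # centered at the baseline mean
  tbv <- rnorm(n)                     # standardized total brain volume
  site <- sample.int(config$n_sites, n, replace = TRUE)
  cov_df <- data.frame(sex = sex, age = age, tbv = tbv)
  if (config$n_sites > 1) {
    for (s in 2:config$n_sites) {
      cov_df[[paste0("site_", s)]] <- as.integer(site == s)
    }
  }
  gam <- config$gamma[intersect(names(config$gamma), names(cov_df))]
  shift <- as.matrix(cov_df[names(gam)]) %*% gam
  f <- c("Id", "Sd", "Ic", "Sc")
  Lt <- chol_psd(config$psi[f, f])
  eta <- t(Lt %*% matrix(rnorm(4 * n), 4, n)) +
    matrix(config$mu[f], n, 4, byrow = TRUE)
  colnames(eta) <- f
  eta[, "Sc"] <- eta[, "Sc"] + as.numeric(shift)
  linkinv <- if (config$link == "probit") pnorm else plogis
  theta <- rep(config$residual_variance, length.out = T_)
  binary <- continuous <- matrix(NA_real_, n, T_)
  for (t in seq_len(T_)) {
    pr <- linkinv(eta[, "Id"] + lam[t] * eta[, "Sd"])
    b <- rbinom(n, 1, pr)
    yc <- eta[, "Ic"] + lam[t] * eta[, "Sc"] + rnorm(n, 0, sqrt(theta[t]))
    binary[, t] <- b
    continuous[, t] <- ifelse(b == 1, yc, NA_real_)
    drop <- runif(n) > config$attrition[t]
    binary[drop, t] <- NA_real_
    continuous[drop, t] <- NA_real_
  }
  data <- two_part_data(binary, continuous, cov_df, lam)
  list(data = data,
       truth = list(eta = eta, shift = as.numeric(shift), site = site,
                    config = config))
}

# separable Gaussian smoothing of a 3-D array (truncated, renormalized at
# the edges so a constant field stays constant)
smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  dims <- dim(vol)
  for (ax in 1:3) {
    d <- dims[ax]
    x <- seq_len(d)
    Km <- exp(-0.5 * outer(x, x, "-")^2 / sigma^2)
    Km <- Km / rowSums(Km)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dv <- dim(v)
    v <- Km %*% matrix(v, d)
    dim(v) <- dv
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Spherical voxel mask
#'
#' Logical 3-D array marking voxels within `radius` of `center` (in voxel
#' units, inclusive). Used both to plant spherical effect regions and to
#' build brain-like analysis masks inside a rectangular volume.
#'
#' @param dims 3-D array dimensions.
#' @param center sphere center (voxel coordinates, 1-based).
#' @param radius sphere radius in voxels.
#' @return logical array of dimension `dims`.
#' @export
sphere_mask <- function(dims, center, radius) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  array(d2 <= radius^2, dims)
}

#' Simulate per-subject brain volumes with planted effects
#'
#' Each subject's volume is a spatially smooth Gaussian random field
#' (rescaled to unit marginal variance), plus, inside every configured
#' sphere, `beta` times the subject's standardized true continuous slope,
#' plus white noise. The whole image is in the mask.
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` element from [generate_trajectories()].
#' @param seed overrides `config$seed + 1` when given.
#' @return a [brain_image_set()] whose `region_masks` attribute carries the
#'   ground-truth effect masks.
#' @export
generate_brain <- function(config, truth, seed = NULL) {
  set.seed(seed %||% (config$seed + 1))
  dims <- config$image_dim
  n <- nrow(truth$eta)
  sc <- truth$eta[, "Sc"]
  sc_std <- (sc - mean(sc)) / sd(sc)
  sigma <- config$smoothing_fwhm / (2 * sqrt(2 * log(2)))
  regions <- lapply(config$effect_regions, function(r)
    sphere_mask(dims, r$center, r$radius))
  data <- array(0, c(n, dims))
  for (i in seq_len(n)) {
    f <- smooth3d(array(rnorm(prod(dims)), dims), sigma)
    f <- f / sd(f)
    for (j in seq_along(regions)) {
      f[regions[[j]]] <- f[regions[[j]]] +
        config$effect_regions[[j]]$beta * sc_std[i]
    }
    f <- f + array(rnorm(prod(dims), 0, config$noise_sd), dims)
    data[i, , , ] <- f
  }
  affine <- diag(c(rep(config$voxel_size, 3), 1))
  bset <- brain_image_set(data, affine, array(TRUE, dims))
  bset$region_masks <- regions
  bset
}

#' Generate a complete synthetic study bundle on disk
#'
#' Composes [generate_trajectories()] and [generate_brain()] and writes the
#' artifacts in the formats the analysis pipeline reads: the behavioral
#' table as CSV, the brain volumes as one 4-D NIfTI plus a mask NIfTI, and
#' the ground truth (latent draws, generating parameters, effect-region
#' voxel indices) as JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param seed overrides `config$seed`.
#' @return invisible list of file paths plus the in-memory objects.
#' @export
generate_study <- function(config, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  traj <- generate_trajectories(config, seed = seed)
  brain <- generate_brain(config, traj$truth, seed = seed + 1)
  behav <- file.path(dir, "behaviour.csv")
  write_two_part_csv(traj$data, behav)
  img <- file.path(dir, "brain.nii.gz")
  mask <- file.path(dir, "mask.nii.gz")
  write_brain_images(brain, img, mask)
  truth_file <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(mu = as.list(traj$truth$config$mu),
         psi = traj$truth$config$psi,
         gamma = as.list(traj$truth$config$gamma),
         residual_variance = traj$truth$config$residual_variance,
         seed = seed,
         eta = traj$truth$eta,
         effect_regions = lapply(seq_along(brain$region_masks), function(j)
           list(spec = config$effect_regions[[j]],
                voxels = which(brain$region_masks[[j]])))),
    truth_file, auto_unbox = TRUE, digits = NA)
  invisible(list(behaviour = behav, image = img, mask = mask,
                 truth = truth_file, data = traj$data,
                 truth_obj = traj$truth, brain = brain))
}
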