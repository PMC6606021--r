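Package: voxelsem
Title: Voxel-Wise Structural Equation Modelling of Two-Part Growth Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-part (semicontinuous) latent growth curve modelling for
    zero-inflated longitudinal outcomes such as AUDIT alcohol-use scores,
    fitted by maximum likelihood with Gauss-Hermite quadrature over the
    discrete-part latent factors and analytic marginalization of the
    continuous part. Supports full-information handling of missing data,
    covariate paths onto latent growth factors, nested model comparison and
    global fit indices, and a mass-univariate driver that refits the model
    with every voxel of a brain tissue-volume map predicting a latent growth
    factor, projects the resulting estimates and p-values back into image
    space, and applies cluster-extent thresholding. Includes a synthetic-data
    generator with known ground truth so the whole pipeline is testable
    without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    numDeriv,
    RNifti,
    jsonlite,
    yaml,
    tibble
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
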