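#' Two-part representation of a semicontinuous longitudinal outcome
#'
#' Container for the decomposed outcome: a binary any-use matrix, a
#' continuous score-given-use matrix (positive where the binary indicator is
#' one, missing elsewhere), per-subject covariates, and occasion time scores.
#'
#' Structural invariants (checked on construction):
#' * `continuous[i,t]` observed implies `binary[i,t] == 1`;
#' * `binary[i,t] == 0` implies `continuous[i,t]` missing;
#' * `binary[i,t]` missing implies `continuous[i,t]` missing.
#'
#' @param binary subjects x occasions matrix over \{0, 1, NA\}.
#' @param continuous subjects x occasions matrix of positive reals or NA.
#' @param covariates data frame (or NULL) with one row per subject.
#' @param occasion_times numeric vector of slope loadings, one per occasion.
#' @param subject_id optional subject identifiers.
#' @return object of class `two_part_data`.
#' @export
two_part_data <- function(binary, continuous, covariates = NULL,
                          occasion_times = seq_len(ncol(binary)) - 1,
                          subject_id = NULL) {
  binary <- as.matrix(binary); continuous <- as.matrix(continuous)
  if (!identical(dim(binary), dim(continuous))) {
    stop("binary and continuous matrices must have identical dimensions")
  }
  if (length(occasion_times) != ncol(binary)) {
    stop("occasion_times must have one entry per occasion")
  }
  if (any(!is.na(binary) & !(binary %in% c(0, 1)))) {
    stop("binary entries must be 0, 1 or NA")
  }
  if (any(is.na(binary) & !is.na(continuous))) {
    stop("continuous observed where binary is missing")
  }
  if (any(!is.na(binary) & binary == 0 & !is.na(continuous))) {
    stop("continuous observed where binary indicates non-use")
  }
  if (any(binary[!is.na(continuous)] != 1)) {
    stop("continuous observed requires binary == 1")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(binary)) {
      stop("covariates must have one row per subject")
    }
  }
  if (is.null(subject_id)) {
    subject_id <- rownames(binary)
    if (is.null(subject_id)) subject_id <- as.character(seq_len(nrow(binary)))
  }
  structure(list(binary = binary, continuous = continuous,
                 covariates = covariates,
                 occasion_times = as.numeric(occasion_times),
                 subject_id = as.character(subject_id)),
            class = "two_part_data")
}

#' @export
print.two_part_data <- function(x, ...) {
  cat(sprintf("<two_part_data> %d subjects x %d occasions\n",
              nrow(x$binary), ncol(x$binary)))
  cat(sprintf("  occasion times: %s\n", paste(x$occasion_times, collapse = ", ")))
  obs_b <- colMeans(!is.na(x$binary))
  use <- colMeans(x$binary == 1, na.rm = TRUE)
  cat(sprintf("  observed binary fraction: %s\n",
              paste(sprintf("%.2f", obs_b), collapse = ", ")))
  cat(sprintf("  use prevalence (observed): %s\n",
              paste(sprintf("%.2f", use), collapse = ", ")))
  if (!is.null(x$covariates)) {
    cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  }
  invisible(x)
}

#' Decompose sum scores into the two-part representation
#'
#' Scores of zero are separated from the positive scores: the binary part
#' distinguishes any positive score (= 1) from non-use (= 0); the continuous
#' part holds the score given that it is positive and is coded missing at
#' non-use occasions, so never-users contribute little to the continuous
#' growth parameters while all use information is retained.
#'
#' @param sums tibble with `subject_id`, `occasion`, `sum_score` (long format).
#' @param covariates optional data frame with a `subject_id` column plus
#'   covariate columns (one row per subject).
#' @param occasion_times numeric slope loadings per occasion; defaults to
#'   `0, 1, ...` over the occasions present.
#' @return [two_part_data()] object with subjects ordered by first appearance.
#' @export
decompose_two_part <- function(sums, covariates = NULL, occasion_times = NULL) {
  if (anyDuplicated(sums[c("subject_id", "occasion")])) {
    d <- sums[duplicated(sums[c("subject_id", "occasion")]), ]
    stop("duplicate subject x occasion rows, e.g. subject ",
         d$subject_id[1L], " occasion ", d$occasion[1L])
  }
  occ <- sort(unique(sums$occasion))
  subj <- unique(as.character(sums$subject_id))
  if (is.null(occasion_times)) occasion_times <- seq_along(occ) - 1
  s <- matrix(NA_real_, length(subj), length(occ),
              dimnames = list(subj, paste0("occ", occ)))
  s[cbind(match(as.character(sums$subject_id), subj),
          match(sums$occasion, occ))] <- sums$sum_score
  binary <- ifelse(is.na(s), NA_real_, as.numeric(s > 0))
  continuous <- ifelse(!is.na(s) & s > 0, s, NA_real_)
  cov_df <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    idx <- match(subj, as.character(covariates$subject_id))
    if (anyNA(idx)) stop("covariates missing for subject(s): ",
                         paste(head(subj[is.na(idx)]), collapse = ", "))
    cov_df <- covariates[idx, setdiff(names(covariates), "subject_id"), drop = FALSE]
    rownames(cov_df) <- subj
  }
  two_part_data(binary, continuous, cov_df, occasion_times, subject_id = subj)
}

#' Natural-log transform of the continuous part
#'
#' Applies `log()` to the observed continuous scores (all positive by
#' construction, so no offset is needed); the binary part and the missingness
#' pattern are untouched. Used as a robustness check against skewness.
#'
#' @param data a [two_part_data()] object.
#' @return transformed `two_part_data`.
#' @export
log_transform_two_part <- function(data) {
  stopifnot(inherits(data, "two_part_data"))
  data$continuous <- log(data$continuous)
  data
}

#' Write / read the tidy CSV form of a two-part dataset
#'
#' Long format with one row per subject x occasion: `subject_id`, `occasion`,
#' `time`, `binary`, `continuous`, followed by the covariate columns.
#'
#' @param data a [two_part_data()] object.
#' @param path file path.
#' @return `write_two_part_csv` returns `path` invisibly;
#'   `read_two_part_csv` returns a `two_part_data`.
#' @export
write_two_part_csv <- function(data, path) {
  T_ <- ncol(data$binary); n <- nrow(data$binary)
  out <- data.frame(
    subject_id = rep(data$subject_id, each = T_),
    occasion = rep(seq_len(T_) - 1L, n),
    time = rep(data$occasion_times, n),
    binary = as.vector(t(data$binary)),
    continuous = as.vector(t(data$continuous)))
  if (!is.null(data$covariates)) {
    out <- cbind(out, data$covariates[rep(seq_len(n), each = T_), , drop = FALSE])
  }
  rownames(out) <- NULL
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_two_part_csv
#' @export
read_two_part_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  occ <- sort(unique(df$occasion))
  subj <- unique(as.character(df$subject_id))
  mk <- function(col) {
    m <- matrix(NA_real_, length(subj), length(occ), dimnames = list(subj, NULL))
    m[cbind(match(as.character(df$subject_id), subj), match(df$occasion, occ))] <-
      df[[col]]
    m
  }
  times <- vapply(occ, function(o) df$time[df$occasion == o][1L], numeric(1))
  cov_cols <- setdiff(names(df), c("subject_id", "occasion", "time",
                                   "binary", "continuous"))
  cov_df <- NULL
  if (length(cov_cols) > 0L) {
    first <- !duplicated(df$subject_id)
    cov_df <- df[first, cov_cols, drop = FALSE]
    rownames(cov_df) <- as.character(df$subject_id[first])
    cov_df <- cov_df[subj, , drop = FALSE]
  }
  two_part_data(mk("binary"), mk("continuous"), cov_df, times, subject_id = subj)
}
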