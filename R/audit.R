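#' Compute AUDIT sum scores from item-level data
#'
#' The AUDIT total score is the sum of the ten item scores (each 0-4, so the
#' total ranges 0-40). With `prorate = FALSE` (the default) any missing item
#' renders the sum missing; with `prorate = TRUE` a partially answered
#' questionnaire is prorated by mean imputation of the missing items, rounded
#' to the nearest integer (at least one item must be answered).
#'
#' @param items data frame with columns `subject_id`, `occasion`, and
#'   `item_1` .. `item_10` (integer 0-4 or `NA`).
#' @param prorate logical; prorate partially missing questionnaires.
#' @return tibble with columns `subject_id`, `occasion`, `sum_score`.
#' @examples
#' it <- data.frame(subject_id = "s1", occasion = 0,
#'                  matrix(0L, 1, 10, dimnames = list(NULL, paste0("item_", 1:10))))
#' it$item_1 <- 1L; it$item_2 <- 2L; it$item_5 <- 1L
#' audit_sum_score(it)
#' @export
audit_sum_score <- function(items, prorate = FALSE) {
  item_cols <- paste0("item_", 1:10)
  req <- c("subject_id", "occasion", item_cols)
  missing_cols <- setdiff(req, names(items))
  if (length(missing_cols) > 0L) {
    stop("item table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(items[item_cols])
  storage.mode(m) <- "double"
  bad <- which(!is.na(m) & (m < 0 | m > 4 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(
      "item score out of range 0-4: subject %s, occasion %s, %s (value %s)",
      items$subject_id[b[1L]], items$occasion[b[1L]],
      item_cols[b[2L]], m[b[1L], b[2L]]))
  }
  if (prorate) {
    n_obs <- rowSums(!is.na(m))
    s <- ifelse(n_obs == 0L, NA_real_, round(rowMeans(m, na.rm = TRUE) * 10))
    s[n_obs == 0L] <- NA_real_
  } else {
    s <- rowSums(m)  # NA if any item NA
  }
  tibble::tibble(subject_id = items$subject_id,
                 occasion = items$occasion,
                 sum_score = as.integer(s))
}

#' Severity categories for AUDIT sum scores
#'
#' WHO interpretation bands: 0 no use at all; 1-7 unproblematic use; 8-15
#' medium-level problems (simple advice warranted); 16-19 high-level problems
#' (brief counselling warranted); 20-40 indicating dependence (further
#' diagnostics warranted).
#'
#' @param score integer vector of sum scores (0-40, `NA` allowed).
#' @return ordered factor with levels `no_use`, `unproblematic`,
#'   `medium_problems`, `high_problems`, `dependence_indicated`.
#' @export
audit_severity <- function(score) {
  if (any(!is.na(score) & (score < 0 | score > 40))) {
    stop("sum score outside 0-40: ",
         paste(score[!is.na(score) & (score < 0 | score > 40)], collapse = ", "))
  }
  cut(score, breaks = c(-0.5, 0.5, 7.5, 15.5, 19.5, 40.5),
      labels = c("no_use", "unproblematic", "medium_problems",
                 "high_problems", "dependence_indicated"),
      ordered_result = TRUE)
}

#' Tabulate severity of use by occasion
#'
#' Counts and percentages of each severity category per occasion, mirroring
#' the standard cohort descriptive table (percentages are of the non-missing
#' scores at that occasion).
#'
#' @param sums tibble as returned by [audit_sum_score()].
#' @return tibble with `occasion`, `category`, `n`, `pct`.
#' @export
severity_table <- function(sums) {
  sev <- audit_severity(sums$sum_score)
  keep <- !is.na(sev)
  tab <- table(occasion = sums$occasion[keep], category = sev[keep])
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  totals <- rowSums(tab)
  out$pct <- 100 * out$Freq / totals[out$occasion]
  names(out)[names(out) == "Freq"] <- "n"
  tibble::as_tibble(out[order(out$occasion), c("occasion", "category", "n", "pct")])
}
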