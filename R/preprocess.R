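#' Flag values within k standard deviations of the mean
#'
#' Single-pass outlier screen: values more than `k` SD from the sample mean
#' (mean and SD computed once over the non-missing values) are flagged for
#' exclusion. Missing values stay missing in the returned mask.
#'
#' @param x Numeric vector.
#' @param k SD multiplier (default 3).
#' @return Logical vector: `TRUE` = keep, `FALSE` = outlier, `NA` = missing.
#' @examples
#' exclude_outliers(c(0, 0, 0, 0, 100))   # all kept: |z| < 3 in a 5-point sample
#' @export
exclude_outliers <- function(x, k = 3) {
  k <- check_scalar(k, "k", min = 0)
  ok <- !is.na(x)
  if (sum(ok) < 2L) abort("need at least 2 non-missing values")
  mu <- mean(x[ok])
  s <- sd(x[ok])
  if (s == 0) {
    warn("zero variance: no outliers excluded")
    return(ifelse(ok, TRUE, NA))
  }
  mask <- abs(x - mu) <= k * s
  mask[!ok] <- NA
  mask
}

#' Standardized residuals after covariate regression
#'
#' Regresses a trait on covariates (with intercept) by OLS and returns the
#' residuals scaled to unit standard deviation. Rows with a missing value in
#' the trait or any covariate come back as `NA`.
#'
#' @param x Numeric trait vector.
#' @param covariates Data frame or matrix of covariates (e.g. sex, age).
#' @return Numeric vector of standardized residuals.
#' @export
residualize <- function(x, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(x)) abort("covariates and trait differ in length")
  X <- cbind(`(intercept)` = 1, as.matrix(covariates))
  use <- !is.na(x) & complete.cases(covariates)
  if (sum(use) <= ncol(X)) {
    abort("not enough complete observations for the covariate regression")
  }
  qrX <- qr(X[use, , drop = FALSE])
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    abort(paste0("rank-deficient covariate design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  r <- qr.resid(qrX, x[use])
  out <- rep(NA_real_, length(x))
  out[use] <- r / sd(r)
  out
}

#' Van der Waerden (rank-based inverse-normal) scores
#'
#' Maps each non-missing value to `qnorm(r / (n + 1))`, where `r` is its rank
#' among the non-missing values (ties receive average ranks) and `n` their
#' count. Missing values propagate. The transform depends only on ranks, so
#' any strictly monotone transform of the input yields identical output, and
#' reapplying it is a no-op (up to ties).
#'
#' @param x Numeric vector.
#' @return Numeric vector of normal scores.
#' @examples
#' quantile_normalize(c(5, 1, 3))  # qnorm(c(3, 1, 2) / 4)
#' @export
quantile_normalize <- function(x) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 2L) abort("need at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  out[ok] <- qnorm(rank(x[ok], ties.method = "average") / (n + 1))
  out
}

#' Unit-weighted composite with a completeness requirement
#'
#' Row mean of the available test scores, set to missing when fewer than
#' `min_complete` tests are observed — e.g. at least 3 of 4 tests for a
#' general-ability or reading composite, 2 of 3 for language or mathematics.
#'
#' @param scores Matrix or data frame, one column per test.
#' @param min_complete Minimum number of non-missing tests per row.
#' @return Numeric composite vector.
#' @export
make_composite <- function(scores, min_complete) {
  scores <- as.matrix(scores)
  min_complete <- check_count(min_complete, "min_complete", min = 1L)
  if (min_complete > ncol(scores)) {
    abort("`min_complete` exceeds the number of tests")
  }
  n_obs <- rowSums(!is.na(scores))
  out <- rowMeans(scores, na.rm = TRUE)
  out[n_obs < min_complete] <- NA_real_
  out
}

#' Keep one randomly chosen individual per family
#'
#' Used to turn a twin cohort into a sample of conventionally unrelated
#' individuals (one member per pair) before GRM-based analysis.
#'
#' @param data Data frame with a family-id column.
#' @param family_col Name of the family-id column.
#' @param seed Optional integer seed; the selection is uniform within family
#'   and reproducible given the seed.
#' @return The subset tibble, one row per family, in original row order.
#' @export
select_one_per_family <- function(data, family_col = "fid", seed = NULL) {
  if (!family_col %in% names(data)) {
    abort(sprintf("column `%s` not found", family_col))
  }
  fam <- as.character(data[[family_col]])
  with_seed(seed, {
    pick <- unlist(lapply(split(seq_along(fam), fam), function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }), use.names = FALSE)
    as_tibble(data[sort(pick), , drop = FALSE])
  })
}

#' Phenotype preprocessing pipeline
#'
#' Applies, per trait column and in this order: the k-SD outlier screen,
#' regression on covariates with standardized residuals, and van der Waerden
#' quantile normalization. Anthropometric-style traits can skip the final
#' normalization (`quantile_norm = FALSE`), keeping only the covariate
#' adjustment.
#'
#' @param data Tibble with trait and covariate columns.
#' @param traits Character vector of trait column names.
#' @param covariates Character vector of covariate column names (may be
#'   empty: then only the outlier screen and, optionally, normalization run).
#' @param k_sd Outlier SD multiplier.
#' @param quantile_norm Apply the rank-based inverse-normal transform?
#' @return The tibble with trait columns replaced by processed scores.
#' @export
preprocess_phenotypes <- function(data, traits, covariates = c("sex", "age"),
                                  k_sd = 3, quantile_norm = TRUE) {
  covariates <- intersect(covariates, names(data))
  for (tr in traits) {
    v <- data[[tr]]
    keep <- exclude_outliers(v, k = k_sd)
    v[is.na(keep) | !keep] <- NA_real_
    if (length(covariates)) {
      v <- residualize(v, data[covariates])
    }
    if (quantile_norm) v <- quantile_normalize(v)
    data[[tr]] <- v
  }
  data
}
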