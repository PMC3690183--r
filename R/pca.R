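#' Ancestry principal components of a genotype matrix
#'
#' Eigendecomposition of the relationship matrix built from column-
#' standardized dosages (equivalently, PCA of the standardized genotype
#' matrix). Axis signs are fixed so the largest-magnitude loading on each
#' axis is positive, making the decomposition deterministic. Axis
#' significance is assessed with the sequential Tracy-Widom procedure of
#' [tracy_widom_select()].
#'
#' @param geno A `genotype_matrix` (typically LD- and relatedness-pruned).
#' @param k Number of axes to return (`k < min(n, m)`).
#' @param alpha Significance level for the Tracy-Widom axis selection.
#' @return A `pca_result`: list with `eigenvalues` (all, descending),
#'   `loadings` (n x k orthonormal matrix), `tw` (tibble: axis, statistic,
#'   p.value), `selected` (indices of the leading significant axes), `ids`.
#' @export
pca_axes <- function(geno, k = 10, alpha = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  n <- nrow(geno$dosage)
  m <- ncol(geno$dosage)
  k <- check_count(k, "k", min = 1L)
  if (k >= min(n, m)) abort("`k` must be smaller than min(n_individuals, n_snps)")
  std <- standardize_dosage(geno)
  w <- std$w[, std$polymorphic, drop = FALSE]
  A <- tcrossprod(w) / ncol(w)
  ee <- eigen(A, symmetric = TRUE)
  vals <- ee$values
  load <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  rownames(load) <- rownames(geno$dosage)
  colnames(load) <- paste0("PC", seq_len(k))
  tw <- tracy_widom_select(vals, alpha = alpha)
  structure(
    list(eigenvalues = vals, loadings = load, tw = tw$table,
         selected = tw$selected, ids = rownames(geno$dosage)),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d axes returned; %d significant (Tracy-Widom)\n",
              ncol(x$loadings), length(x$selected)))
  invisible(x)
}

#' Tracy-Widom upper-tail probability
#'
#' Upper-tail probability of the Tracy-Widom TW1 distribution, by linear
#' interpolation of `log p` on an embedded table computed from the Painleve
#' II representation of the TW1 distribution function.
#'
#' @param x Numeric vector of TW1-normalized statistics.
#' @return Upper-tail probabilities.
#' @export
tw_pvalue <- function(x) {
  lo <- .tw1_s[1]
  hi <- .tw1_s[length(.tw1_s)]
  lp <- stats::approx(.tw1_s, .tw1_logp, xout = pmin(pmax(x, lo), hi),
                      rule = 2)$y
  p <- exp(lp)
  p[x > hi] <- exp(.tw1_logp[length(.tw1_logp)])
  p[x < lo] <- 1
  p
}

#' Sequential Tracy-Widom test for significant axes
#'
#' Tests leading eigenvalues of a genotype-derived covariance spectrum in
#' sequence. For each leading eigenvalue, the remaining spectrum of length
#' `p` with sums `S1`, `S2` gives an effective sample size
#' `n_eff = (p + 1) S1^2 / (p S2 - S1^2)` (moment-matched so a white Wishart
#' spectrum recovers its true sample count); the normalized largest
#' eigenvalue `L = p * lambda / S1` is centred and scaled with the
#' Tracy-Widom constants for an `n_eff x p` white Wishart matrix and referred
#' to TW1. Selection keeps the leading run of axes with `p < alpha`,
#' stopping at the first non-significant axis.
#'
#' @param eigenvalues Numeric vector, descending.
#' @param alpha Significance level (default 0.05).
#' @return List: `table` (tibble with axis, eigenvalue, statistic, p.value)
#'   and `selected` (integer indices).
#' @export
tracy_widom_select <- function(eigenvalues, alpha = 0.05) {
  if (length(eigenvalues) < 3L) abort("need at least 3 eigenvalues")
  alpha <- check_scalar(alpha, "alpha", min = 0, max = 1)
  # trailing zero (or negative) eigenvalues carry no information; keep the
  # positive part of the spectrum
  lam_all <- eigenvalues
  n_test <- max(which(lam_all > 1e-12)) - 2L
  n_test <- max(min(n_test, length(lam_all) - 2L), 0L)
  axis <- integer(0); stat <- numeric(0); pval <- numeric(0)
  for (j in seq_len(n_test)) {
    lam <- lam_all[j:length(lam_all)]
    lam <- lam[lam > 1e-12]
    p <- length(lam)
    if (p < 3L || lam[1] <= 0) {
      warn(sprintf("axis %d skipped: non-positive eigenvalues", j))
      break
    }
    s1 <- sum(lam); s2 <- sum(lam^2)
    denom <- p * s2 - s1^2
    if (denom <= 0) break
    n_eff <- (p + 1) * s1^2 / denom
    L1 <- p * lam[1] / s1
    sq <- sqrt(n_eff - 1) + sqrt(p)
    mu <- sq^2 / n_eff
    sig <- sq / n_eff * (1 / sqrt(n_eff - 1) + 1 / sqrt(p))^(1 / 3)
    tw <- (L1 - mu) / sig
    axis <- c(axis, j); stat <- c(stat, tw); pval <- c(pval, tw_pvalue(tw))
  }
  tab <- tibble(axis = axis, eigenvalue = lam_all[axis],
                statistic = stat, p.value = pval)
  sig_run <- which(cumsum(tab$p.value >= alpha) == 0)
  list(table = tab, selected = as.integer(sig_run))
}
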