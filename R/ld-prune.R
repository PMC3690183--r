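#' Sliding-window LD pruning
#'
#' Scans windows of `window` SNPs advancing by `step`, and within each window
#' removes SNPs until no retained pair has a squared Pearson correlation of
#' dosages above `r2_max`. On a conflict the SNP at the earlier position is
#' kept and the later one removed, mirroring the usual position-ordered
#' pruning convention.
#'
#' @param geno A `genotype_matrix`.
#' @param r2_max Maximum tolerated squared correlation (default 0.2).
#' @param window Window size in SNPs (>= 2).
#' @param step Window advance in SNPs.
#' @return Character vector of retained SNP ids, in position order.
#' @export
ld_prune <- function(geno, r2_max = 0.2, window = 50, step = 5) {
  stopifnot(inherits(geno, "genotype_matrix"))
  window <- check_count(window, "window", min = 2L)
  step <- check_count(step, "step", min = 1L)
  r2_max <- check_scalar(r2_max, "r2_max", min = 0, max = 1)

  ord <- order(geno$info$pos)
  x <- geno$dosage[, ord, drop = FALSE]
  m <- ncol(x)
  keep <- rep(TRUE, m)
  # drop monomorphic SNPs up front: correlation undefined
  keep[apply(x, 2, function(v) var(v, na.rm = TRUE)) == 0] <- FALSE

  start <- 1L
  repeat {
    end <- min(start + window - 1L, m)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) >= 2L) {
      r2 <- suppressWarnings(cor(x[, idx, drop = FALSE],
                                 use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      for (b in seq_along(idx)[-1]) {
        if (!keep[idx[b]]) next
        earlier <- idx[seq_len(b - 1L)]
        if (any(r2[b, seq_len(b - 1L)] > r2_max & keep[earlier])) {
          keep[idx[b]] <- FALSE
        }
      }
    }
    if (end == m) break
    start <- start + step
  }
  geno$info$snp_id[ord][keep]
}

#' Subset a genotype matrix to a set of SNPs
#' @param geno A `genotype_matrix`.
#' @param snp_ids SNP ids to keep.
#' @return The subset `genotype_matrix`.
#' @export
geno_subset <- function(geno, snp_ids) {
  ix <- match(snp_ids, colnames(geno$dosage))
  if (anyNA(ix)) abort("unknown SNP ids")
  geno$dosage <- geno$dosage[, ix, drop = FALSE]
  geno$info <- geno$info[ix, , drop = FALSE]
  geno
}

#' Subset a genotype matrix to a set of individuals
#' @param geno A `genotype_matrix`.
#' @param ids Individual ids to keep.
#' @return The subset `genotype_matrix`.
#' @export
geno_subset_individuals <- function(geno, ids) {
  ix <- match(ids, rownames(geno$dosage))
  if (anyNA(ix)) abort("unknown individual ids")
  geno$dosage <- geno$dosage[ix, , drop = FALSE]
  geno$subpop <- geno$subpop[ix]
  geno$info$freq <- colMeans(geno$dosage, na.rm = TRUE) / 2
  geno
}
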