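#' Genomic relationship matrix
#'
#' For individuals j, k and SNPs i with dosage `x`, sample alternate-allele
#' frequency `p_i`:
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' where the sum runs over SNPs non-missing in both individuals and `M_jk` is
#' their count (pairwise-complete handling; with `impute_mean = TRUE` missing
#' dosages are replaced by `2 p_i` and every pair uses all polymorphic SNPs).
#' Monomorphic SNPs are skipped. The same formula is applied on the diagonal.
#'
#' @param geno A `genotype_matrix`.
#' @param impute_mean Replace missing dosages by their SNP mean instead of
#'   pairwise-complete counting.
#' @return A `grm` object: list with `A` (n x n symmetric matrix), `n_snp`
#'   (n x n matrix of per-pair SNP counts) and `ids`.
#' @examples
#' g <- sim_genotypes(50, 200, seed = 1)
#' a <- compute_grm(g)
#' mean(diag(a$A))
#' @export
compute_grm <- function(geno, impute_mean = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(geno$dosage) < 2L) abort("need at least 2 individuals")
  std <- standardize_dosage(geno)
  keep <- std$polymorphic
  if (!any(keep)) abort("no polymorphic SNPs")
  w <- std$w[, keep, drop = FALSE]
  obs <- !is.na(geno$dosage[, keep, drop = FALSE])
  num <- tcrossprod(w)                # missing entries are zero in w
  m_pair <- if (impute_mean) {
    matrix(ncol(w), nrow(w), nrow(w))
  } else {
    tcrossprod(obs * 1)
  }
  if (any(m_pair == 0)) {
    bad <- which(m_pair == 0, arr.ind = TRUE)
    bad <- bad[bad[, 1] <= bad[, 2], , drop = FALSE]
    abort(paste0("pairs with no jointly observed SNP: ",
                 paste(utils::head(apply(bad, 1, paste, collapse = "/"), 5),
                       collapse = ", ")))
  }
  A <- num / m_pair
  ids <- rownames(geno$dosage)
  dimnames(A) <- list(ids, ids)
  dimnames(m_pair) <- list(ids, ids)
  structure(list(A = A, n_snp = m_pair, ids = ids), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat(sprintf(
    "<grm> %d individuals; mean diagonal %.3f; off-diagonal mean %.2e (sd %.3f)\n",
    length(x$ids), mean(diag(x$A)), mean(off), sd(off)
  ))
  invisible(x)
}

#' Subset a GRM to a set of individuals
#' @param grm A `grm`.
#' @param ids Individual ids to keep.
#' @return The subset `grm`.
#' @export
grm_subset <- function(grm, ids) {
  ix <- match(ids, grm$ids)
  if (anyNA(ix)) abort("unknown individual ids")
  structure(
    list(A = grm$A[ix, ix, drop = FALSE],
         n_snp = grm$n_snp[ix, ix, drop = FALSE],
         ids = grm$ids[ix]),
    class = "grm"
  )
}

#' Remove close relatives from a GRM
#'
#' Greedily prunes the sample so that no retained pair has estimated
#' relatedness above `threshold` (default 0.025, roughly a fourth-cousin
#' cutoff). At each step the individual involved in the most over-threshold
#' pairs is dropped; ties drop the higher index, making the result
#' deterministic.
#'
#' @param grm A `grm`.
#' @param threshold Relatedness cutoff (> 0).
#' @return Character vector of retained individual ids.
#' @export
prune_related <- function(grm, threshold = 0.025) {
  if (threshold <= 0) abort("`threshold` must be positive")
  A <- grm$A
  diag(A) <- 0
  alive <- rep(TRUE, nrow(A))
  over <- A > threshold
  repeat {
    counts <- rowSums(over[, alive, drop = FALSE]) * alive
    if (max(counts) == 0) break
    drop <- max(which(counts == max(counts)))   # tie -> higher index
    alive[drop] <- FALSE
    over[drop, ] <- FALSE
    over[, drop] <- FALSE
  }
  grm$ids[alive]
}

#' Write / read a GRM in the GCTA text-triplet format
#'
#' `<prefix>.grm.gz` holds one line per lower-triangle pair (including the
#' diagonal): `index_i index_j n_snps value`, 1-based with `index_i >=
#' index_j`; `<prefix>.grm.id` holds family and individual ids. Values are
#' written with 17 significant digits so a round-trip is bit-exact.
#'
#' @param grm A `grm`.
#' @param prefix Path prefix for the `.grm.gz` / `.grm.id` pair.
#' @return `write_grm` returns `prefix` invisibly; `read_grm` returns a
#'   `grm` (with per-pair SNP counts).
#' @export
write_grm <- function(grm, prefix) {
  n <- length(grm$ids)
  i <- rep(seq_len(n), seq_len(n))
  j <- sequence(seq_len(n))
  lines <- paste(i, j, grm$n_snp[cbind(i, j)], fmt_num(grm$A[cbind(i, j)]),
                 sep = "\t")
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(lines, con)
  close(con)
  writeLines(paste(grm$ids, grm$ids, sep = "\t"), paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' @rdname write_grm
#' @export
read_grm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")[[2]]
  tr <- read.table(gzfile(paste0(prefix, ".grm.gz")), header = FALSE,
                   col.names = c("i", "j", "n", "value"),
                   colClasses = c("integer", "integer", "numeric", "numeric"))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tr$i, tr$j)] <- tr$value
  A[cbind(tr$j, tr$i)] <- tr$value
  M[cbind(tr$i, tr$j)] <- tr$n
  M[cbind(tr$j, tr$i)] <- tr$n
  structure(list(A = A, n_snp = M, ids = ids), class = "grm")
}
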