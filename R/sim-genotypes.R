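#' Simulate unlinked biallelic SNP genotypes
#'
#' Draws additive dosages (0/1/2 copies of the alternate allele) at `m`
#' independent SNPs for `n` individuals. Ancestral allele frequencies are
#' uniform on `maf_range`. With `fst > 0`, each subpopulation receives its own
#' frequency drawn from the Balding-Nichols distribution
#' `Beta(p (1 - Fst) / Fst, (1 - p)(1 - Fst) / Fst)`, which has mean `p` and
#' variance `Fst p (1 - p)`; this is the standard model for simulating
#' ancestral stratification that principal-component covariates must absorb.
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range Length-2 numeric, ancestral frequency range in (0, 0.5].
#' @param fst Wright's fixation index governing subpopulation differentiation
#'   (0 = panmictic).
#' @param subpop_fractions Proportions of the sample assigned to each
#'   subpopulation; must sum to 1.
#' @param seed Optional integer seed; identical seeds give identical cohorts.
#'
#' @return A `genotype_matrix` object: list with `dosage` (n x m integer
#'   matrix, rownames = individual ids), `info` (tibble: snp_id, chrom, pos,
#'   ref, alt, ancestral frequency `p`, sample frequency `freq`), and
#'   `subpop` (integer subpopulation label per individual).
#' @examples
#' g <- sim_genotypes(50, 100, seed = 1)
#' dim(g$dosage)
#' @export
sim_genotypes <- function(n, m, maf_range = c(0.05, 0.5), fst = 0,
                          subpop_fractions = 1, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  m <- check_count(m, "m", min = 1L)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5] with min <= max.")
  }
  fst <- check_scalar(fst, "fst", min = 0, max = 0.999)
  if (any(subpop_fractions <= 0) || abs(sum(subpop_fractions) - 1) > 1e-8) {
    abort("`subpop_fractions` must be positive and sum to 1.")
  }
  n_pop <- length(subpop_fractions)

  with_seed(seed, {
    # deterministic subpopulation assignment by fractions (rounded shares)
    sizes <- diff(round(cumsum(c(0, subpop_fractions)) * n))
    sizes[n_pop] <- n - sum(sizes[-n_pop])
    subpop <- rep(seq_len(n_pop), times = sizes)

    p_anc <- runif(m, maf_range[1], maf_range[2])
    dosage <- matrix(0L, n, m)
    if (fst > 0 && n_pop > 1L) {
      for (k in seq_len(n_pop)) {
        rows <- which(subpop == k)
        a <- p_anc * (1 - fst) / fst
        b <- (1 - p_anc) * (1 - fst) / fst
        p_k <- rbeta(m, a, b)
        p_k <- pmin(pmax(p_k, 1e-6), 1 - 1e-6)
        dosage[rows, ] <- matrix(
          rbinom(length(rows) * m, 2L, rep(p_k, each = length(rows))),
          nrow = length(rows)
        )
      }
    } else {
      dosage[] <- rbinom(n * m, 2L, rep(p_anc, each = n))
    }

    ids <- sprintf("ind_%04d", seq_len(n))
    rownames(dosage) <- ids
    snp_ids <- sprintf("snp_%05d", seq_len(m))
    colnames(dosage) <- snp_ids

    info <- tibble(
      snp_id = snp_ids,
      chrom = "1",
      pos = seq_len(m),
      ref = "A",
      alt = "G",
      p = p_anc,
      freq = colMeans(dosage, na.rm = TRUE) / 2
    )
    structure(
      list(dosage = dosage, info = info, subpop = subpop),
      class = "genotype_matrix"
    )
  })
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d SNPs (%d subpopulation%s, %.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), length(unique(x$subpop)),
    if (length(unique(x$subpop)) > 1) "s" else "",
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' Inject missing genotype calls
#'
#' Sets a random fraction of dosage cells to `NA`, to exercise the
#' pairwise-complete SNP counts of the relationship-matrix builder.
#'
#' @param geno A `genotype_matrix`.
#' @param rate Per-cell missingness probability.
#' @param seed Optional integer seed.
#' @return The `genotype_matrix` with missing calls and refreshed sample
#'   frequencies.
#' @export
add_missing_genotypes <- function(geno, rate, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  rate <- check_scalar(rate, "rate", min = 0, max = 1)
  with_seed(seed, {
    miss <- runif(length(geno$dosage)) < rate
    geno$dosage[miss] <- NA_integer_
    geno$info$freq <- colMeans(geno$dosage, na.rm = TRUE) / 2
    geno
  })
}

# column-standardized dosages (x - 2p) / sqrt(2 p (1 - p)) using sample
# frequencies; missing entries become 0 so they drop out of cross-products
standardize_dosage <- function(geno, impute_zero = TRUE) {
  x <- geno$dosage
  p <- colMeans(x, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  w <- sweep(x, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  if (impute_zero) w[is.na(w)] <- 0
  list(w = w, p = p, polymorphic = keep)
}
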