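#' Simulate a pair of traits with a known pleiotropic architecture
#'
#' Draws two quantitative traits from the additive model that bivariate GREML
#' estimates: a subset of `n_causal` SNPs receives bivariate effect sizes
#' `beta_i ~ MVN(0, sigma_g / n_causal)` on the standardized-dosage scale, so
#' the genetic covariance of the traits converges to `sigma_g`; residuals are
#' `MVN(0, sigma_e)`. The true genetic correlation is
#' `sigma_g[1,2] / sqrt(sigma_g[1,1] * sigma_g[2,2])`.
#'
#' Monomorphic (zero-variance) SNPs are never chosen as causal: the causal set
#' is drawn uniformly from the polymorphic SNPs.
#'
#' @param geno A `genotype_matrix` from [sim_genotypes()].
#' @param n_causal Number of causal SNPs (at most the number of polymorphic
#'   SNPs).
#' @param sigma_g 2x2 positive semi-definite genetic covariance matrix.
#' @param sigma_e 2x2 positive semi-definite residual covariance matrix.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `fid`, `iid`, `trait1`, `trait2`. The causal
#'   SNP ids, effect sizes and realized genetic values are attached as
#'   attributes `causal`, `effects`, `genetic_values`.
#' @examples
#' g <- sim_genotypes(200, 500, seed = 1)
#' ph <- sim_phenotypes(g, 50, diag(2) * 0.35, diag(2) * 0.65, seed = 2)
#' cor(ph$trait1, ph$trait2)
#' @export
sim_phenotypes <- function(geno, n_causal, sigma_g, sigma_e, seed = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  sigma_g <- check_psd(sigma_g, "sigma_g")
  sigma_e <- check_psd(sigma_e, "sigma_e")
  std <- standardize_dosage(geno)
  poly <- which(std$polymorphic)
  n_causal <- check_count(n_causal, "n_causal", min = 1L)
  if (n_causal > length(poly)) {
    abort("`n_causal` exceeds the number of polymorphic SNPs.")
  }
  n <- nrow(geno$dosage)

  with_seed(seed, {
    causal <- sort(sample(poly, n_causal))
    if (all(sigma_g == 0)) {
      gv <- matrix(0, n, 2)
      beta <- matrix(0, n_causal, 2)
    } else {
      beta <- MASS::mvrnorm(n_causal, c(0, 0), sigma_g / n_causal)
      beta <- matrix(beta, ncol = 2)
      gv <- std$w[, causal, drop = FALSE] %*% beta
    }
    ev <- MASS::mvrnorm(n, c(0, 0), sigma_e)
    y <- gv + ev
    out <- tibble(
      fid = rownames(geno$dosage),
      iid = rownames(geno$dosage),
      trait1 = y[, 1],
      trait2 = y[, 2]
    )
    attr(out, "causal") <- colnames(geno$dosage)[causal]
    attr(out, "effects") <- beta
    attr(out, "genetic_values") <- gv
    out
  })
}

#' Attach sex and age covariates with known linear effects
#'
#' Adds `sex ~ Bernoulli(0.5)` (coded 0/1) and `age ~ Uniform(11, 12)` to a
#' phenotype table and shifts each trait by the requested slopes, so that the
#' covariate-regression stage of the preprocessing pipeline has a known signal
#' to remove.
#'
#' @param phen Phenotype tibble with columns `trait1`, `trait2`.
#' @param sex_effect,age_effect Length-2 slopes (one per trait).
#' @param seed Optional integer seed.
#' @return The tibble with `sex`, `age` columns and perturbed traits.
#' @export
attach_covariates <- function(phen, sex_effect = c(0, 0), age_effect = c(0, 0),
                              seed = NULL) {
  stopifnot(is.data.frame(phen), all(c("trait1", "trait2") %in% names(phen)))
  stopifnot(length(sex_effect) == 2L, length(age_effect) == 2L)
  with_seed(seed, {
    n <- nrow(phen)
    phen$sex <- rbinom(n, 1L, 0.5)
    phen$age <- runif(n, 11, 12)
    phen$trait1 <- phen$trait1 + sex_effect[1] * phen$sex + age_effect[1] * phen$age
    phen$trait2 <- phen$trait2 + sex_effect[2] * phen$sex + age_effect[2] * phen$age
    as_tibble(phen)
  })
}

#' Inject missing phenotype values
#'
#' @param phen Phenotype tibble.
#' @param rate Per-cell missingness probability applied to the trait columns.
#' @param traits Trait column names.
#' @param seed Optional integer seed.
#' @return The tibble with missing trait values.
#' @export
add_missing_phenotypes <- function(phen, rate, traits = c("trait1", "trait2"),
                                   seed = NULL) {
  rate <- check_scalar(rate, "rate", min = 0, max = 1)
  with_seed(seed, {
    for (tr in traits) {
      phen[[tr]][runif(nrow(phen)) < rate] <- NA_real_
    }
    phen
  })
}
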