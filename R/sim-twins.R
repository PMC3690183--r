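#' Simulate bivariate twin pairs under a Cholesky ACE model
#'
#' Each pair's four observations (two traits x two twins) are drawn from a
#' 4-variate normal with within-person covariance `aa' + cc' + ee'` and
#' cross-twin covariance `aa' + cc'` for monozygotic pairs or
#' `0.5 aa' + cc'` for dizygotic pairs — the standard biometric expectation
#' with the dizygotic additive-genetic coefficient fixed at 1/2.
#'
#' @param n_mz,n_dz Numbers of MZ and DZ pairs (either may be 0, not both).
#' @param a,c,e Lower-triangular 2x2 path matrices for the additive genetic,
#'   shared environmental and non-shared environmental factors.
#' @param mu Length-2 trait means.
#' @param seed Optional integer seed.
#'
#' @return A `twin_dataset` tibble with columns `pair_id`,
#'   `zygosity` ("MZ"/"DZ"), `t1_twin1`, `t2_twin1`, `t1_twin2`, `t2_twin2`.
#' @examples
#' tw <- sim_twins(100, 100, a = diag(2) * 0.7, c = diag(2) * 0.3,
#'                 e = diag(2) * 0.6, seed = 1)
#' @export
sim_twins <- function(n_mz, n_dz, a, c, e, mu = c(0, 0), seed = NULL) {
  n_mz <- check_count(n_mz, "n_mz", min = 0L)
  n_dz <- check_count(n_dz, "n_dz", min = 0L)
  if (n_mz + n_dz == 0L) abort("need at least one twin pair")
  pa <- check_lower_tri(a, "a")
  pc <- check_lower_tri(c, "c")
  pe <- check_lower_tri(e, "e")

  SA <- tcrossprod(pa); SC <- tcrossprod(pc); SE <- tcrossprod(pe)
  S <- SA + SC + SE
  sig4 <- function(cross) rbind(cbind(S, cross), cbind(cross, S))

  with_seed(seed, {
    draw <- function(n, cross) {
      if (n == 0L) return(matrix(numeric(0), 0, 4))
      MASS::mvrnorm(n, rep(mu, 2), sig4(cross))
    }
    zmz <- draw(n_mz, SA + SC)
    zdz <- draw(n_dz, 0.5 * SA + SC)
    z <- rbind(zmz, zdz)
    out <- tibble(
      pair_id = sprintf("pair_%04d", seq_len(n_mz + n_dz)),
      zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
      t1_twin1 = z[, 1], t2_twin1 = z[, 2],
      t1_twin2 = z[, 3], t2_twin2 = z[, 4]
    )
    class(out) <- c("twin_dataset", class(out))
    out
  })
}

#' Path matrices reproducing given ACE covariance components
#'
#' Inverts the Cholesky ACE parameterization: given the additive genetic,
#' shared and non-shared environmental covariance matrices (e.g. standardized
#' components from a twin report, which are covariance matrices when traits
#' have unit variance), returns the lower-triangular path matrices `a`, `c`,
#' `e` such that `aa'`, `cc'`, `ee'` reproduce them.
#'
#' @param sigma_a,sigma_c,sigma_e 2x2 positive semi-definite matrices.
#' @return List with lower-triangular matrices `a`, `c`, `e`.
#' @export
ace_paths <- function(sigma_a, sigma_c, sigma_e) {
  list(
    a = lower_chol(check_psd(sigma_a, "sigma_a")),
    c = lower_chol(check_psd(sigma_c, "sigma_c")),
    e = lower_chol(check_psd(sigma_e, "sigma_e"))
  )
}
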