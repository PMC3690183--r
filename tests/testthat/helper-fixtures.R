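# shared fixtures and independent oracles used across test files

# published reference variance components (bivariate DNA-based analysis):
# V(G)_tr1, V(G)_tr2, C(G)_tr12, V(e)_tr1, V(e)_tr2, C(e)_tr12
ref_gcta <- list(
  g_language = c(vg1 = 0.36, vg2 = 0.35, cg = 0.29,
                 ve1 = 0.63, ve2 = 0.65, ce = 0.33),
  g_maths    = c(vg1 = 0.36, vg2 = 0.32, cg = 0.25,
                 ve1 = 0.64, ve2 = 0.67, ce = 0.38)
)

# published reference twin ACE components (standardized)
ref_twin <- list(
  g_maths = list(A = matrix(c(0.46, 0.36, 0.36, 0.48), 2),
                 C = matrix(c(0.21, 0.19, 0.19, 0.20), 2),
                 E = matrix(c(0.33, 0.07, 0.07, 0.32), 2)),
  g_reading = c(vg1 = 0.46, vg2 = 0.59, cg = 0.34),
  height_weight = list(A = matrix(c(0.81, 0.54, 0.54, 0.85), 2),
                       C = matrix(c(0.09, 0.06, 0.06, 0.04), 2),
                       E = matrix(c(0.10, 0.06, 0.06, 0.11), 2))
)

sigma_g_ref <- matrix(c(0.36, 0.29, 0.29, 0.35), 2)
sigma_e_ref <- matrix(c(0.63, 0.33, 0.33, 0.65), 2)

# independently coded dense bivariate REML objective (the brute-force oracle
# for the AI-REML implementation); complete data, intercept-only designs
oracle_biv_m2reml <- function(theta, A, y1, y2) {
  n <- nrow(A)
  In <- diag(n)
  V <- rbind(cbind(theta[1] * A + theta[4] * In, theta[3] * A + theta[6] * In),
             cbind(theta[3] * A + theta[6] * In, theta[2] * A + theta[5] * In))
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(1e10)
  # the raw REML likelihood is unbounded at singular V (degenerate spikes);
  # the comparison targets the interior optimum, so near-singular V is
  # rejected rather than rewarded
  if (min(diag(cV))^2 < 1e-5 * max(diag(cV))^2) return(1e10)
  Vi <- chol2inv(cV)
  X <- rbind(cbind(rep(1, n), 0), cbind(0, rep(1, n)))
  y <- c(y1, y2)
  M <- t(X) %*% Vi %*% X
  b <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(2 * sum(log(diag(cV))) + determinant(M)$modulus +
               t(r) %*% Vi %*% r)
}

oracle_uni_m2reml <- function(theta, A, y) {
  n <- nrow(A)
  V <- theta[1] * A + theta[2] * diag(n)
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(1e10)
  Vi <- chol2inv(cV)
  X <- matrix(1, n, 1)
  M <- t(X) %*% Vi %*% X
  b <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(2 * sum(log(diag(cV))) + log(M[1, 1]) + t(r) %*% Vi %*% r)
}

# Derivative-free minimization of the oracle objective from a neutral
# moment-based start, with polish restarts (restarting the simplex from its
# own solution until it stops improving). At toy sample sizes the REML
# surface also has degenerate spikes at singular covariance, so a global
# search is not the oracle's job: both routes target the interior optimum
# reached from the half-the-phenotypic-covariance start.
oracle_minimize <- function(obj, start) {
  best <- optim(start, obj, method = "Nelder-Mead",
                control = list(maxit = 50000, reltol = 1e-15))
  for (k in 1:6) {
    nxt <- optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 50000, reltol = 1e-15))
    improved <- nxt$value < best$value - 1e-12
    best <- nxt
    if (!improved) break
  }
  best
}

# the same moment-based starting point the AI-REML route uses
oracle_start_biv <- function(y1, y2) {
  v1 <- var(y1); v2 <- var(y2); c12 <- cov(y1, y2) / 2
  c(v1 / 2, v2 / 2, c12, v1 / 2, v2 / 2, c12)
}

# Toy instances for oracle-equivalence checks (n <= 30). Variance components
# are identified by relatedness contrast, so the cohort carries planted
# close relatives (pairs sharing 85% of their dosages): the GRM spectrum is
# then well spread and the REML surface has a clean interior optimum that
# both optimization routes must reach. Generating correlations are kept
# moderate so the optimum stays away from the PSD boundary.
make_toy_cohort <- function(i, n = 30, m = 100) {
  sg <- matrix(c(0.5, 0.15, 0.15, 0.45), 2)
  se <- matrix(c(0.5, 0.10, 0.10, 0.55), 2)
  g <- sim_genotypes(n, m, seed = 9000 + i)
  set.seed(400 + i)
  for (k in seq_len(n %/% 2)) {
    keep <- runif(m) < 0.85
    g$dosage[2 * k, keep] <- g$dosage[2 * k - 1, keep]
  }
  ph <- suppressWarnings(sim_phenotypes(g, 40, sg, se, seed = 9500 + i))
  list(geno = g, grm = compute_grm(g), ph = ph)
}

# build a grm object directly from a relatedness matrix (for pruning tests)
make_grm <- function(A, n_snp = 1000L) {
  ids <- sprintf("ind_%04d", seq_len(nrow(A)))
  dimnames(A) <- list(ids, ids)
  structure(list(A = A, n_snp = matrix(n_snp, nrow(A), nrow(A)), ids = ids),
            class = "grm")
}
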