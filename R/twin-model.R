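#' Control parameters for the twin-model optimizer
#'
#' @param n_restarts Number of seeded random restarts of the quasi-Newton
#'   optimizer (guards against local optima; the reported solution is the
#'   lowest `-2 lnL`).
#' @param seed Seed for the restart perturbations.
#' @param max_iter Iteration cap per optimizer run.
#' @return A list of class `twin_control`.
#' @export
twin_control <- function(n_restarts = 5, seed = 42, max_iter = 1000) {
  structure(list(n_restarts = check_count(n_restarts, "n_restarts", min = 1L),
                 seed = seed,
                 max_iter = check_count(max_iter, "max_iter")),
            class = "twin_control")
}

# sufficient statistics per (zygosity x missingness pattern) group:
# group-wise counts, means and MLE scatter matrices carry the whole
# multivariate-normal likelihood
twin_groups <- function(data) {
  z <- as.matrix(data[, c("t1_twin1", "t2_twin1", "t1_twin2", "t2_twin2")])
  zyg <- as.character(data$zygosity)
  if (!all(zyg %in% c("MZ", "DZ"))) abort("zygosity must be 'MZ' or 'DZ'")
  pat <- apply(!is.na(z), 1, paste, collapse = "")
  keys <- split(seq_len(nrow(z)), paste(zyg, pat))
  groups <- list()
  for (ix in keys) {
    obs <- !is.na(z[ix[1], ])
    if (!any(obs)) next
    sub <- z[ix, obs, drop = FALSE]
    mu <- colMeans(sub)
    S <- crossprod(sweep(sub, 2, mu)) / nrow(sub)
    groups[[length(groups) + 1L]] <- list(
      zyg = zyg[ix[1]], obs = obs, n = nrow(sub), mean = mu, S = S
    )
  }
  groups
}

# expected 4x4 covariance and mean under the Cholesky ACE model
twin_expected <- function(SA, SC, SE, mu, zyg) {
  S <- SA + SC + SE
  cross <- if (zyg == "MZ") SA + SC else 0.5 * SA + SC
  list(cov = rbind(cbind(S, cross), cbind(cross, S)),
       mean = rep(mu, 2))
}

# -2 log-likelihood over sufficient-statistic groups
twin_m2ll <- function(par, groups, mask) {
  th <- unmask_par(par, mask)
  SA <- tcrossprod(th$a); SC <- tcrossprod(th$c); SE <- tcrossprod(th$e)
  total <- 0
  for (g in groups) {
    ex <- twin_expected(SA, SC, SE, th$mu, g$zyg)
    Sig <- ex$cov[g$obs, g$obs, drop = FALSE]
    cS <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(cS)) return(1e10)
    k <- sum(g$obs)
    delta <- g$mean - ex$mean[g$obs]
    Sinv <- chol2inv(cS)
    total <- total + g$n * (k * log(2 * pi) + 2 * sum(log(diag(cS))) +
                              sum(Sinv * g$S) + drop(t(delta) %*% Sinv %*% delta))
  }
  total
}

# free-parameter packing: full parameterization is
# (a11, a21, a22, c11, c21, c22, e11, e21, e22, mu1, mu2); restricted models
# fix whole path matrices at zero
par_mask <- function(model) {
  keep <- c(A = model %in% c("ACE", "AE"),
            C = model %in% c("ACE", "CE"),
            E = TRUE)
  mask <- c(rep(keep["A"], 3), rep(keep["C"], 3), rep(keep["E"], 3), TRUE, TRUE)
  names(mask) <- c("a11", "a21", "a22", "c11", "c21", "c22",
                   "e11", "e21", "e22", "mu1", "mu2")
  mask
}

unmask_par <- function(par, mask) {
  full <- numeric(length(mask))
  full[mask] <- par
  lt <- function(v) matrix(c(v[1], v[2], 0, v[3]), 2, 2)
  list(a = lt(full[1:3]), c = lt(full[4:6]), e = lt(full[7:9]),
       mu = full[10:11])
}

# moment-based starting values: the biometric expectations invert to
# SA = 2 (MZcross - DZcross), SC = 2 DZcross - MZcross, SE = within - MZcross
twin_moment_start <- function(groups) {
  acc <- function(zyg) {
    w <- matrix(0, 2, 2); x <- matrix(0, 2, 2); n <- 0
    for (g in groups) {
      if (g$zyg != zyg || !all(g$obs) || g$n < 2) next
      S <- g$S
      w <- w + g$n * (S[1:2, 1:2] + S[3:4, 3:4]) / 2
      x <- x + g$n * (S[1:2, 3:4] + t(S[1:2, 3:4])) / 2
      n <- n + g$n
    }
    if (n == 0) return(NULL)
    list(within = w / n, cross = x / n)
  }
  mz <- acc("MZ"); dz <- acc("DZ")
  if (is.null(mz) || is.null(dz)) {
    # fall back to an agnostic equal split of the pooled within-person moments
    pool <- if (!is.null(mz)) mz$within else dz$within
    SA <- SC <- SE <- pool / 3
  } else {
    SA <- 2 * (mz$cross - dz$cross)
    SC <- 2 * dz$cross - mz$cross
    SE <- (mz$within + dz$within) / 2 - mz$cross
  }
  mu <- c(0, 0); nsum <- 0
  for (g in groups) {
    if (!all(g$obs)) next
    mu <- mu + g$n * (g$mean[1:2] + g$mean[3:4]) / 2
    nsum <- nsum + g$n
  }
  if (nsum > 0) mu <- mu / nsum
  list(a = lower_chol(psd_project(SA)), c = lower_chol(psd_project(SC)),
       e = lower_chol(psd_project(SE, floor = 1e-3)), mu = mu)
}

psd_project <- function(m, floor = 0) {
  m <- (m + t(m)) / 2
  ee <- eigen(m, symmetric = TRUE)
  ee$vectors %*% diag(pmax(ee$values, floor), 2) %*% t(ee$vectors)
}

#' Bivariate Cholesky ACE twin model
#'
#' Fits the bivariate ACE model to MZ/DZ twin pairs by full-information
#' maximum likelihood. The additive-genetic, shared- and non-shared-
#' environmental covariance matrices are parameterized through lower-
#' triangular path matrices (`Sigma_A = a a'` etc., positive semi-definite by
#' construction). Expected per-pair covariance: within-person blocks
#' `Sigma_A + Sigma_C + Sigma_E` for both zygosities; cross-twin blocks
#' `Sigma_A + Sigma_C` (MZ) and `0.5 Sigma_A + Sigma_C` (DZ). One free mean
#' per trait is shared across twin order and zygosity. Pairs with missing
#' cells contribute their observed sub-vector likelihood. Standard errors
#' come from the numerical Hessian of `-2 lnL` at the optimum; derived
#' quantities (standardized components and the component correlations) get
#' delta-method standard errors.
#'
#' @param data A `twin_dataset` tibble (see [sim_twins()]), or any data frame
#'   with columns `zygosity`, `t1_twin1`, `t2_twin1`, `t1_twin2`, `t2_twin2`.
#' @param model `"ACE"` (default) or a restriction: `"AE"`, `"CE"`, `"E"`.
#' @param control A [twin_control()].
#' @return A `twin_fit`: path matrices (canonical nonnegative-diagonal form),
#'   component covariance matrices, Table-style standardized components,
#'   component correlations with SEs, `minus2lnL`, parameter covariance and
#'   sample sizes.
#' @examples
#' tw <- sim_twins(150, 150, a = diag(2) * .7, c = diag(2) * .3,
#'                 e = diag(2) * .65, seed = 3)
#' fit <- fit_twin_cholesky(tw)
#' component_correlations(fit)
#' @export
fit_twin_cholesky <- function(data, model = c("ACE", "AE", "CE", "E"),
                              control = twin_control()) {
  model <- match.arg(model)
  groups <- twin_groups(data)
  n_mz <- sum(data$zygosity == "MZ"); n_dz <- sum(data$zygosity == "DZ")
  if (model == "ACE" && (n_mz < 20 || n_dz < 20)) {
    warn("fewer than 20 MZ or DZ pairs; ACE components are weakly identified")
  }
  n_complete <- sum(stats::complete.cases(
    data[, c("t1_twin1", "t2_twin1", "t1_twin2", "t2_twin2")]))
  fit_twin_groups(groups, model, control,
                  n_pairs = c(MZ = n_mz, DZ = n_dz), n_complete = n_complete)
}

#' Fit the twin model to moment matrices
#'
#' Entry point for fitting from sufficient statistics rather than raw pairs:
#' supply the 4x4 observed covariance matrix (and optionally mean) per
#' zygosity. Feeding exact population moments recovers the generating
#' parameters exactly (to optimizer tolerance), which is the noise-free check
#' of the likelihood machinery.
#'
#' @param mz_cov,dz_cov 4x4 covariance matrices, variable order
#'   `(t1_twin1, t2_twin1, t1_twin2, t2_twin2)`.
#' @param n_mz,n_dz Pair counts behind each matrix.
#' @param mz_mean,dz_mean Length-4 mean vectors (default zero).
#' @param model,control As in [fit_twin_cholesky()].
#' @return A `twin_fit`.
#' @export
fit_twin_moments <- function(mz_cov, dz_cov, n_mz, n_dz,
                             mz_mean = rep(0, 4), dz_mean = rep(0, 4),
                             model = "ACE", control = twin_control()) {
  groups <- list(
    list(zyg = "MZ", obs = rep(TRUE, 4), n = n_mz, mean = mz_mean, S = mz_cov),
    list(zyg = "DZ", obs = rep(TRUE, 4), n = n_dz, mean = dz_mean, S = dz_cov)
  )
  fit_twin_groups(groups, model, control,
                  n_pairs = c(MZ = n_mz, DZ = n_dz), n_complete = n_mz + n_dz)
}

fit_twin_groups <- function(groups, model, control, n_pairs, n_complete) {
  mask <- par_mask(model)
  st <- twin_moment_start(groups)
  full0 <- c(st$a[c(1, 2, 4)], st$c[c(1, 2, 4)], st$e[c(1, 2, 4)], st$mu)
  par0 <- full0[mask]
  obj <- function(p) twin_m2ll(p, groups, mask)

  best <- NULL
  with_seed(control$seed, {
    for (r in seq_len(control$n_restarts)) {
      start <- if (r == 1) par0 else par0 * (1 + 0.3 * rnorm(length(par0))) +
        0.05 * rnorm(length(par0))
      res <- tryCatch(
        nlminb(start, obj, control = list(iter.max = control$max_iter,
                                          eval.max = 4 * control$max_iter,
                                          rel.tol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      if (is.null(best) || res$objective < best$objective - 1e-9) best <- res
    }
  })
  if (is.null(best)) abort("twin-model optimizer failed in all restarts")
  if (best$convergence != 0 && !grepl("relative convergence|both X|singular",
                                      best$message %||% "")) {
    warn(paste0("optimizer message: ", best$message))
  }

  th <- unmask_par(best$par, mask)
  # canonical form: likelihood is invariant to column sign flips of the path
  # matrices; report nonnegative diagonals
  canon <- function(L) {
    if (L[1, 1] < 0) L[, 1] <- -L[, 1]
    if (L[2, 2] < 0) L[, 2] <- -L[, 2]
    L
  }
  th$a <- canon(th$a); th$c <- canon(th$c); th$e <- canon(th$e)
  full <- c(th$a[c(1, 2, 4)], th$c[c(1, 2, 4)], th$e[c(1, 2, 4)], th$mu)
  par_hat <- full[mask]

  H <- tryCatch(optimHess(par_hat, obj), error = function(e) NULL)
  vcov_par <- if (!is.null(H)) {
    tryCatch(2 * solve(H), error = function(e) NULL)
  }
  se_available <- !is.null(vcov_par) && all(is.finite(vcov_par)) &&
    all(diag(vcov_par) >= -1e-8)
  if (!se_available) vcov_par <- NULL

  derived <- twin_derived(par_hat, mask)
  der_se <- rep(NA_real_, length(derived))
  if (se_available) {
    J <- numeric_jacobian(function(p) twin_derived(p, mask), par_hat)
    dv <- J %*% vcov_par %*% t(J)
    der_se <- sqrt(pmax(diag(dv), 0))
  }
  names(der_se) <- names(derived)

  structure(
    list(paths = th[c("a", "c", "e")],
         Sigma = list(A = tcrossprod(th$a), C = tcrossprod(th$c),
                      E = tcrossprod(th$e)),
         means = th$mu,
         derived = derived, derived_se = der_se,
         minus2lnL = best$objective,
         par = par_hat, par_mask = mask, vcov_par = vcov_par,
         se_available = se_available,
         n_pairs = n_pairs, n_complete = n_complete,
         model = model, convergence = best$convergence),
    class = "twin_fit"
  )
}

# map free parameters to all reported quantities (standardized components
# per the usual twin-table layout, plus the three component correlations)
twin_derived <- function(par, mask) {
  th <- unmask_par(par, mask)
  SA <- tcrossprod(th$a); SC <- tcrossprod(th$c); SE <- tcrossprod(th$e)
  vp <- diag(SA + SC + SE)
  gm <- sqrt(vp[1] * vp[2])
  rr <- function(S) if (S[1, 1] > 0 && S[2, 2] > 0) {
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  } else NA_real_
  c(
    VG_tr1 = SA[1, 1] / vp[1], VG_tr2 = SA[2, 2] / vp[2], CG_tr12 = SA[1, 2] / gm,
    VC_tr1 = SC[1, 1] / vp[1], VC_tr2 = SC[2, 2] / vp[2], CC_tr12 = SC[1, 2] / gm,
    VE_tr1 = SE[1, 1] / vp[1], VE_tr2 = SE[2, 2] / vp[2], CE_tr12 = SE[1, 2] / gm,
    r_G = rr(SA), r_C = rr(SC), r_E = rr(SE),
    r_P = (SA[1, 2] + SC[1, 2] + SE[1, 2]) / gm
  )
}

numeric_jacobian <- function(f, x, eps = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit> %s model, -2lnL = %.3f (%d MZ + %d DZ pairs)\n",
              x$model, x$minus2lnL, x$n_pairs["MZ"], x$n_pairs["DZ"]))
  print(round(rbind(estimate = x$derived, se = x$derived_se), 3))
  invisible(x)
}

#' Standardized twin-model components
#'
#' Per trait, the A/C/E covariance components divided by the fitted total
#' variance; cross-trait components scaled by the geometric mean of the two
#' fitted variances, so that the three standardized covariance components sum
#' to the fitted phenotypic correlation.
#'
#' @param fit A `twin_fit`.
#' @return Tibble with one row per component (A, C, E): standardized
#'   variances, standardized covariance, component correlation, and SEs.
#' @export
twin_standardized <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  d <- fit$derived; s <- fit$derived_se
  tibble(
    component = c("A", "C", "E"),
    V_tr1 = d[c("VG_tr1", "VC_tr1", "VE_tr1")],
    V_tr1_se = s[c("VG_tr1", "VC_tr1", "VE_tr1")],
    V_tr2 = d[c("VG_tr2", "VC_tr2", "VE_tr2")],
    V_tr2_se = s[c("VG_tr2", "VC_tr2", "VE_tr2")],
    C_tr12 = d[c("CG_tr12", "CC_tr12", "CE_tr12")],
    C_tr12_se = s[c("CG_tr12", "CC_tr12", "CE_tr12")],
    r = d[c("r_G", "r_C", "r_E")],
    r_se = s[c("r_G", "r_C", "r_E")]
  )
}

#' Component correlations of a twin fit
#'
#' `r_X = Sigma_X[1,2] / sqrt(Sigma_X[1,1] * Sigma_X[2,2])` for X = A, C, E,
#' with delta-method standard errors from the path-parameter covariance.
#'
#' @param fit A `twin_fit`.
#' @return Tibble with `component`, `estimate`, `std.error`.
#' @export
component_correlations <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"))
  tibble(
    component = c("r_G", "r_C", "r_E"),
    estimate = unname(fit$derived[c("r_G", "r_C", "r_E")]),
    std.error = unname(fit$derived_se[c("r_G", "r_C", "r_E")])
  )
}
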