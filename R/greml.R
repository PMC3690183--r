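#' Control parameters for REML fitting
#'
#' @param max_iter Iteration cap (error on non-convergence).
#' @param tol Convergence tolerance on the change in the REML log-likelihood.
#' @param em_steps Number of initial EM-flavoured updates before switching to
#'   average-information updates.
#' @param verbose Print the per-iteration log-likelihood?
#' @return A list of class `greml_control`.
#' @export
greml_control <- function(max_iter = 100, tol = 1e-8, em_steps = 1,
                          verbose = FALSE) {
  structure(list(max_iter = check_count(max_iter, "max_iter"),
                 tol = check_scalar(tol, "tol", min = 0),
                 em_steps = check_count(em_steps, "em_steps", min = 0L),
                 verbose = isTRUE(verbose)),
            class = "greml_control")
}

# Generic REML driver. `engine(theta)` must return
# list(logL, score, AI, N, ok); variance components are unconstrained
# (GCTA-like), with step-halving whenever a proposed update would decrease
# the objective and AI bending (+ eps * I) when the AI matrix is singular.
reml_driver <- function(engine, theta, control) {
  ev <- engine(theta)
  if (!ev$ok) abort("starting values give a non-positive-definite covariance")
  trace <- tibble(iteration = 0L, logL = ev$logL)
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    if (it <= control$em_steps) {
      delta <- 2 * theta^2 / ev$N * ev$score
    } else {
      AI <- ev$AI
      delta <- tryCatch(solve(AI, ev$score), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) {
        eps <- 1e-6 * sum(diag(AI))
        delta <- solve(AI + diag(eps, nrow(AI)), ev$score)
      }
    }
    # step halving: never accept a downhill step
    try_step <- function(delta) {
      ev_new <- engine(theta + delta)
      halvings <- 0L
      while ((!ev_new$ok || ev_new$logL < ev$logL - 1e-12) && halvings < 40L) {
        delta <- delta / 2
        ev_new <- engine(theta + delta)
        halvings <- halvings + 1L
      }
      list(ev = ev_new, delta = delta, halvings = halvings,
           ok = ev_new$ok && !(halvings == 40L && ev_new$logL < ev$logL))
    }
    st <- try_step(delta)
    if (!st$ok && it > control$em_steps) {
      # the AI direction dies at the PD-cone boundary; the EM-flavoured
      # direction is uphill and stays inside the cone
      st <- try_step(2 * theta^2 / ev$N * ev$score)
    }
    if (!st$ok && length(theta) > 2L) {
      # active-set fallback: when one component block sits on the boundary
      # it vetoes the joint step; block-restricted steps still traverse the
      # remaining ridge (e.g. a degenerate duplicated-trait fit)
      half <- length(theta) %/% 2L
      for (blk in list(seq_len(half), half + seq_len(length(theta) - half))) {
        d_blk <- numeric(length(theta))
        d_blk[blk] <- delta[blk]
        st <- try_step(d_blk)
        if (st$ok && st$ev$logL > ev$logL + control$tol) break
      }
    }
    if (!st$ok) {
      # no representable uphill step: the objective cannot be improved at
      # floating-point resolution (optimum, possibly on the PD boundary)
      converged <- TRUE
      break
    }
    delta <- st$delta
    ev_new <- st$ev
    halvings <- st$halvings
    theta <- theta + delta
    d_logL <- ev_new$logL - ev$logL
    ev <- ev_new
    trace <- rbind(trace, tibble(iteration = it, logL = ev$logL))
    if (control$verbose) {
      message(sprintf("iter %3d logL %.8f", it, ev$logL))
    }
    # a halved step can stall with a large gradient remaining, so require
    # either a full accepted AI step or a negligible Newton decrement
    # (the expected remaining likelihood gain, 0.5 * s' AI^-1 s)
    if (abs(d_logL) < control$tol && it > control$em_steps) {
      decrement <- tryCatch(
        0.5 * sum(ev$score * solve(ev$AI, ev$score)),
        error = function(e) {
          eps <- 1e-6 * sum(diag(ev$AI))
          0.5 * sum(ev$score * solve(ev$AI + diag(eps, nrow(ev$AI)),
                                     ev$score))
        })
      if (halvings == 0L || abs(decrement) < 1e-6) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    abort(paste0("REML did not converge in ", control$max_iter,
                 " iterations; logL trace: ",
                 paste(sprintf("%.4f", tail(trace$logL, 5)), collapse = " -> ")))
  }
  vcov <- tryCatch(solve(ev$AI), error = function(e) {
    eps <- 1e-6 * sum(diag(ev$AI))
    solve(ev$AI + diag(eps, nrow(ev$AI)))
  })
  list(theta = theta, logL = ev$logL, vcov = vcov, trace = trace,
       iterations = nrow(trace) - 1L, converged = converged)
}

# univariate engine in the GRM eigenbasis: V = vg * D + ve * I
engine_uni_eigen <- function(y, X, d) {
  n <- length(y); p <- ncol(X)
  function(theta) {
    b <- theta[1] * d + theta[2]
    if (any(b <= 0)) return(list(ok = FALSE, logL = -Inf))
    ib <- 1 / b
    M <- crossprod(X, X * ib)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(list(ok = FALSE, logL = -Inf))
    beta <- backsolve(cM, forwardsolve(t(cM), crossprod(X, y * ib)))
    r <- drop(y - X %*% beta)
    u <- r * ib
    logL <- -0.5 * (sum(log(b)) + 2 * sum(log(diag(cM))) + sum(r * u))
    Tm <- X * ib                         # V^-1 X
    Minv <- chol2inv(cM)
    w_list <- list(d, rep(1, n))
    score <- numeric(2); q <- matrix(0, n, 2)
    trs <- numeric(2)
    for (k in 1:2) {
      w <- w_list[[k]]
      Sk <- crossprod(Tm, w * Tm)
      trPVk <- sum(ib * w) - sum(Minv * Sk)
      uVu <- sum(w * u^2)
      score[k] <- -0.5 * (trPVk - uVu)
      q[, k] <- w * u
    }
    Pq <- q * ib - Tm %*% (Minv %*% crossprod(Tm, q))
    AI <- 0.5 * crossprod(q, Pq)
    AI <- (AI + t(AI)) / 2
    list(ok = TRUE, logL = logL, score = score, AI = AI, N = n)
  }
}

# bivariate engine in the GRM eigenbasis (both traits observed on the same
# individuals): V factorizes into per-eigenvalue 2x2 blocks
#   B_i = Sigma_G * d_i + Sigma_E.
# theta order: (vg1, vg2, cg12, ve1, ve2, ce12)
engine_biv_eigen <- function(Y, X, d) {
  n <- nrow(Y); p <- ncol(X)
  y1 <- Y[, 1]; y2 <- Y[, 2]
  one <- rep(1, n)
  # structure of each component: (a11, a12, a22) on the 2x2 block, and the
  # per-eigenvalue weight (d for genetic, 1 for residual)
  struct <- list(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0),
                 c(1, 0, 0), c(0, 0, 1), c(0, 1, 0))
  function(theta) {
    b11 <- theta[1] * d + theta[4]
    b22 <- theta[2] * d + theta[5]
    b12 <- theta[3] * d + theta[6]
    det <- b11 * b22 - b12^2
    if (any(det <= 0) || any(b11 <= 0)) return(list(ok = FALSE, logL = -Inf))
    i11 <- b22 / det; i22 <- b11 / det; i12 <- -b12 / det
    M11 <- crossprod(X, X * i11)
    M12 <- crossprod(X, X * i12)
    M22 <- crossprod(X, X * i22)
    M <- rbind(cbind(M11, M12), cbind(M12, M22))
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(list(ok = FALSE, logL = -Inf))
    rhs <- c(crossprod(X, i11 * y1 + i12 * y2),
             crossprod(X, i12 * y1 + i22 * y2))
    beta <- backsolve(cM, forwardsolve(t(cM), rhs))
    r1 <- drop(y1 - X %*% beta[seq_len(p)])
    r2 <- drop(y2 - X %*% beta[p + seq_len(p)])
    u1 <- i11 * r1 + i12 * r2
    u2 <- i12 * r1 + i22 * r2
    yPy <- sum(r1 * u1) + sum(r2 * u2)
    logL <- -0.5 * (sum(log(det)) + 2 * sum(log(diag(cM))) + yPy)

    Ttop <- cbind(i11 * X, i12 * X)      # (V^-1 X) rows, trait-1 block
    Tbot <- cbind(i12 * X, i22 * X)
    Minv <- chol2inv(cM)
    cross <- function(w) list(tt = crossprod(Ttop, w * Ttop),
                              tb = crossprod(Ttop, w * Tbot),
                              bb = crossprod(Tbot, w * Tbot))
    cw <- list(g = cross(d), e = cross(one))
    trV <- list(g = c(sum(d * i11), sum(d * i22), sum(d * i12)),
                e = c(sum(i11), sum(i22), sum(i12)))
    uu <- list(g = c(sum(d * u1^2), sum(d * u2^2), sum(d * u1 * u2)),
               e = c(sum(u1^2), sum(u2^2), sum(u1 * u2)))

    score <- numeric(6)
    Q1 <- matrix(0, n, 6); Q2 <- matrix(0, n, 6)
    for (k in 1:6) {
      a <- struct[[k]]
      grp <- if (k <= 3) "g" else "e"
      w <- if (k <= 3) d else one
      cwk <- cw[[grp]]
      Sk <- a[1] * cwk$tt + a[2] * (cwk$tb + t(cwk$tb)) + a[3] * cwk$bb
      trVinvVk <- a[1] * trV[[grp]][1] + a[3] * trV[[grp]][2] +
        2 * a[2] * trV[[grp]][3]
      uVu <- a[1] * uu[[grp]][1] + a[3] * uu[[grp]][2] + 2 * a[2] * uu[[grp]][3]
      score[k] <- -0.5 * ((trVinvVk - sum(Minv * Sk)) - uVu)
      Q1[, k] <- w * (a[1] * u1 + a[2] * u2)
      Q2[, k] <- w * (a[2] * u1 + a[3] * u2)
    }
    # P Q for the average-information matrix
    Vq1 <- i11 * Q1 + i12 * Q2
    Vq2 <- i12 * Q1 + i22 * Q2
    s <- crossprod(Ttop, Q1) + crossprod(Tbot, Q2)
    gam <- Minv %*% s
    Pq1 <- Vq1 - Ttop %*% gam
    Pq2 <- Vq2 - Tbot %*% gam
    AI <- 0.5 * (crossprod(Q1, Pq1) + crossprod(Q2, Pq2))
    AI <- (AI + t(AI)) / 2
    list(ok = TRUE, logL = logL, score = score, AI = AI, N = 2 * n)
  }
}

# dense engine for arbitrary stacking (full-information bivariate fits with
# non-identical trait samples, and toy oracle checks)
engine_dense <- function(y, X, Vk) {
  N <- length(y)
  function(theta) {
    V <- matrix(0, N, N)
    for (k in seq_along(Vk)) V <- V + theta[k] * Vk[[k]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ok = FALSE, logL = -Inf))
    Vinv <- chol2inv(cV)
    VinvX <- Vinv %*% X
    M <- crossprod(X, VinvX)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(list(ok = FALSE, logL = -Inf))
    Minv <- chol2inv(cM)
    P <- Vinv - VinvX %*% Minv %*% t(VinvX)
    Py <- drop(P %*% y)
    logL <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cM))) +
                      sum(y * Py))
    score <- numeric(length(Vk))
    Q <- matrix(0, N, length(Vk))
    for (k in seq_along(Vk)) {
      q <- drop(Vk[[k]] %*% Py)
      Q[, k] <- q
      score[k] <- -0.5 * (sum(P * Vk[[k]]) - sum(Py * q))
    }
    AI <- 0.5 * crossprod(Q, P %*% Q)
    AI <- (AI + t(AI)) / 2
    list(ok = TRUE, logL = logL, score = score, AI = AI, N = N)
  }
}

#' GREML variance components against a genomic relationship matrix
#'
#' Fits the mixed model `y = X b + g + e` with `Cov(g) = A * vg` (A the GRM)
#' by restricted maximum likelihood, maximizing
#' `-0.5 * (log|V| + log|X' V^-1 X| + y' P y)`. One EM-flavoured update is
#' followed by average-information (AI) updates with step-halving; sampling
#' (co)variances of the components come from the inverse AI matrix at the
#' optimum. With two traits the bivariate extension is fitted: genetic
#' covariance structure `[vg1, cg; cg, vg2] (x) A` and residual structure
#' `[ve1, ce; ce, ve2] (x) I`, where individuals observed for only one trait
#' still contribute through the stacked full-information likelihood.
#' Components are unconstrained during optimization; fits with a negative
#' component are flagged, not clamped.
#'
#' When both traits are observed on the same individuals the model is solved
#' in the eigenbasis of the GRM (per-eigenvalue 2x2 blocks), which makes
#' cohort-scale fits fast; otherwise a dense stacked representation is used.
#' Both paths maximize the identical objective.
#'
#' @param data Tibble with an `iid` column, trait column(s) and any covariate
#'   columns.
#' @param grm A `grm` object covering the phenotyped individuals.
#' @param traits One (univariate) or two (bivariate) trait column names.
#' @param covariates Covariate column names entering the fixed effects next
#'   to the intercept (e.g. ancestry principal components).
#' @param control A [greml_control()].
#' @return A `greml_fit`: components and standard errors, inverse-AI sampling
#'   covariance, `logL`, sample sizes, heritabilities, and for bivariate fits
#'   the genetic and residual correlations with delta-method standard errors.
#' @examples
#' g <- sim_genotypes(300, 600, seed = 1)
#' ph <- sim_phenotypes(g, 100, matrix(c(.36, .29, .29, .35), 2),
#'                      matrix(c(.63, .33, .33, .65), 2), seed = 2)
#' fit <- greml(ph, compute_grm(g), traits = c("trait1", "trait2"))
#' tidy(fit)
#' @export
greml <- function(data, grm, traits, covariates = NULL,
                  control = greml_control()) {
  stopifnot(inherits(grm, "grm"), is.data.frame(data))
  if (!"iid" %in% names(data)) abort("`data` must have an `iid` column")
  if (!length(traits) %in% 1:2) abort("`traits` must name 1 or 2 columns")
  missing_tr <- setdiff(c(traits, covariates), names(data))
  if (length(missing_tr)) {
    abort(paste0("column(s) not in `data`: ", paste(missing_tr, collapse = ", ")))
  }
  data <- data[!duplicated(data$iid), , drop = FALSE]
  data <- data[data$iid %in% grm$ids, , drop = FALSE]
  cov_ok <- if (length(covariates)) complete.cases(data[covariates]) else TRUE
  Xall <- cbind(`(intercept)` = rep(1, nrow(data)),
                if (length(covariates)) as.matrix(data[covariates]))
  if (qr(Xall)$rank < ncol(Xall)) abort("rank-deficient fixed-effect design")

  if (length(traits) == 1L) {
    use <- !is.na(data[[traits]]) & cov_ok
    n <- sum(use)
    if (n < 30) warn(sprintf("only %d observations; estimates will be unstable", n))
    if (n < ncol(Xall) + 2) abort("too few observations")
    ids <- data$iid[use]
    A <- grm$A[match(ids, grm$ids), match(ids, grm$ids)]
    y <- data[[traits]][use]
    X <- Xall[use, , drop = FALSE]
    ee <- eigen(A, symmetric = TRUE)
    dvals <- pmax(ee$values, 0)
    yt <- drop(crossprod(ee$vectors, y))
    Xt <- crossprod(ee$vectors, X)
    theta0 <- c(var(y) / 2, var(y) / 2)
    fit <- reml_driver(engine_uni_eigen(yt, Xt, dvals), theta0, control)
    out <- new_greml_fit(fit, traits, n_pair = n, n_per_trait = n,
                         uni = TRUE)
    return(out)
  }

  # bivariate
  use1 <- !is.na(data[[traits[1]]]) & cov_ok
  use2 <- !is.na(data[[traits[2]]]) & cov_ok
  n1 <- sum(use1); n2 <- sum(use2)
  n_pair <- sum(use1 & use2)
  if (min(n1, n2) < 30) {
    warn("fewer than 30 observations for a trait; estimates will be unstable")
  }
  both <- use1 & use2
  y1p <- data[[traits[1]]][both]; y2p <- data[[traits[2]]][both]
  sg <- stats::cov(cbind(y1p, y2p))
  v1 <- var(data[[traits[1]]][use1]); v2 <- var(data[[traits[2]]][use2])
  c12 <- sg[1, 2] / 2
  # sanitize a degenerate starting correlation
  if (abs(c12) >= sqrt(v1 * v2) / 2) c12 <- sign(c12) * 0.5 * sqrt(v1 * v2) / 2
  theta0 <- c(v1 / 2, v2 / 2, c12, v1 / 2, v2 / 2, c12)

  if (identical(which(use1), which(use2))) {
    ids <- data$iid[use1]
    A <- grm$A[match(ids, grm$ids), match(ids, grm$ids)]
    ee <- eigen(A, symmetric = TRUE)
    dvals <- pmax(ee$values, 0)
    Yt <- crossprod(ee$vectors, cbind(data[[traits[1]]][use1],
                                      data[[traits[2]]][use2]))
    Xt <- crossprod(ee$vectors, Xall[use1, , drop = FALSE])
    fit <- reml_driver(engine_biv_eigen(Yt, Xt, dvals), theta0, control)
  } else {
    ids1 <- data$iid[use1]; ids2 <- data$iid[use2]
    i1 <- match(ids1, grm$ids); i2 <- match(ids2, grm$ids)
    A11 <- grm$A[i1, i1, drop = FALSE]
    A22 <- grm$A[i2, i2, drop = FALSE]
    A12 <- grm$A[i1, i2, drop = FALSE]
    J12 <- outer(ids1, ids2, "==") * 1
    z11 <- matrix(0, n1, n1); z22 <- matrix(0, n2, n2); z12 <- matrix(0, n1, n2)
    Vk <- list(
      rbind(cbind(A11, z12), cbind(t(z12), z22)),
      rbind(cbind(z11, z12), cbind(t(z12), A22)),
      rbind(cbind(z11, A12), cbind(t(A12), z22)),
      rbind(cbind(diag(n1), z12), cbind(t(z12), z22)),
      rbind(cbind(z11, z12), cbind(t(z12), diag(n2))),
      rbind(cbind(z11, J12), cbind(t(J12), z22))
    )
    y <- c(data[[traits[1]]][use1], data[[traits[2]]][use2])
    X1 <- Xall[use1, , drop = FALSE]; X2 <- Xall[use2, , drop = FALSE]
    X <- rbind(cbind(X1, X1 * 0), cbind(X2 * 0, X2))
    fit <- reml_driver(engine_dense(y, X, Vk), theta0, control)
  }
  new_greml_fit(fit, traits, n_pair = n_pair, n_per_trait = c(n1, n2),
                uni = FALSE)
}

# assemble the user-facing fit object with derived quantities
new_greml_fit <- function(fit, traits, n_pair, n_per_trait, uni) {
  th <- fit$theta; V <- fit$vcov
  if (uni) {
    terms <- c("V(G)", "V(e)")
    vp <- sum(th); h2 <- th[1] / vp
    gh <- c(th[2], -th[1]) / vp^2
    h2_se <- sqrt(drop(t(gh) %*% V %*% gh))
    vp_se <- sqrt(sum(V))
    comp <- tibble(
      term = c(terms, "Vp", "V(G)/Vp"),
      estimate = c(th, vp, h2),
      std.error = c(sqrt(diag(V)), vp_se, h2_se)
    )
    rg <- re <- NULL
  } else {
    terms <- c("V(G)_tr1", "V(G)_tr2", "C(G)_tr12",
               "V(e)_tr1", "V(e)_tr2", "C(e)_tr12")
    vp1 <- th[1] + th[4]; vp2 <- th[2] + th[5]
    vp1_se <- sqrt(V[1, 1] + V[4, 4] + 2 * V[1, 4])
    vp2_se <- sqrt(V[2, 2] + V[5, 5] + 2 * V[2, 5])
    h2 <- c(th[1] / vp1, th[2] / vp2)
    g1 <- c(th[4], -th[1]) / vp1^2
    h1_se <- sqrt(drop(t(g1) %*% V[c(1, 4), c(1, 4)] %*% g1))
    g2 <- c(th[5], -th[2]) / vp2^2
    h2_se <- sqrt(drop(t(g2) %*% V[c(2, 5), c(2, 5)] %*% g2))
    rg <- rg_from_components(th[1], th[2], th[3], V[1:3, 1:3])
    re <- rg_from_components(th[4], th[5], th[6], V[4:6, 4:6])
    comp <- tibble(
      term = c(terms, "Vp_tr1", "Vp_tr2", "V(G)/Vp_tr1", "V(G)/Vp_tr2",
               "r_G", "r_E"),
      estimate = c(th, vp1, vp2, h2, rg$estimate, re$estimate),
      std.error = c(sqrt(diag(V)), vp1_se, vp2_se, h1_se, h2_se,
                    rg$std.error, re$std.error)
    )
  }
  structure(
    list(components = comp, theta = th, vcov = V, logL = fit$logL,
         n = n_pair, n_per_trait = n_per_trait, traits = traits,
         r_G = rg, r_E = re, iterations = fit$iterations,
         converged = fit$converged, trace = fit$trace,
         negative_components = any(th[if (uni) c(1, 2) else c(1, 2, 4, 5)] < 0),
         type = if (uni) "univariate" else "bivariate"),
    class = "greml_fit"
  )
}

#' @export
print.greml_fit <- function(x, ...) {
  cat(sprintf("<greml_fit> %s REML fit (%d iterations, logL %.3f, n = %d)\n",
              x$type, x$iterations, x$logL, x$n))
  print(as.data.frame(x$components), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Correlation of a pair of variance components
#'
#' `r = c12 / sqrt(v1 * v2)`, the construction used for genetic, shared- and
#' non-shared-environmental correlations alike. When a 3x3 sampling
#' covariance of `(v1, v2, c12)` is supplied, the standard error follows from
#' the delta method with gradient `(-r/(2 v1), -r/(2 v2), 1/sqrt(v1 v2))`,
#' which stays finite as `c12 -> 0`.
#'
#' @param v1,v2 Variance components (must be positive for the correlation to
#'   be defined).
#' @param c12 Covariance component.
#' @param vcov Optional 3x3 sampling covariance of `(v1, v2, c12)`.
#' @return Tibble with `estimate` and `std.error` (NA when `vcov` is absent);
#'   if either variance is non-positive the estimate is `NA` with attribute
#'   `undefined = TRUE` — no silent clamping.
#' @examples
#' rg_from_components(0.36, 0.35, 0.29)   # 0.817
#' @export
rg_from_components <- function(v1, v2, c12, vcov = NULL) {
  if (v1 <= 0 || v2 <= 0) {
    out <- tibble(estimate = NA_real_, std.error = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  r <- c12 / sqrt(v1 * v2)
  se <- NA_real_
  if (!is.null(vcov)) {
    g <- c(-r / (2 * v1), -r / (2 * v2), 1 / sqrt(v1 * v2))
    se <- sqrt(max(drop(t(g) %*% vcov %*% g), 0))
  }
  tibble(estimate = r, std.error = se)
}

#' Genetic correlation of a bivariate GREML fit
#' @param fit A bivariate `greml_fit`.
#' @return Tibble with `estimate` and `std.error`.
#' @export
genetic_correlation <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"))
  if (fit$type != "bivariate") abort("requires a bivariate fit")
  fit$r_G
}

#' Residual (environmental) correlation of a bivariate GREML fit
#' @param fit A bivariate `greml_fit`.
#' @return Tibble with `estimate` and `std.error`.
#' @export
env_correlation <- function(fit) {
  stopifnot(inherits(fit, "greml_fit"))
  if (fit$type != "bivariate") abort("requires a bivariate fit")
  fit$r_E
}
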