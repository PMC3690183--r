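test_that("published component rows reproduce the printed correlations", {
  # genetic correlations from 2-dp rounded components
  r1 <- rg_from_components(0.36, 0.35, 0.29)
  expect_equal(r1$estimate, 0.817, tolerance = 1e-3)
  r2 <- rg_from_components(0.36, 0.32, 0.25)
  expect_equal(r2$estimate, 0.737, tolerance = 1e-3)
  # residual correlations via the same construction
  e1 <- rg_from_components(0.63, 0.65, 0.33)
  expect_equal(e1$estimate, 0.516, tolerance = 1e-3)
  e2 <- rg_from_components(0.64, 0.67, 0.38)
  expect_equal(e2$estimate, 0.580, tolerance = 1e-3)
  # zero covariance: r = 0 with SE = sqrt(Var C)/sqrt(v1 v2)
  vc <- diag(c(0.01, 0.01, 0.04))
  r0 <- rg_from_components(0.5, 0.5, 0, vc)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$std.error, sqrt(0.04) / 0.5)
  # nonpositive variance: undefined, flagged, not clamped
  bad <- rg_from_components(-0.1, 0.5, 0.2)
  expect_true(is.na(bad$estimate))
  expect_true(isTRUE(attr(bad, "undefined")))
})

test_that("delta-method r_E variance matches the component-ratio algebra", {
  # the variance of a correlation of components, written out term by term
  v <- c(ve1 = 0.63, ve2 = 0.65, ce = 0.33)
  set.seed(1)
  S <- crossprod(matrix(rnorm(9, sd = 0.1), 3))  # arbitrary PSD sampling cov
  re <- v["ce"] / sqrt(v["ve1"] * v["ve2"])
  var_re <- re^2 * (S[1, 1] / (4 * v["ve1"]^2) + S[2, 2] / (4 * v["ve2"]^2) +
                      S[3, 3] / v["ce"]^2 + S[1, 2] / (2 * v["ve1"] * v["ve2"]) -
                      S[1, 3] / (v["ve1"] * v["ce"]) -
                      S[2, 3] / (v["ve2"] * v["ce"]))
  out <- rg_from_components(v["ve1"], v["ve2"], v["ce"], S)
  expect_equal(out$std.error, sqrt(as.numeric(var_re)), tolerance = 1e-12)
})

test_that("univariate REML recovers null and planted heritability", {
  g <- sim_genotypes(600, 1200, seed = 2)
  a <- compute_grm(g)
  # pure noise: h2 within 2 SE of zero
  set.seed(99)
  d0 <- tibble::tibble(iid = rownames(g$dosage), trait1 = rnorm(600))
  f0 <- greml(d0, a, traits = "trait1")
  h0 <- f0$components[f0$components$term == "V(G)/Vp", ]
  expect_lt(abs(h0$estimate), 2 * h0$std.error)
  # planted h2 = 0.36
  ph <- sim_phenotypes(g, 200, sigma_g_ref, sigma_e_ref, seed = 3)
  f1 <- greml(ph, a, traits = "trait1")
  h1 <- f1$components[f1$components$term == "V(G)/Vp", ]
  expect_lt(abs(h1$estimate - 0.36), 2 * h1$std.error)
  expect_true(f1$converged)
})

test_that("the REML objective never decreases along the iteration trace", {
  g <- sim_genotypes(300, 500, seed = 4)
  ph <- sim_phenotypes(g, 100, sigma_g_ref, sigma_e_ref, seed = 5)
  f <- greml(ph, compute_grm(g), traits = c("trait1", "trait2"))
  expect_true(all(diff(f$trace$logL) > -1e-9))
})

test_that("AI-REML matches derivative-free maximization on toy data", {
  d <- make_toy_cohort(101, n = 20)
  a <- d$grm; ph <- d$ph
  # univariate, 4 decimals
  f <- greml(ph, a, traits = "trait1") |> suppressWarnings()
  nm <- oracle_minimize(function(th) oracle_uni_m2reml(th, a$A, ph$trait1),
                        c(var(ph$trait1) / 2, var(ph$trait1) / 2))
  expect_equal(unname(f$theta), nm$par, tolerance = 1e-4)
  # bivariate, 3 decimals
  fb <- greml(ph, a, traits = c("trait1", "trait2")) |> suppressWarnings()
  nmb <- oracle_minimize(
    function(th) oracle_biv_m2reml(th, a$A, ph$trait1, ph$trait2),
    oracle_start_biv(ph$trait1, ph$trait2))
  expect_lt(max(abs(fb$theta - nmb$par)), 1e-3)
  expect_equal(-2 * fb$logL, nmb$value, tolerance = 1e-6)
})

test_that("bivariate REML recovers the generating components", {
  g <- sim_genotypes(1000, 2000, seed = 9)
  ph <- sim_phenotypes(g, 300, sigma_g_ref, sigma_e_ref, seed = 10)
  f <- greml(ph, compute_grm(g), traits = c("trait1", "trait2"))
  truth <- c(sigma_g_ref[1, 1], sigma_g_ref[2, 2], sigma_g_ref[1, 2],
             sigma_e_ref[1, 1], sigma_e_ref[2, 2], sigma_e_ref[1, 2])
  se <- sqrt(diag(f$vcov))
  expect_true(all(abs(f$theta - truth) < 2 * se))
  rg <- genetic_correlation(f)
  expect_lt(abs(rg$estimate - 0.29 / sqrt(0.36 * 0.35)), 2 * rg$std.error)
})

test_that("a duplicated trait drives the genetic correlation to one", {
  g <- sim_genotypes(400, 800, seed = 11)
  ph <- sim_phenotypes(g, 150, sigma_g_ref, sigma_e_ref, seed = 12)
  ph$trait2 <- ph$trait1
  f <- greml(ph, compute_grm(g), traits = c("trait1", "trait2"))
  expect_equal(genetic_correlation(f)$estimate, 1, tolerance = 1e-3)
})

test_that("estimates are invariant to covariate reparameterization and trait scale", {
  g <- sim_genotypes(300, 600, seed = 13)
  ph <- sim_phenotypes(g, 100, sigma_g_ref, sigma_e_ref, seed = 14)
  ph <- attach_covariates(ph, sex_effect = c(0.3, 0.1), seed = 15)
  a <- compute_grm(g)
  f1 <- greml(ph, a, traits = c("trait1", "trait2"), covariates = "sex")
  ph2 <- ph
  ph2$sex <- 10 * ph2$sex - 3    # affine reparameterization
  f2 <- greml(ph2, a, traits = c("trait1", "trait2"), covariates = "sex")
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  # positive rescaling of one trait leaves r_G unchanged
  ph3 <- ph
  ph3$trait2 <- 3.7 * ph3$trait2
  f3 <- greml(ph3, a, traits = c("trait1", "trait2"), covariates = "sex")
  expect_equal(genetic_correlation(f3)$estimate,
               genetic_correlation(f1)$estimate, tolerance = 1e-5)
})

test_that("full-information stacking handles non-identical trait samples", {
  g <- sim_genotypes(220, 500, seed = 16)
  ph <- sim_phenotypes(g, 100, sigma_g_ref, sigma_e_ref, seed = 17)
  ph$trait1[1:30] <- NA
  ph$trait2[190:220] <- NA
  f <- greml(ph, compute_grm(g), traits = c("trait1", "trait2"))
  expect_equal(f$n, sum(!is.na(ph$trait1) & !is.na(ph$trait2)))
  expect_equal(f$n_per_trait, c(190, 189))
  expect_true(f$converged)
  expect_true(is.finite(genetic_correlation(f)$std.error))
  # the dense path agrees with the eigen path on complete data
  ph_c <- sim_phenotypes(g, 100, sigma_g_ref, sigma_e_ref, seed = 18)
  f_eigen <- greml(ph_c, compute_grm(g), traits = c("trait1", "trait2"))
  nmb <- oracle_minimize(
    function(th) oracle_biv_m2reml(th, compute_grm(g)$A, ph_c$trait1,
                                   ph_c$trait2),
    oracle_start_biv(ph_c$trait1, ph_c$trait2))
  expect_lt(max(abs(f_eigen$theta - nmb$par)), 2e-3)
})

test_that("input validation and tidiers behave", {
  g <- sim_genotypes(80, 150, seed = 19)
  ph <- sim_phenotypes(g, 40, sigma_g_ref, sigma_e_ref, seed = 20)
  a <- compute_grm(g)
  expect_error(greml(ph, a, traits = "missing_col"), "not in `data`")
  ph$bad <- ph$trait1 * 0 + 1    # collinear with intercept
  expect_error(suppressWarnings(
    greml(ph, a, traits = "trait1", covariates = "bad")), "rank-deficient")
  f <- suppressWarnings(greml(ph, a, traits = c("trait1", "trait2")))
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
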