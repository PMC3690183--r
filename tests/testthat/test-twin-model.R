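test_that("published twin component rows reproduce the printed correlations", {
  expect_equal(rg_from_components(0.46, 0.59, 0.34)$estimate, 0.653,
               tolerance = 1e-3)
  expect_equal(rg_from_components(0.81, 0.85, 0.54)$estimate, 0.651,
               tolerance = 1e-3)
})

test_that("an E-only world is recovered as pure non-shared environment", {
  z <- matrix(0, 2, 2)
  tw <- sim_twins(1500, 1500, a = z, c = z, e = diag(2) * 0.8, seed = 1)
  f <- fit_twin_cholesky(tw)
  expect_gt(f$derived["VE_tr1"], 0.94)
  expect_gt(f$derived["VE_tr2"], 0.94)
  s <- twin_standardized(f)
  expect_lt(max(abs(s$C_tr12[s$component == "C"])), 0.05)
})

test_that("exact population moments are reproduced to high precision", {
  gm <- ref_twin$g_maths
  S <- gm$A + gm$C + gm$E
  mzc <- gm$A + gm$C; dzc <- 0.5 * gm$A + gm$C
  f <- fit_twin_moments(rbind(cbind(S, mzc), cbind(mzc, S)),
                        rbind(cbind(S, dzc), cbind(dzc, S)), 1000, 1000)
  expect_lt(max(abs(f$Sigma$A - gm$A)), 1e-6)
  expect_lt(max(abs(f$Sigma$C - gm$C)), 1e-6)
  expect_lt(max(abs(f$Sigma$E - gm$E)), 1e-6)
  # fitted expected covariances reproduce the input moments
  ex_mz <- rbind(cbind(S, mzc), cbind(mzc, S))
  fit_mz <- rbind(cbind(Reduce(`+`, f$Sigma), f$Sigma$A + f$Sigma$C),
                  cbind(f$Sigma$A + f$Sigma$C, Reduce(`+`, f$Sigma)))
  expect_lt(max(abs(fit_mz - ex_mz)), 1e-6)
})

test_that("simulated height-weight twins return the reference correlation", {
  hw <- ref_twin$height_weight
  p <- ace_paths(hw$A, hw$C, hw$E)
  tw <- sim_twins(2000, 2000, p$a, p$c, p$e, seed = 2)
  f <- fit_twin_cholesky(tw)
  rg <- component_correlations(f)
  expect_lt(abs(rg$estimate[rg$component == "r_G"] - 0.65),
            2 * rg$std.error[rg$component == "r_G"])
})

test_that("the ACE likelihood dominates its restrictions", {
  gm <- ref_twin$g_maths
  p <- ace_paths(gm$A, gm$C, gm$E)
  tw <- sim_twins(500, 500, p$a, p$c, p$e, seed = 3)
  f_ace <- fit_twin_cholesky(tw)
  for (m in c("AE", "CE", "E")) {
    f_r <- fit_twin_cholesky(tw, model = m)
    expect_lte(f_ace$minus2lnL, f_r$minus2lnL + 1e-6)
  }
})

test_that("the likelihood is invariant to path-column sign flips", {
  gm <- ref_twin$g_maths
  p <- ace_paths(gm$A, gm$C, gm$E)
  tw <- sim_twins(100, 100, p$a, p$c, p$e, seed = 4)
  groups <- pleiokit:::twin_groups(tw)
  mask <- pleiokit:::par_mask("ACE")
  par <- c(p$a[c(1, 2, 4)], p$c[c(1, 2, 4)], p$e[c(1, 2, 4)], 0, 0)
  flip <- par
  flip[1:2] <- -flip[1:2]          # flip first column of a
  flip[6] <- -flip[6]              # flip second column of c
  expect_equal(pleiokit:::twin_m2ll(par, groups, mask),
               pleiokit:::twin_m2ll(flip, groups, mask), tolerance = 1e-10)
  # and the reported solution is in canonical nonnegative-diagonal form
  f <- fit_twin_cholesky(tw)
  expect_gte(f$paths$a[1, 1], 0)
  expect_gte(f$paths$a[2, 2], 0)
  expect_gte(f$paths$e[1, 1], 0)
})

test_that("missing cells contribute through their observed sub-vectors", {
  gm <- ref_twin$g_maths
  p <- ace_paths(gm$A, gm$C, gm$E)
  tw <- sim_twins(600, 600, p$a, p$c, p$e, seed = 5)
  set.seed(6)
  for (col in c("t1_twin1", "t2_twin2")) {
    tw[[col]][sample(nrow(tw), 60)] <- NA
  }
  f <- fit_twin_cholesky(tw)
  expect_true(f$se_available)
  expect_lt(abs(f$derived["r_G"] - 0.36 / sqrt(0.46 * 0.48)),
            3 * f$derived_se["r_G"])
  expect_lt(f$n_complete, 1200)
})

test_that("genetic-correlation recovery is unbiased across replicates", {
  gm <- ref_twin$g_maths
  p <- ace_paths(gm$A, gm$C, gm$E)
  true_rg <- gm$A[1, 2] / sqrt(gm$A[1, 1] * gm$A[2, 2])
  ctrl <- twin_control(n_restarts = 1)
  rgs <- vapply(1:100, function(i) {
    tw <- sim_twins(2000, 2000, p$a, p$c, p$e, seed = 1000 + i)
    f <- fit_twin_cholesky(tw, control = ctrl)
    unname(f$derived["r_G"])
  }, numeric(1))
  expect_lt(abs(mean(rgs) - true_rg), 0.03)
})

test_that("twin tidiers and plots expose the fit", {
  gm <- ref_twin$g_maths
  p <- ace_paths(gm$A, gm$C, gm$E)
  tw <- sim_twins(120, 120, p$a, p$c, p$e, seed = 7)
  f <- fit_twin_cholesky(tw)
  td <- tidy(f)
  expect_true(all(c("VG_tr1", "r_G", "r_P") %in% td$term))
  gl <- glance(f)
  expect_equal(gl$n_mz, 120)
  expect_s3_class(autoplot(f), "ggplot")
  # standardized shares per trait sum to one
  s <- twin_standardized(f)
  expect_equal(sum(s$V_tr1), 1, tolerance = 1e-6)
  expect_equal(sum(s$V_tr2), 1, tolerance = 1e-6)
  # covariance split sums to the fitted phenotypic correlation
  expect_equal(sum(s$C_tr12), unname(f$derived["r_P"]), tolerance = 1e-6)
})
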