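test_that("E-only twins show no cross-twin covariance", {
  z <- matrix(0, 2, 2)
  tw <- sim_twins(1500, 1500, a = z, c = z, e = diag(2) * 0.8, seed = 1)
  for (zyg in c("MZ", "DZ")) {
    d <- tw[tw$zygosity == zyg, ]
    cc <- cov(cbind(d$t1_twin1, d$t1_twin2))[1, 2]
    expect_lt(abs(cc), 3 * 0.64 / sqrt(nrow(d)))
  }
})

test_that("MZ twins sharing all variance are identical", {
  z <- matrix(0, 2, 2)
  tw <- sim_twins(50, 0, a = diag(2) * 0.9, c = z, e = z, seed = 2)
  expect_lt(max(abs(tw$t1_twin1 - tw$t1_twin2)), 1e-6)
  expect_lt(max(abs(tw$t2_twin1 - tw$t2_twin2)), 1e-6)
})

test_that("cross-twin covariances match the biometric expectation", {
  # reference height-weight components: MZ cross-twin trait-1 covariance
  # 0.81 + 0.09 = 0.90, DZ 0.5 * 0.81 + 0.09 = 0.495
  hw <- ref_twin$height_weight
  p <- ace_paths(hw$A, hw$C, hw$E)
  n <- 4000
  tw <- sim_twins(n, n, p$a, p$c, p$e, seed = 3)
  mz <- tw[tw$zygosity == "MZ", ]; dz <- tw[tw$zygosity == "DZ", ]
  se <- sqrt((1 * 1 + 0.9^2) / n)   # var of a sample covariance, approx
  expect_lt(abs(cov(mz$t1_twin1, mz$t1_twin2) - 0.90), 3 * se)
  expect_lt(abs(cov(dz$t1_twin1, dz$t1_twin2) - 0.495), 3 * se)
})

test_that("MZ cross-twin covariance dominates DZ when aa' is nonnegative", {
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(c(runif(1, 0.3, 0.9), runif(1, 0, 0.4), 0,
                  runif(1, 0.3, 0.9)), 2, 2)
    cm <- matrix(c(runif(1, 0, 0.5), runif(1, 0, 0.2), 0,
                   runif(1, 0, 0.5)), 2, 2)
    em <- diag(2) * runif(1, 0.4, 0.8)
    tw <- sim_twins(2500, 2500, a, cm, em, seed = 100 + i)
    mz <- tw[tw$zygosity == "MZ", ]; dz <- tw[tw$zygosity == "DZ", ]
    for (v in c("t1", "t2")) {
      cmz <- cov(mz[[paste0(v, "_twin1")]], mz[[paste0(v, "_twin2")]])
      cdz <- cov(dz[[paste0(v, "_twin1")]], dz[[paste0(v, "_twin2")]])
      expect_gt(cmz - cdz, -0.1)
    }
  }
})

test_that("twin simulation is deterministic and validates inputs", {
  p <- ace_paths(diag(2) * 0.5, diag(2) * 0.2, diag(2) * 0.3)
  t1 <- sim_twins(20, 20, p$a, p$c, p$e, seed = 5)
  t2 <- sim_twins(20, 20, p$a, p$c, p$e, seed = 5)
  expect_identical(t1, t2)
  expect_error(sim_twins(-1, 5, p$a, p$c, p$e), "n_mz")
  expect_error(sim_twins(5, 5, matrix(1, 2, 2), p$c, p$e), "lower-triangular")
})
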