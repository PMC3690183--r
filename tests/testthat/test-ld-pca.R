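test_that("LD pruning keeps independent SNPs and drops duplicates", {
  g <- sim_genotypes(400, 120, seed = 1)
  kept <- ld_prune(g)
  expect_gt(length(kept), 110)   # independent SNPs survive
  # plant an exact duplicate: r^2 = 1, later copy removed
  g2 <- g
  g2$dosage[, 20] <- g2$dosage[, 10]
  kept2 <- ld_prune(g2)
  expect_true("snp_00010" %in% kept2)
  expect_false("snp_00020" %in% kept2)
})

test_that("a planted correlated pair loses its later member", {
  g <- sim_genotypes(600, 60, seed = 2)
  set.seed(22)
  x <- g$dosage[, 5]
  y <- ifelse(runif(600) < 0.75, x, sample(x))   # r^2 around 0.5
  g$dosage[, 6] <- as.integer(y)
  r2 <- cor(g$dosage[, 5], g$dosage[, 6])^2
  expect_gt(r2, 0.2)
  kept <- ld_prune(g, r2_max = 0.2)
  expect_true("snp_00005" %in% kept)
  expect_false("snp_00006" %in% kept)
})

test_that("leading axis separates differentiated subpopulations", {
  g <- sim_genotypes(300, 1500, fst = 0.05,
                     subpop_fractions = c(0.5, 0.5), seed = 3)
  pc <- pca_axes(g, k = 5)
  r <- cor(pc$loadings[, 1], g$subpop)
  expect_gt(abs(r), 0.9)
  expect_true(1 %in% pc$selected)
  # loadings orthonormal
  expect_lt(max(abs(crossprod(pc$loadings) - diag(5))), 1e-8)
  # eigenvalues descending
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
})

test_that("no axis separates labels in a panmictic sample", {
  g <- sim_genotypes(300, 1500, fst = 0, subpop_fractions = c(0.5, 0.5),
                     seed = 4)
  pc <- pca_axes(g, k = 5)
  expect_lt(max(abs(cor(pc$loadings, g$subpop))), 0.25)
})

test_that("TW1 tail probabilities match published significance points", {
  expect_equal(tw_pvalue(0.9793), 0.05, tolerance = 0.002)
  expect_equal(tw_pvalue(2.0234), 0.01, tolerance = 0.005)
  expect_equal(tw_pvalue(3.2724), 0.001, tolerance = 0.02)
  expect_true(all(diff(tw_pvalue(seq(-3, 5, by = 0.1))) < 0))
})

test_that("Tracy-Widom axis test is calibrated on null spectra", {
  set.seed(5)
  n <- 80; m <- 400
  hits <- vapply(1:120, function(i) {
    x <- matrix(rnorm(n * m), n, m)
    ev <- eigen(tcrossprod(scale(x)) / m, symmetric = TRUE,
                only.values = TRUE)$values
    tw <- tracy_widom_select(ev, alpha = 0.05)
    tw$table$p.value[1] < 0.05
  }, logical(1))
  # ~5% type-I error; allow a generous binomial band
  expect_gt(mean(hits), 0.005)
  expect_lt(mean(hits), 0.13)
})

test_that("strong structure is detected and alpha = 0 selects nothing", {
  g <- sim_genotypes(200, 800, fst = 0.1, subpop_fractions = c(0.5, 0.5),
                     seed = 6)
  std <- pca_axes(g, k = 4)
  expect_true(1 %in% std$selected)
  tw0 <- tracy_widom_select(std$eigenvalues, alpha = 0)
  expect_length(tw0$selected, 0)
  expect_error(tracy_widom_select(c(1, 0.5)), "at least 3")
})
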