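test_that("GRM formula matches hand evaluation on a 2x1 example", {
  g <- sim_genotypes(2, 1, seed = 1)
  g$dosage[] <- c(2L, 0L)
  a <- compute_grm(g)
  # p = 0.5: A_12 = (2-1)(0-1)/(2*0.5*0.5) = -2; diagonal = +2
  expect_equal(a$A[1, 2], -2)
  expect_equal(a$A[1, 1], 2)
  expect_equal(a$A[2, 2], 2)
})

test_that("duplicated individuals have identical relatedness entries", {
  g <- sim_genotypes(3, 100, seed = 2)
  g$dosage[2, ] <- g$dosage[1, ]
  a <- compute_grm(g)
  expect_equal(a$A[1, 2], a$A[1, 1])
  expect_equal(a$A[1, 2], a$A[2, 2])
})

test_that("complete-data GRM equals the standardized cross-product", {
  g <- sim_genotypes(60, 150, seed = 3)
  a <- compute_grm(g)
  x <- g$dosage
  p <- colMeans(x) / 2
  keep <- p > 0 & p < 1
  w <- scale(x[, keep], center = 2 * p[keep],
             scale = sqrt(2 * p[keep] * (1 - p[keep])))
  expect_lt(max(abs(a$A - tcrossprod(w) / sum(keep))), 1e-10)
  expect_true(isSymmetric(a$A))
  expect_gt(mean(diag(a$A)), 0.9)
  expect_lt(mean(diag(a$A)), 1.1)
})

test_that("off-diagonal relatedness of unrelateds is centred as theory predicts", {
  n <- 300; m <- 2000
  g <- sim_genotypes(n, m, seed = 4)
  a <- compute_grm(g)
  off <- a$A[upper.tri(a$A)]
  # sample-frequency centering makes every SNP's standardized dosages sum to
  # zero, so sum(A) = 0 exactly and the off-diagonal mean is -tr(A)/(n(n-1)),
  # about -1/n; around that centre, pair noise has SD 1/sqrt(m)
  expect_lt(abs(sum(a$A)), 1e-8)
  centre <- -sum(diag(a$A)) / (n * (n - 1))
  expect_equal(mean(off), centre, tolerance = 1e-10)
  expect_lt(abs(mean(off)), 2 / n)
  expect_lt(abs(sd(off) - 1 / sqrt(m)), 0.3 / sqrt(m))
})

test_that("pairwise-complete counts track missingness", {
  g <- sim_genotypes(40, 200, seed = 5)
  g2 <- add_missing_genotypes(g, 0.1, seed = 6)
  a <- compute_grm(g2)
  obs <- !is.na(g2$dosage)
  p <- colMeans(g2$dosage, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  expect_equal(a$n_snp[3, 7], sum(obs[3, keep] & obs[7, keep]))
  expect_true(all(a$n_snp <= sum(keep)))
  # a pair with zero joint SNPs is an error
  g3 <- sim_genotypes(3, 4, seed = 7)
  g3$dosage[1, 1:2] <- NA; g3$dosage[2, 3:4] <- NA
  expect_error(compute_grm(g3), "jointly observed")
})

test_that("GRM round-trips bit-exactly through the GCTA text format", {
  g <- sim_genotypes(25, 120, seed = 8)
  g <- add_missing_genotypes(g, 0.05, seed = 9)
  a <- compute_grm(g)
  prefix <- file.path(withr::local_tempdir(), "test")
  write_grm(a, prefix)
  b <- read_grm(prefix)
  expect_identical(b$A, a$A)
  expect_identical(b$ids, a$ids)
  expect_equal(b$n_snp, a$n_snp)
})

test_that("relatedness pruning enforces the cutoff with minimal removals", {
  # all pairs below the cutoff: nobody removed
  A0 <- diag(10) + 0.01
  expect_length(prune_related(make_grm(A0)), 10)
  # one related pair: exactly one of the two removed
  A1 <- diag(10) * 0.99 + 0.01
  A1[1, 2] <- A1[2, 1] <- 0.5
  kept <- prune_related(make_grm(A1))
  expect_length(kept, 9)
  expect_false(all(c("ind_0001", "ind_0002") %in% kept))
  # star: hub related to 5 others; only the hub goes
  A2 <- diag(8) * 0.99 + 0.001
  A2[1, 2:6] <- A2[2:6, 1] <- 0.3
  kept2 <- prune_related(make_grm(A2))
  expect_setequal(kept2, sprintf("ind_%04d", 2:8))
  expect_error(prune_related(make_grm(A0), threshold = 0), "positive")
})

test_that("no retained pair exceeds the threshold on random structures", {
  set.seed(10)
  for (i in 1:10) {
    n <- 30
    A <- diag(n)
    pairs <- matrix(sample(n, 16, replace = TRUE), ncol = 2)
    for (r in seq_len(nrow(pairs))) {
      if (pairs[r, 1] != pairs[r, 2]) {
        A[pairs[r, 1], pairs[r, 2]] <- A[pairs[r, 2], pairs[r, 1]] <-
          runif(1, 0.05, 0.6)
      }
    }
    kept <- prune_related(make_grm(A), threshold = 0.025)
    ix <- match(kept, sprintf("ind_%04d", seq_len(n)))
    sub <- A[ix, ix]
    diag(sub) <- 0
    expect_lte(max(sub), 0.025)
  }
})
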