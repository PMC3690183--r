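test_that("outlier screen keeps moderate extremes and flags true tails", {
  # in a 5-point sample the z-score of 100 among zeros is 1.79 < 3
  expect_true(all(exclude_outliers(c(0, 0, 0, 0, 100))))
  expect_warning(m <- exclude_outliers(rep(2, 10)), "zero variance")
  expect_true(all(m))
  # missing values stay missing in the mask
  m2 <- exclude_outliers(c(0, 0, 0, 0, 100, NA))
  expect_true(is.na(m2[6]))
  set.seed(1)
  x <- rnorm(1e5)
  frac <- mean(!exclude_outliers(x))
  expect_lt(abs(frac - 0.0027), 3 * sqrt(0.0027 / 1e5) + 2e-4)
})

test_that("residualize removes planted covariate signal", {
  set.seed(2)
  n <- 500
  cov_tab <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 11, 12))
  y <- 1.5 + 0.8 * cov_tab$sex - 0.3 * cov_tab$age + rnorm(n)
  r <- residualize(y, cov_tab)
  expect_equal(sd(r), 1, tolerance = 1e-10)
  expect_lt(abs(cor(r, cov_tab$sex)), 1e-8)
  expect_lt(abs(cor(r, cov_tab$age)), 1e-8)
  expect_lt(abs(coef(lm(r ~ sex + age, cov_tab))["sex"]), 1e-8)
  # no covariate effect: residuals are a z-scored version of the input
  y0 <- rnorm(n)
  r0 <- residualize(y0, cov_tab)
  expect_gt(cor(r0, y0), 0.99)
})

test_that("residualize errors on degenerate designs, naming the column", {
  cov_tab <- data.frame(sex = c(0, 1, 0, 1), dup = c(0, 1, 0, 1))
  expect_error(residualize(rnorm(4), cov_tab), "dup")
  expect_error(residualize(rnorm(3), data.frame(a = 1:3, b = c(1, 2, 4))),
               "complete observations")
})

test_that("van der Waerden scores follow the rank formula", {
  expect_equal(quantile_normalize(c(5, 1, 3)),
               c(0.6745, -0.6745, 0), tolerance = 1e-4)
  # rank invariance under monotone transforms
  set.seed(3)
  x <- rnorm(50)
  expect_equal(quantile_normalize(x), quantile_normalize(exp(2 * x)))
  # average-rank ties: both central values of four map to qnorm(0.5) = 0
  q <- quantile_normalize(c(1, 2, 2, 5))
  expect_equal(q[2:3], c(0, 0))
  # idempotence and missing propagation
  y <- c(x, NA)
  expect_equal(quantile_normalize(quantile_normalize(y)), quantile_normalize(y))
  expect_true(is.na(quantile_normalize(y)[51]))
  expect_error(quantile_normalize(c(NA, NA)), "non-missing")
})

test_that("composites respect the completeness rule", {
  s <- rbind(c(1, 2, 3, NA),   # 3 of 4 present
             c(1, 2, NA, NA),  # 2 of 4 present
             c(1, 2, 3, 4))
  comp <- make_composite(s, min_complete = 3)
  expect_equal(comp, c(2, NA, 2.5))
  expect_equal(make_composite(s[, 1:3], 2)[2], 1.5)
  expect_error(make_composite(s, 5), "exceeds")
})

test_that("one-per-family selection is uniform and deterministic", {
  d <- tibble::tibble(fid = rep(c("f1", "f2", "f3"), each = 2),
                      iid = paste0("i", 1:6))
  s1 <- select_one_per_family(d, seed = 7)
  expect_identical(s1, select_one_per_family(d, seed = 7))
  expect_equal(nrow(s1), 3)
  expect_equal(anyDuplicated(s1$fid), 0)
  # singleton families pass through
  d2 <- tibble::tibble(fid = c("a", "b"), iid = c("x", "y"))
  expect_identical(select_one_per_family(d2, seed = 1)$iid, c("x", "y"))
  picks <- vapply(1:400, function(s) {
    select_one_per_family(d, seed = s)$iid[1]
  }, character(1))
  frac <- mean(picks == "i1")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 400))
})

test_that("the full preprocessing pipeline yields near-normal scores", {
  set.seed(8)
  n <- 2000
  d <- tibble::tibble(
    iid = as.character(seq_len(n)),
    sex = rbinom(n, 1, 0.5), age = runif(n, 11, 12),
    trait1 = exp(rnorm(n)) + 0.4 * rbinom(n, 1, 0.5),
    trait2 = rnorm(n)^3
  )
  out <- preprocess_phenotypes(d, c("trait1", "trait2"))
  for (tr in c("trait1", "trait2")) {
    v <- out[[tr]][!is.na(out[[tr]])]
    expect_lt(abs(mean(v)), 1e-2)
    expect_lt(abs(sd(v) - 1), 0.05)
    skew <- mean((v - mean(v))^3) / sd(v)^3
    kurt <- mean((v - mean(v))^4) / sd(v)^4 - 3
    expect_lt(abs(skew), 0.05)
    expect_lt(abs(kurt), 0.1)
  }
  # anthropometric path: covariate adjustment without quantile normalization
  out2 <- preprocess_phenotypes(d, "trait1", quantile_norm = FALSE)
  v <- out2$trait1[!is.na(out2$trait1)]
  skew2 <- mean((v - mean(v))^3) / sd(v)^3
  expect_gt(abs(skew2), 0.5)   # the log-normal shape survives
})
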