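# internal validation and RNG helpers

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max))
  }
  as.numeric(x)
}

# symmetric positive semi-definite check with a small tolerance
check_psd <- function(m, name, d = 2L) {
  if (!is.matrix(m) || !all(dim(m) == d) || any(is.na(m))) {
    abort(sprintf("`%s` must be a %dx%d numeric matrix.", name, d, d))
  }
  if (max(abs(m - t(m))) > 1e-8) {
    abort(sprintf("`%s` must be symmetric.", name))
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort(sprintf("`%s` must be positive semi-definite.", name))
  }
  m
}

check_lower_tri <- function(m, name) {
  if (!is.matrix(m) || !all(dim(m) == 2L) || any(is.na(m))) {
    abort(sprintf("`%s` must be a 2x2 numeric matrix.", name))
  }
  if (abs(m[1, 2]) > 1e-12) {
    abort(sprintf("`%s` must be lower-triangular.", name))
  }
  m
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. With seed = NULL the current stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# lower Cholesky factor with graceful handling of semi-definite input
lower_chol <- function(m) {
  ev <- eigen(m, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(d), nrow = length(d)) %*% t(ev$vectors)
  # return the triangular factor of the PSD-projected matrix
  cc <- suppressWarnings(chol(L %*% t(L) + diag(1e-12, nrow(m))))
  t(cc)
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")
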