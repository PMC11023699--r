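# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators are pure functions of
# (arguments, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column standardization that tolerates a zero-sd column by erroring with
# the offending names (several ops need that contract).
standardize <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant vector")
  (x - mean(x)) / s
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Pearson correlations between a vector and every column of a matrix,
# without per-column cor() calls.
cor_vec_mat <- function(v, m) {
  v <- as.numeric(v)
  m <- as.matrix(m)
  stopifnot(length(v) == nrow(m))
  vc <- v - mean(v)
  mc <- sweep(m, 2L, colMeans(m))
  num <- as.numeric(crossprod(vc, mc))
  den <- sqrt(sum(vc^2)) * sqrt(colSums(mc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
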