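# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# the user's random stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# sign() with sign(0) resolved to +1, the documented tie convention for the
# bag decision rule.
sign0 <- function(x) ifelse(x >= 0, 1L, -1L)

# Pairwise Hamming distances between the rows of two 0/1 matrices, computed
# with one BLAS product: H(a, b) = |a| + |b| - 2 a.b for binary vectors.
hamming_cross <- function(a, b) {
  a <- matrix(as.numeric(a), nrow = nrow(a))
  b <- matrix(as.numeric(b), nrow = nrow(b))
  h <- -2 * tcrossprod(a, b)
  h <- h + rowSums(a)
  h <- sweep(h, 2L, rowSums(b), `+`)
  round(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
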