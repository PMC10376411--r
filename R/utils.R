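# Internal helpers: seed management and small validators.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed derived from a master seed and up to two indices.
# Arithmetic in doubles (exact below 2^53), reduced to a positive 32-bit int,
# so replicate b of stream a is the same regardless of how many replicates
# are requested in total.
child_seed <- function(seed, a = 0L, b = 0L) {
  x <- (as.double(seed) %% 2147483647) * 48271 + as.double(a) * 100003 +
    as.double(b) * 7919 + 1
  as.integer(x %% 2147483629)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Symmetry check within tolerance.
is_symmetric_matrix <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

upper_tri_values <- function(m) m[upper.tri(m)]
off_diag_values <- function(m) m[row(m) != col(m)]
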