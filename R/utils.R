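# Internal helpers shared across modules.

# Run `expr` under a local RNG stream: set the seed if given, and restore the
# caller's .Random.seed afterwards so functions with explicit seed arguments
# leave no hidden global state behind.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a bounded child seed for stage `k` of a run seeded with `seed`.
childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483629)
}

# ms -> integer number of bins; errors when not commensurate with dt.
msToBins <- function(x, dt, what = "value") {
  b <- x / dt
  if (abs(b - round(b)) > 1e-8)
    stop(sprintf("%s (%g ms) must be an integer multiple of dt = %g ms",
                 what, x, dt), call. = FALSE)
  as.integer(round(b))
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(A, tol = NULL) {
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(s$d) * .Machine$double.eps
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

frobenius <- function(A) sqrt(sum(A * A))

# Relative Frobenius distance ||A - B||_F / ||B||_F.
relFrobenius <- function(A, B) frobenius(A - B) / frobenius(B)

# A stable digest of a numeric matrix for config-matching.
matrixDigest <- function(A) {
  v <- signif(as.vector(A), 12)
  paste(dim(A)[1], dim(A)[2], format(sum(v * seq_along(v)), digits = 15),
        format(sum(v * v), digits = 15), sep = ":")
}
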