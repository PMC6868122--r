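#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif var sd cor quantile fft wilcox.test cov convolve
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls never disturb user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific 32-bit sub-seed from a master seed.
subseed <- function(seed, stream) {
  (as.integer(seed) * 1009L + as.integer(stream) * 9176L) %% 2147483647L
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}

vec3 <- function(x, name = "vector") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop(sprintf("`%s` must be a finite length-3 numeric vector", name), call. = FALSE)
  x
}
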