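#' @importFrom rlang abort warn .data
#' @importFrom stats var median sd fft rnorm runif rexp logLik pchisq pt
#'   p.adjust cor.test coef quantile setNames nobs
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generators funnel through this so identical
# spec + seed is bit-reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
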