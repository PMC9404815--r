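#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rpois rexp sd var filter predict setNames
#' @importFrom utils read.csv write.csv head tail
NULL

## Evaluate `code` under a fixed RNG state, restoring the caller's state on
## exit.  All stochastic operations in the package funnel through this so a
## single integer seed makes any run reproducible without clobbering the
## session RNG.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

## round-half-up (base round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Derive a child seed from a master seed and an index, staying inside the
## 32-bit integer range R requires of set.seed().
childSeed <- function(master, index) {
  (as.double(master) * 7919 + as.double(index) * 104729) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
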