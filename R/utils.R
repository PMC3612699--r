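#' @import methods
#' @importFrom stats runif rnorm plogis cor median setNames
#' @importFrom utils head modifyList write.csv read.csv
NULL

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit integer mix of a base seed and a few indices, used to
# derive per-image / per-stage seeds so that streams are independent.
mixSeed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) h <- (h * 7919 + as.numeric(v) * 104729 + 12345) %% 2147483647
  as.integer(h)
}

# Stable argmax: first index attaining the maximum.
whichMax1 <- function(x) which.max(x)

stopIfNot01 <- function(x, what = "values") {
  if (any(!is.finite(x))) stop("non-finite ", what)
  if (min(x) < 0 || max(x) > 1) stop(what, " outside [0,1]")
  invisible(TRUE)
}
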