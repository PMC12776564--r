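#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit. All stochastic operations in
#' the package route their seeds through this helper so that identical
#' seeds give bit-identical streams regardless of surrounding code.
#'
#' @param seed integer scalar, or NULL to leave the RNG state alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out of one master seed into independent named
#' streams (data, weight init, shuffling, ...). Kept below 2^31 so the
#' result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param stream small non-negative integer identifying the stream.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 30269) %% 2147483423
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
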