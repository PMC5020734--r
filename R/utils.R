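# internal helpers: seed scoping and deterministic seed splitting

# run code under a given seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule so that pipeline stages and ensemble
#' realizations each get an independent, reproducible stream: an LCG-style
#' mix of the master seed and a stage/realization index, reduced modulo
#' 2^31 - 1. The arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param seed Master seed (integer-valued).
#' @param index Nonnegative integer stage or realization index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  m <- 2147483647
  s <- (as.double(seed) %% m + m) %% m
  x <- (s * 48271) %% m
  x <- (x + (as.double(index) * 16807) %% m) %% m
  x <- (x * 69621) %% m
  as.integer(x %% (m - 2) + 1)
}

stop_if_negative <- function(x, what) {
  if (any(x < 0)) stop(what, " must be nonnegative")
  invisible(x)
}
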