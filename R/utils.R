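# Seed handling. All stochastic operations accept explicit seeds; helper
# runs code under a temporary RNG state so library calls never disturb the
# caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a replicate-level RNG seed from a master seed
#'
#' Splitting rule used throughout the package: a linear-congruential hash
#' of (master seed, replicate index, frame index, stream id) reduced
#' modulo 2^31 - 1. Distinct inputs give distinct, reproducible seeds and
#' the result always fits a 32-bit integer.
#'
#' @param master master seed (integer).
#' @param replicate replicate index (>= 0).
#' @param frame frame index (>= 0).
#' @param stream extra stream discriminator (>= 0), e.g. one per
#'   condition or profile.
#' @export
derive_seed <- function(master, replicate = 0L, frame = 0L, stream = 0L) {
  m <- 2147483647
  h <- (as.numeric(master) %% m)
  for (x in c(replicate, frame, stream)) {
    h <- (h * 48271 + as.numeric(x) + 1) %% m
  }
  as.integer(h) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
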