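## RNG helpers: every stochastic operation takes a master seed and derives
## per-stream seeds from it, so any replicate (restart, reference draw,
## noise replicate, CV replicate) can be reproduced in isolation.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state, so package internals never
#' perturb the user's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
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

#' Derive a sub-stream seed from a master seed
#'
#' Deterministic integer hash of the master seed, a stream tag and any
#' number of integer indices; results stay below 2^31.
#'
#' @param seed integer master seed.
#' @param tag character stream label.
#' @param ... integer indices (replicate, k, ...).
#' @return A single integer in \[0, 2^31).
#' @keywords internal
deriveSeed <- function(seed, tag, ...) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  for (ix in c(...)) h <- (h * 48271 + as.double(ix) + 1) %% m
  as.integer(h)
}
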