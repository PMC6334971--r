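# Small shared helpers.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with \code{set.seed(seed)} and restores the caller's RNG
#' state afterwards, so seeded generators never perturb surrounding
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
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

# round half away from zero (base round() rounds half to even)
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive a stream of sub-seeds from one master seed, kept below 2^31
subSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}
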