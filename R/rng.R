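#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic stages of the package draw their randomness from named
#' substreams of a single master seed, so that any single subject, bootstrap
#' replicate or pipeline stage can be regenerated in isolation.
#'
#' @param seed master integer seed
#' @param label character stream label (e.g. `"covariates"`, `"image"`)
#' @param index optional integer index within the stream
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.double(seed) %% 2147483647) * 48271 +
                as.double(index) * 2654435) %% 2147483647)
}

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
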