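#' Derive a named substream seed from a global seed
#'
#' All randomness in plumfuse flows from one integer seed, fanned out into
#' named independent substreams (one per pipeline stage), so that e.g. changing
#' the train/test split seed never perturbs the simulated spectra. The mapping
#' is a fixed modular hash: deterministic, platform independent, and always
#' below 2^31 so the result is a valid `set.seed()` argument.
#'
#' @param seed Integer global seed.
#' @param stream Character stream name, e.g. `"ssc"`, `"spectra"`, `"images"`.
#' @return A single integer seed.
#' @examples
#' substream_seed(1, "ssc")
#' substream_seed(1, "images")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

# evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
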