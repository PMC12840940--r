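#' Sample a synthetic soluble-solids reference table
#'
#' Draws per-fruit soluble solid content (SSC, degrees Brix) from a normal
#' distribution truncated by rejection to `[lower, upper]`. The defaults are
#' the fitted distribution of a 120-fruit model-building cohort of Sanhua
#' plums: mean 13.00 and SD 1.25 degrees Brix on 10.2-15.3 degrees Brix.
#' Rejection (rather than clipping) preserves the truncated-normal shape, so
#' the sample moments converge to the truncated distribution's rather than to
#' a spike-contaminated one.
#'
#' @param n_samples Number of fruits to draw (>= 0).
#' @param mu,sigma Mean and SD (degrees Brix) of the parent normal; `sigma >= 0`.
#' @param lower,upper Truncation bounds (degrees Brix), `lower < upper`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param id_prefix Prefix for generated sample identifiers.
#' @return A tibble with columns `sample_id` (character, unique) and
#'   `ssc_brix` (numeric, all within `[lower, upper]`).
#' @examples
#' ssc <- sample_ssc(5, seed = 1)
#' ssc
#' @export
sample_ssc <- function(n_samples = 120, mu = 13.00, sigma = 1.25,
                       lower = 10.2, upper = 15.3, seed = 1,
                       id_prefix = "plum") {
  if (!is.numeric(sigma) || sigma < 0) {
    abort("`sigma` must be >= 0", class = "plumfuse_parameter_error")
  }
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("`lower` must be strictly less than `upper`",
          class = "plumfuse_parameter_error")
  }
  if (!is.numeric(n_samples) || n_samples < 0 || n_samples != round(n_samples)) {
    abort("`n_samples` must be a non-negative integer",
          class = "plumfuse_parameter_error")
  }
  n_samples <- as.integer(n_samples)
  if (sigma == 0 && (mu < lower || mu > upper)) {
    abort("degenerate distribution (sigma = 0) with `mu` outside the bounds",
          class = "plumfuse_parameter_error")
  }
  vals <- with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n_samples) {
      draw <- rnorm(max(2L * (n_samples - length(out)), 16L), mu, sigma)
      out <- c(out, draw[draw >= lower & draw <= upper])
    }
    out[seq_len(n_samples)]
  })
  tibble(
    sample_id = sprintf("%s_%03d", id_prefix, seq_len(n_samples)),
    ssc_brix = vals
  )
}
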