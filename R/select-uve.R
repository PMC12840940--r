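#' Uninformative variable elimination (UVE) wavelength selection
#'
#' Appends `p` artificial noise columns to the predictor block and refits a
#' PLSR over resampled folds (leave-one-out by default), collecting the
#' per-variable regression coefficients of every fit. A variable's
#' *reliability* is `c_j = mean(b_j) / sd(b_j)` across folds; real variables
#' whose `|c_j|` does not exceed the `percentile_cutoff`-th percentile of the
#' noise columns' `|c|` are discarded as uninformative. Predictors are
#' autoscaled (unit variance, per fold) inside the PLSR, making the
#' reliability scale-free: rescaling a real column by any positive factor
#' leaves its reliability unchanged, and the magnitude of `noise_scale` is
#' immaterial.
#'
#' @param x Predictor matrix or wide spectral tibble (training set).
#' @param y Numeric response.
#' @param n_latent PLSR components for the augmented fits (default 10,
#'   capped by feasibility).
#' @param noise_scale Amplitude of the uniform artificial noise columns
#'   (default 1e-10).
#' @param percentile_cutoff Percentile (0-100) of the noise reliabilities
#'   used as the threshold (default 99; a percentile rather than the maximum
#'   resists a single extreme noise reliability).
#' @param seed Integer seed for the noise columns.
#' @return A `selection_result` with `$reliability` (length p, real
#'   variables), `$threshold`, and the retained indices (never pointing at a
#'   noise column).
#' @export
uve_select <- function(x, y, n_latent = 10, noise_scale = 1e-10,
                       percentile_cutoff = 99, seed = 1) {
  wl <- if (is.data.frame(x)) spectra_wavelengths(x) else NULL
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n < 5) abort("UVE needs n >= 5", class = "plumfuse_parameter_error")
  noise <- with_seed(substream_seed(seed, "uve"),
                     matrix(runif(n * p), n, p) * noise_scale)
  aug <- cbind(x, noise)

  coefs <- matrix(NA_real_, n, 2 * p)      # one row of coefficients per fold
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    a <- min(n_latent, length(tr) - 1, 2 * p)
    fit <- plsr_fit(aug[tr, , drop = FALSE], y[tr], n_latent = a, scale = TRUE)
    coefs[i, ] <- fit$coefficients
  }
  mu <- colMeans(coefs)
  s <- apply(coefs, 2, sd)
  reliability <- numeric(2 * p)
  ok <- s > 0
  reliability[ok] <- mu[ok] / s[ok]
  if (any(!ok)) {
    warn("zero coefficient SD for some variables; their reliability is set to 0")
  }
  threshold <- as.numeric(quantile(abs(reliability[(p + 1):(2 * p)]),
                                   percentile_cutoff / 100, type = 7))
  selected <- which(abs(reliability[seq_len(p)]) > threshold)
  if (length(selected) == 0) {
    selected <- which.max(abs(reliability[seq_len(p)]))
  }
  new_selection_result("UVE", selected, wl,
                       tibble(threshold = threshold,
                              n_retained = length(selected)),
                       seed,
                       extra = list(reliability = reliability[seq_len(p)],
                                    threshold = threshold))
}
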