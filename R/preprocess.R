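#' Reflectance calibration against dark and white references
#'
#' Converts raw counts to relative reflectance per sample and wavelength:
#' `R = (S - D) / (W - D)`, where `D` is the dark-current spectrum (light off,
#' fiber port covered) and `W` the standard white board spectrum.
#'
#' @param spectra Raw wide spectral tibble (see [spectra_tbl()]).
#' @param dark,white Reference tibbles (`wavelength_nm`, `intensity`) on the
#'   same grid; `white` must exceed `dark` at every wavelength.
#' @return A wide spectral tibble of reflectance values.
#' @examples
#' raw <- simulate_spectra(sample_ssc(2, seed = 1), seed = 1)
#' refl <- calibrate_reflectance(raw$spectra, raw$dark, raw$white)
#' @export
calibrate_reflectance <- function(spectra, dark, white) {
  wl <- check_same_grid(spectra, dark, white)
  denom <- white$intensity - dark$intensity
  if (any(denom <= 0)) {
    bad <- wl[which(denom <= 0)[1]]
    abort(paste0("white reference does not exceed dark current at ", bad, " nm"),
          class = "plumfuse_calibration_error")
  }
  m <- spectra_matrix(spectra)
  r <- sweep(sweep(m, 2, dark$intensity, `-`), 2, denom, `/`)
  spectra_tbl(r, wl, spectra$sample_id)
}

#' Savitzky-Golay polynomial smoothing
#'
#' Replaces each spectrum by the moving least-squares polynomial fit evaluated
#' at the window center. Edges are handled by fitting the boundary window's
#' polynomial and evaluating it at the edge positions, so the wavelength grid
#' is preserved (downstream wavelength selection indexes into it). Delegates
#' to `signal::sgolayfilt`, whose transient handling implements exactly this
#' polynomial-extension rule.
#'
#' @param spectra Wide spectral tibble.
#' @param window Odd window length in points, `>= 3` (default 11 — a
#'   conventional Vis/NIR smoothing width on a 1 nm grid).
#' @param order Polynomial order, `< window` (default 2).
#' @return A wide spectral tibble on the same grid.
#' @export
sg_smooth <- function(spectra, window = 11, order = 2) {
  p <- length(spectra_wavelengths(spectra))
  if (window %% 2 != 1 || window < 3 || order >= window || order < 0 ||
      window > p) {
    abort("need odd `window` in [3, n_wavelengths] and `order` < `window`",
          class = "plumfuse_parameter_error")
  }
  m <- spectra_matrix(spectra)
  sm <- if (nrow(m) == 0) m else
    t(apply(m, 1, signal::sgolayfilt, p = order, n = window))
  spectra_tbl(sm, spectra_wavelengths(spectra), spectra$sample_id)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum to zero mean and unit sample SD
#' (`n - 1` denominator), removing per-sample multiplicative scatter and
#' additive baseline effects.
#'
#' @param spectra Wide spectral tibble with >= 2 wavelengths per spectrum.
#' @return A wide spectral tibble; every row has mean 0 and SD 1.
#' @export
snv <- function(spectra) {
  m <- spectra_matrix(spectra)
  if (ncol(m) < 2) {
    abort("SNV needs at least 2 wavelengths", class = "plumfuse_parameter_error")
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  if (any(s == 0)) {
    bad <- spectra$sample_id[which(s == 0)[1]]
    abort(paste0("zero-variance spectrum: ", bad),
          class = "plumfuse_degenerate_error")
  }
  spectra_tbl((m - mu) / s, spectra_wavelengths(spectra), spectra$sample_id)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum, `x = a + b * ref`, and
#' returns `(x - a) / b`, inverting per-sample multiplicative and additive
#' scatter. With `reference = "mean"` the reference is the mean spectrum of
#' the fitted set; it is attached to the result (attribute `msc_reference`)
#' so it can be frozen on training data and replayed on test data without
#' information leakage.
#'
#' @param spectra Wide spectral tibble.
#' @param reference `"mean"` or a numeric spectrum on the same grid.
#' @return A wide spectral tibble with attribute `msc_reference`.
#' @export
msc <- function(spectra, reference = "mean") {
  m <- spectra_matrix(spectra)
  if (identical(reference, "mean")) {
    reference <- colMeans(m)
  }
  if (length(reference) != ncol(m)) {
    abort("MSC reference must be on the same wavelength grid",
          class = "plumfuse_format_error")
  }
  refc <- reference - mean(reference)
  ss_ref <- sum(refc^2)
  if (ss_ref == 0) {
    abort("MSC reference spectrum is constant", class = "plumfuse_correction_error")
  }
  # slope of x on ref; sum(refc) = 0 so the centered cross-product suffices
  b <- as.vector(m %*% refc) / ss_ref
  a <- rowMeans(m) - b * mean(reference)
  if (any(abs(b) < 1e-12)) {
    bad <- spectra$sample_id[which(abs(b) < 1e-12)[1]]
    abort(paste0("degenerate MSC slope for sample: ", bad),
          class = "plumfuse_correction_error")
  }
  out <- spectra_tbl((m - a) / b, spectra_wavelengths(spectra), spectra$sample_id)
  attr(out, "msc_reference") <- as.numeric(reference)
  out
}

#' Preprocessing chains
#'
#' The five spectral treatments compared in the pipeline are SG, SNV, MSC and
#' the combinations SG+SNV and SG+MSC, applied left to right.
#' `fit_preprocess()` parses a chain specification (case-insensitive, `+`
#' separated), applies it to the training spectra, and freezes any stateful
#' parameters (the MSC mean reference); `apply_preprocess()` replays the
#' frozen chain on new spectra.
#'
#' @param spectra Wide spectral tibble (training set for `fit_preprocess`).
#' @param chain Chain specification string, e.g. `"SG+SNV"`.
#' @param sg_window,sg_order Savitzky-Golay settings (see [sg_smooth()]).
#' @return `fit_preprocess()`: a list of class `preprocess_chain` with the
#'   transformed training spectra in `$spectra`. `apply_preprocess()`: a wide
#'   spectral tibble.
#' @examples
#' raw <- simulate_spectra(sample_ssc(4, seed = 1), seed = 1)
#' refl <- calibrate_reflectance(raw$spectra, raw$dark, raw$white)
#' pp <- fit_preprocess(refl[1:3, ], "SG+SNV")
#' apply_preprocess(pp, refl[4, ])
#' @export
fit_preprocess <- function(spectra, chain = "SG+SNV", sg_window = 11,
                           sg_order = 2) {
  steps <- parse_chain(chain)
  state <- list()
  out <- spectra
  for (i in seq_along(steps)) {
    step <- steps[i]
    out <- tryCatch(
      switch(step,
        SG = sg_smooth(out, sg_window, sg_order),
        SNV = snv(out),
        MSC = {
          res <- msc(out, "mean")
          state$msc_reference <- attr(res, "msc_reference")
          res
        }),
      error = function(e) {
        abort(paste0("preprocessing step ", i, " (", step, ") failed: ",
                     conditionMessage(e)),
              class = "plumfuse_chain_error", parent = e)
      })
  }
  structure(list(steps = steps, sg_window = sg_window, sg_order = sg_order,
                 state = state, spectra = out),
            class = "preprocess_chain")
}

#' @rdname fit_preprocess
#' @param fitted A fitted `preprocess_chain`.
#' @export
apply_preprocess <- function(fitted, spectra) {
  stopifnot(inherits(fitted, "preprocess_chain"))
  out <- spectra
  for (i in seq_along(fitted$steps)) {
    step <- fitted$steps[i]
    out <- tryCatch(
      switch(step,
        SG = sg_smooth(out, fitted$sg_window, fitted$sg_order),
        SNV = snv(out),
        MSC = msc(out, fitted$state$msc_reference)),
      error = function(e) {
        abort(paste0("preprocessing step ", i, " (", step, ") failed: ",
                     conditionMessage(e)),
              class = "plumfuse_chain_error", parent = e)
      })
  }
  out
}

parse_chain <- function(chain) {
  if (!is.character(chain) || length(chain) != 1 || !nzchar(trimws(chain))) {
    abort("preprocessing chain must be a non-empty string like \"SG+SNV\"",
          class = "plumfuse_parameter_error")
  }
  steps <- toupper(trimws(strsplit(chain, "+", fixed = TRUE)[[1]]))
  steps <- steps[steps != "NONE"]
  if (length(steps) == 0) {
    abort("preprocessing chain is empty", class = "plumfuse_parameter_error")
  }
  bad <- setdiff(steps, c("SG", "SNV", "MSC"))
  if (length(bad)) {
    abort(paste0("unknown preprocessing step: ", bad[1]),
          class = "plumfuse_parameter_error")
  }
  steps
}
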