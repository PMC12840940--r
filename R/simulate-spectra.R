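#' Forward model and acquisition settings for simulated spectra
#'
#' `spectral_forward_model()` parameterizes the map from a fruit's SSC to its
#' true diffuse reflectance over 400-1100 nm: a gentle polynomial baseline,
#' Gaussian absorption-driven peaks near 720 and 820 nm whose amplitudes are
#' affine in SSC, and a narrow valley near 740 nm. `acquisition_params()`
#' carries the instrument knobs (integration time, disc motor speed, light
#' spot diameter, fruit posture); in the generator these act purely as scalar
#' signal and noise multipliers — intensity scales with integration time and
#' with the inverse spot diameter, and per-channel noise grows with motor
#' speed. No physical optics are simulated.
#'
#' Noise model (all seeded): a per-sample multiplicative scatter factor and
#' additive offset (what SNV/MSC are designed to remove), per-wavelength
#' detector noise, and an SSC-equivalent chemical perturbation (degrees
#' Brix) that shifts the SSC value *driving the spectrum* without changing
#' the reference value — bounding the attainable spectral prediction
#' accuracy the way un-modelled matrix effects do in real fruit. The
#' perturbation is `ssc_equivalent_noise_sd` times a per-fruit standard
#' normal *matrix factor* shared with [simulate_images()] (where it tints
#' the fruit's color): appearance carries a trace of exactly the variation
#' the spectra mis-read, which is what makes spectral-image fusion
#' informative rather than redundant.
#'
#' @param wavelength_grid Ascending grid in nm within \[400, 1100\].
#' @param baseline Coefficients `c(b0, b1, b2)` of the reflectance baseline
#'   `b0 + b1 (lambda - 750) + b2 (lambda - 750)^2`.
#' @param peak_centers,peak_sd Centers (nm) and Gaussian SDs (nm) of the
#'   reflectance peaks (FWHM about 40 nm by default).
#' @param peak_amplitude Peak amplitudes at SSC = 13 degrees Brix.
#' @param ssc_coupling Amplitude change per degree Brix for each peak.
#' @param valley_center,valley_sd,valley_amplitude,valley_coupling The
#'   subtracted valley component, same parameterization.
#' @param scatter_multiplier_sd SD of the per-sample multiplicative scatter
#'   factor (unitless, around 1).
#' @param additive_offset_sd SD of the per-sample additive baseline offset
#'   (reflectance units).
#' @param noise_sd SD of per-wavelength detector noise (reflectance units)
#'   at the reference motor speed of 6.6 r/min.
#' @param ssc_equivalent_noise_sd SD (degrees Brix) of chemical noise on the
#'   SSC value driving the spectrum.
#' @return A list of class `spectral_forward_model` / `acquisition_params`.
#' @examples
#' fwd <- spectral_forward_model()
#' acq <- acquisition_params(integration_time_ms = 14)
#' @export
spectral_forward_model <- function(wavelength_grid = seq(400, 1100, by = 1),
                                   baseline = c(0.42, 1.5e-4, -2e-7),
                                   peak_centers = c(720, 820),
                                   peak_sd = c(17, 17),
                                   peak_amplitude = c(0.20, 0.16),
                                   ssc_coupling = c(0.018, 0.012),
                                   valley_center = 740,
                                   valley_sd = 6,
                                   valley_amplitude = 0.10,
                                   valley_coupling = 0.003,
                                   scatter_multiplier_sd = 0.05,
                                   additive_offset_sd = 0.01,
                                   noise_sd = 0.002,
                                   ssc_equivalent_noise_sd = 0.35) {
  check_grid(wavelength_grid)
  if (min(wavelength_grid) < 400 || max(wavelength_grid) > 1100) {
    abort("wavelength grid must lie within [400, 1100] nm",
          class = "plumfuse_parameter_error")
  }
  sds <- c(scatter_multiplier_sd, additive_offset_sd, noise_sd,
           ssc_equivalent_noise_sd)
  if (any(sds < 0)) {
    abort("noise SDs must all be >= 0", class = "plumfuse_parameter_error")
  }
  structure(
    list(
      wavelength_grid = as.numeric(wavelength_grid), baseline = baseline,
      peak_centers = peak_centers, peak_sd = peak_sd,
      peak_amplitude = peak_amplitude, ssc_coupling = ssc_coupling,
      valley_center = valley_center, valley_sd = valley_sd,
      valley_amplitude = valley_amplitude, valley_coupling = valley_coupling,
      scatter_multiplier_sd = scatter_multiplier_sd,
      additive_offset_sd = additive_offset_sd, noise_sd = noise_sd,
      ssc_equivalent_noise_sd = ssc_equivalent_noise_sd
    ),
    class = "spectral_forward_model"
  )
}

#' @rdname spectral_forward_model
#' @param integration_time_ms Spectrometer integration time (ms); signal
#'   intensity scales linearly with it.
#' @param motor_speed_rpm Free-fall disc motor speed (r/min); per-wavelength
#'   noise SD scales with `motor_speed_rpm / 6.6`.
#' @param spot_diameter_mm Illumination spot diameter (mm); signal intensity
#'   scales with `20 / spot_diameter_mm`.
#' @param posture Fruit posture code, one of `"A"`, `"B"`, `"C"` (equatorial
#'   vs stem-end illumination); posture `"C"` attenuates the signal slightly.
#' @export
acquisition_params <- function(integration_time_ms = 14,
                               motor_speed_rpm = 6.6,
                               spot_diameter_mm = 20,
                               posture = c("A", "B", "C")) {
  posture <- match.arg(posture)
  vals <- c(integration_time_ms, motor_speed_rpm, spot_diameter_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("acquisition parameters must be strictly positive",
          class = "plumfuse_parameter_error")
  }
  structure(
    list(integration_time_ms = integration_time_ms,
         motor_speed_rpm = motor_speed_rpm,
         spot_diameter_mm = spot_diameter_mm, posture = posture),
    class = "acquisition_params"
  )
}

# shared per-fruit "matrix factor": one standard-normal latent per sample,
# drawn in its own substream so spectra and images agree on it for a given
# (seed, ssc table) while each generator stays independently reproducible.
# It models un-assayed fruit-matrix variation (skin, ripeness stage) that
# perturbs the spectral chemistry *and* shows in the fruit's appearance —
# the complementary signal that makes image fusion genuinely informative.
matrix_factor <- function(n, seed) {
  with_seed(substream_seed(seed, "matrix"), rnorm(n))
}

# true reflectance r(lambda; ssc) in (0, 1): baseline + peaks - valley
true_reflectance <- function(fwd, ssc) {
  wl <- fwd$wavelength_grid
  d <- wl - 750
  base <- fwd$baseline[1] + fwd$baseline[2] * d + fwd$baseline[3] * d^2
  r <- matrix(rep(base, each = length(ssc)), nrow = length(ssc), ncol = length(wl))
  for (k in seq_along(fwd$peak_centers)) {
    amp <- fwd$peak_amplitude[k] + fwd$ssc_coupling[k] * (ssc - 13)
    shape <- exp(-(wl - fwd$peak_centers[k])^2 / (2 * fwd$peak_sd[k]^2))
    r <- r + outer(amp, shape)
  }
  vamp <- fwd$valley_amplitude + fwd$valley_coupling * (ssc - 13)
  vshape <- exp(-(wl - fwd$valley_center)^2 / (2 * fwd$valley_sd^2))
  r - outer(vamp, vshape)
}

#' Simulate raw free-fall spectra with dark and white references
#'
#' Generates one raw spectrum per fruit in `ssc`, plus the dark-current and
#' white-board reference spectra on the same grid. Each raw spectrum is
#' `dark + (scatter * r + offset) * (white - dark) + noise`, where `r` is the
#' forward model's true reflectance at the fruit's (chemically noised) SSC, so
#' that [calibrate_reflectance()] recovers `r` exactly when all noise knobs
#' are zero. The white reference — and hence overall intensity — scales with
#' integration time and inversely with spot diameter; per-wavelength noise SD
#' scales with motor speed.
#'
#' @param ssc A tibble with `sample_id` and `ssc_brix` (see [sample_ssc()]).
#' @param fwd A [spectral_forward_model()].
#' @param acq An [acquisition_params()].
#' @param seed Integer seed; identical inputs and seed reproduce the output
#'   bit for bit.
#' @return A list with elements `spectra` (wide spectral tibble, see
#'   [spectra_tbl()]), `dark` and `white` (tibbles with `wavelength_nm`,
#'   `intensity`), and `ssc` (the input table).
#' @examples
#' ssc <- sample_ssc(3, seed = 1)
#' raw <- simulate_spectra(ssc, seed = 1)
#' raw$spectra[, 1:4]
#' @export
simulate_spectra <- function(ssc, fwd = spectral_forward_model(),
                             acq = acquisition_params(), seed = 1) {
  stopifnot(is.data.frame(ssc), all(c("sample_id", "ssc_brix") %in% names(ssc)))
  if (anyDuplicated(ssc$sample_id)) {
    abort("sample ids must be unique", class = "plumfuse_format_error")
  }
  wl <- fwd$wavelength_grid
  n <- nrow(ssc)
  p <- length(wl)

  gain <- 4000 * (acq$integration_time_ms / 11) * (20 / acq$spot_diameter_mm) *
    if (acq$posture == "C") 0.85 else 1
  d <- wl - 750
  dark <- 100 + 0.02 * (wl - 400)
  white <- dark + gain * (1 - 0.15 * (d / 350)^2)

  eta <- fwd$ssc_equivalent_noise_sd * matrix_factor(n, seed)
  draws <- with_seed(substream_seed(seed, "spectra"), {
    list(
      scatter = 1 + rnorm(n, 0, fwd$scatter_multiplier_sd),
      offset = rnorm(n, 0, fwd$additive_offset_sd),
      eps = matrix(rnorm(n * p, 0, fwd$noise_sd * acq$motor_speed_rpm / 6.6),
                   nrow = n)
    )
  })

  r <- true_reflectance(fwd, ssc$ssc_brix + eta)
  refl <- if (n == 0) r else r * draws$scatter + draws$offset + draws$eps
  raw <- sweep(refl, 2, white - dark, `*`)
  raw <- sweep(raw, 2, dark, `+`)

  list(
    spectra = spectra_tbl(raw, wl, ssc$sample_id),
    dark = reference_tbl(wl, dark),
    white = reference_tbl(wl, white),
    ssc = ssc
  )
}
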