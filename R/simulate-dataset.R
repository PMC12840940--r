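#' Generate a complete synthetic plum dataset on disk
#'
#' Runs the three generators ([sample_ssc()], [simulate_spectra()],
#' [simulate_images()]) under named substreams of one seed and writes the
#' bundle: `spectra.csv`, `dark.csv`, `white.csv`, `ssc.csv`, an `images/`
#' directory of PNGs, and a `manifest.txt` recording the seed and every
#' parameter. Re-running with the same configuration reproduces identical
#' files.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_samples Number of fruits.
#' @param seed Global integer seed.
#' @param ssc_params Named list overriding [sample_ssc()] defaults
#'   (`mu`, `sigma`, `lower`, `upper`).
#' @param fwd A [spectral_forward_model()].
#' @param acq An [acquisition_params()].
#' @param image_params Named list overriding [simulate_images()] defaults.
#' @return Invisibly, a list with the generated `ssc`, `spectra`, `dark`,
#'   `white`, `images`, and the manifest as a named list.
#' @examples
#' \donttest{
#' d <- simulate_dataset(tempfile(), n_samples = 3, seed = 1)
#' nrow(d$ssc)
#' }
#' @export
simulate_dataset <- function(out_dir, n_samples = 120, seed = 1,
                             ssc_params = list(), fwd = spectral_forward_model(),
                             acq = acquisition_params(), image_params = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir),
          class = "plumfuse_io_error")
  }

  ssc_args <- modifyList(
    list(mu = 13.00, sigma = 1.25, lower = 10.2, upper = 15.3), ssc_params)
  ssc <- sample_ssc(n_samples, mu = ssc_args$mu, sigma = ssc_args$sigma,
                    lower = ssc_args$lower, upper = ssc_args$upper,
                    seed = substream_seed(seed, "ssc"))
  raw <- simulate_spectra(ssc, fwd, acq, seed = seed)
  img_args <- c(list(ssc = ssc, seed = seed), image_params)
  images <- do.call(simulate_images, img_args)

  write_ssc_csv(ssc, file.path(out_dir, "ssc.csv"))
  write_spectra_csv(raw$spectra, file.path(out_dir, "spectra.csv"))
  write_reference_csv(raw$dark, file.path(out_dir, "dark.csv"))
  write_reference_csv(raw$white, file.path(out_dir, "white.csv"))
  write_images(images, file.path(out_dir, "images"))

  manifest <- list(
    format_version = 1, n_samples = n_samples, seed = seed,
    ssc_mu = ssc_args$mu, ssc_sigma = ssc_args$sigma,
    ssc_lower = ssc_args$lower, ssc_upper = ssc_args$upper,
    integration_time_ms = acq$integration_time_ms,
    motor_speed_rpm = acq$motor_speed_rpm,
    spot_diameter_mm = acq$spot_diameter_mm, posture = acq$posture,
    peak_centers_nm = fwd$peak_centers, valley_center_nm = fwd$valley_center,
    scatter_multiplier_sd = fwd$scatter_multiplier_sd,
    additive_offset_sd = fwd$additive_offset_sd, noise_sd = fwd$noise_sd,
    ssc_equivalent_noise_sd = fwd$ssc_equivalent_noise_sd,
    image_size = if (!is.null(image_params$image_size)) image_params$image_size else 96,
    image_noise_sd = if (!is.null(image_params$noise_sd)) image_params$noise_sd else 3.2
  )
  write_manifest(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(ssc = ssc, spectra = raw$spectra, dark = raw$dark,
                 white = raw$white, images = images, manifest = manifest))
}
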