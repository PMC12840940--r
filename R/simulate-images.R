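#' Simulate RGB fruit images carrying weak SSC information
#'
#' Renders one 8-bit RGB image per fruit: an elliptical fruit region on a
#' near-black box background. The region's base color is an affine function of
#' the fruit's SSC (`base + coupling * (ssc - 13)`), perturbed by a per-sample
#' color jitter *along the coupling direction* plus per-pixel grain, and
#' overlaid with a fixed low-frequency texture field. Jittering along the
#' coupling direction makes the color-SSC association genuinely weak — a model
#' on image features alone cannot exceed
#' `R^2 = var(ssc) / (var(ssc) + jitter^2)` no matter how many color channels
#' it pools — emulating the moderate predictive power of fruit appearance.
#' Both jitter and grain scale with the single `noise_sd` knob, so
#' `noise_sd = 0` together with zeroed couplings yields identical fruit
#' pixels across samples.
#'
#' Independently of SSC, the fruit's per-sample *matrix factor* (the shared
#' latent that also perturbs its spectrum, see [simulate_spectra()]) tints
#' the color along `matrix_coupling`. Because the factor is orthogonal to
#' SSC it does not change what an image-only model can achieve, but it gives
#' a fused model a view of the variation the spectra mis-read — the
#' complementary signal that lets fusion beat either single modality.
#'
#' @param ssc A tibble with `sample_id` and `ssc_brix`.
#' @param image_size Side length in pixels (square image, >= 16).
#' @param base_color Fruit RGB at SSC = 13 degrees Brix (8-bit channel units).
#' @param coupling Channel change per degree Brix, length 3.
#' @param matrix_coupling Channel change per SD of the shared matrix factor,
#'   length 3.
#' @param noise_sd Channel-unit noise scale: the SD of the per-sample jitter
#'   along the coupling direction, `0.75 * noise_sd` the SD of an isotropic
#'   per-sample color jitter, and `noise_sd` again the per-pixel grain SD.
#' @param texture_amplitude Amplitude (channel units) of the fixed
#'   low-frequency texture field added to all channels inside the fruit.
#' @param seed Integer seed.
#' @return A named list (one element per `sample_id`) of
#'   `image_size x image_size x 3` numeric arrays with values in \[0, 255\],
#'   with attribute `mask` (logical fruit-region matrix, shared by all images).
#' @examples
#' imgs <- simulate_images(sample_ssc(2, seed = 1), image_size = 32, seed = 1)
#' dim(imgs[[1]])
#' @export
simulate_images <- function(ssc, image_size = 96,
                            base_color = c(150, 60, 50),
                            coupling = c(2.5, 1.0, 0.5),
                            matrix_coupling = c(-2, 3, 1.5),
                            noise_sd = 3.2,
                            texture_amplitude = 6,
                            seed = 1) {
  stopifnot(is.data.frame(ssc), all(c("sample_id", "ssc_brix") %in% names(ssc)))
  if (!is.numeric(image_size) || image_size < 16) {
    abort("`image_size` must be >= 16 pixels", class = "plumfuse_parameter_error")
  }
  if (any(!is.finite(coupling)) || length(coupling) != 3) {
    abort("`coupling` must be 3 finite values", class = "plumfuse_parameter_error")
  }
  s <- as.integer(image_size)
  n <- nrow(ssc)

  # fixed geometry and texture, identical across samples
  cx <- (s + 1) / 2
  xs <- matrix(seq_len(s), s, s)          # row index
  ys <- t(xs)                              # column index
  mask <- ((xs - cx) / (0.40 * s))^2 + ((ys - cx) / (0.34 * s))^2 <= 1
  texture <- texture_amplitude *
    (sin(2 * pi * xs / (0.37 * s)) * cos(2 * pi * ys / (0.29 * s)) +
       0.5 * sin(2 * pi * (xs + ys) / (0.53 * s)))

  dir <- if (sum(coupling^2) > 0) coupling / sqrt(sum(coupling^2)) else c(1, 1, 1) / sqrt(3)
  mf <- matrix_factor(n, seed)
  draws <- with_seed(substream_seed(seed, "images"), {
    list(jitter = rnorm(n, 0, noise_sd),
         jitter_iso = matrix(rnorm(3 * n, 0, 0.75 * noise_sd), 3, max(n, 1)),
         grain = if (noise_sd > 0) rnorm(n * s * s, 0, noise_sd) else numeric(n * s * s))
  })
  grain <- array(draws$grain, dim = c(s, s, n))

  imgs <- lapply(seq_len(n), function(i) {
    col0 <- base_color + coupling * (ssc$ssc_brix[i] - 13) +
      matrix_coupling * mf[i] + dir * draws$jitter[i] + draws$jitter_iso[, i]
    img <- array(8, dim = c(s, s, 3))      # near-black background
    for (ch in 1:3) {
      plane <- col0[ch] + texture + grain[, , i]
      img[, , ch][mask] <- plane[mask]
    }
    pmin(pmax(round(img), 0), 255)
  })
  names(imgs) <- ssc$sample_id
  attr(imgs, "mask") <- mask
  imgs
}

#' Write simulated images as 8-bit RGB PNG files
#'
#' @param images A list of arrays from [simulate_images()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths (`<sample_id>.png`).
#' @export
write_images <- function(images, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::imap_chr(images, function(img, id) {
    path <- file.path(dir, paste0(id, ".png"))
    png::writePNG(img / 255, path)
    path
  })
  invisible(unname(paths))
}

#' Read an 8-bit RGB PNG as a fruit image array
#'
#' @param path Path to a PNG file.
#' @return A `height x width x 3` numeric array with values in \[0, 255\].
#' @export
read_fruit_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  round(px[, , 1:3, drop = FALSE] * 255)
}
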