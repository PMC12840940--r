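test_that("reflectance calibration maps dark/white/midpoint correctly", {
  wl <- seq(500, 509)
  dark <- tibble::tibble(wavelength_nm = wl, intensity = 100 + wl / 10)
  white <- tibble::tibble(wavelength_nm = wl, intensity = 4000 - wl / 5)
  w_mat <- matrix(rep(white$intensity, each = 3), 3)
  d_mat <- matrix(rep(dark$intensity, each = 3), 3)

  expect_equal(unname(spectra_matrix(calibrate_reflectance(
    make_spectra(w_mat, wl), dark, white))), matrix(1, 3, 10))
  expect_equal(unname(spectra_matrix(calibrate_reflectance(
    make_spectra(d_mat, wl), dark, white))), matrix(0, 3, 10))
  expect_equal(unname(spectra_matrix(calibrate_reflectance(
    make_spectra((w_mat + d_mat) / 2, wl), dark, white))), matrix(0.5, 3, 10))

  # grid mismatch and non-positive dynamic range are refused
  expect_error(calibrate_reflectance(make_spectra(w_mat, wl + 1), dark, white),
               class = "plumfuse_format_error")
  bad_white <- white; bad_white$intensity[4] <- dark$intensity[4]
  expect_error(calibrate_reflectance(make_spectra(w_mat, wl), dark, bad_white),
               regexp = "503", class = "plumfuse_calibration_error")
})

test_that("Savitzky-Golay reproduces polynomials and matches a windowed polyfit oracle", {
  wl <- seq(400, 459)
  # constants and exact quadratics are fixed points of an order-2 filter
  const <- make_spectra(matrix(7, 2, 60), wl)
  expect_equal(spectra_matrix(sg_smooth(const, 11, 2)), spectra_matrix(const))

  quad <- make_spectra(matrix(3 + 0.5 * wl - 0.01 * wl^2, 1, byrow = TRUE), wl)
  sm <- sg_smooth(quad, 11, 2)
  expect_equal(spectra_matrix(sm)[1, ], spectra_matrix(quad)[1, ],
               tolerance = 1e-9)

  # random spectrum: every point (edges included) matches the brute-force
  # per-window least-squares polynomial fit
  set.seed(41)
  y <- cumsum(rnorm(60))
  sm <- spectra_matrix(sg_smooth(make_spectra(matrix(y, 1), wl), 5, 2))[1, ]
  expect_equal(unname(sm), oracle_sg(y, 5, 2), tolerance = 1e-8)

  expect_error(sg_smooth(const, 4, 2), class = "plumfuse_parameter_error")
  expect_error(sg_smooth(const, 5, 5), class = "plumfuse_parameter_error")
})

test_that("SNV standardizes each spectrum with the sample SD", {
  expect_equal(
    unname(spectra_matrix(snv(make_spectra(matrix(c(1, 2, 3), 1))))[1, ]),
    c(-1, 0, 1))

  set.seed(42)
  sp <- make_spectra(matrix(rnorm(200, 10, 3), 4))
  out <- spectra_matrix(snv(sp))
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))
  expect_equal(spectra_matrix(snv(snv(sp))), out)   # idempotent

  flat <- make_spectra(matrix(5, 2, 10))
  expect_error(snv(flat), regexp = "s001", class = "plumfuse_degenerate_error")
})

test_that("MSC inverts affine scatter and matches the normal-equations oracle", {
  set.seed(43)
  ref <- sin(seq(0, 3, length.out = 50)) + 2
  distorted <- rbind(3 + 2 * ref, ref)
  out <- msc(make_spectra(distorted), reference = ref)
  expect_equal(unname(spectra_matrix(out)[1, ]), ref, tolerance = 1e-10)
  expect_equal(unname(spectra_matrix(out)[2, ]), ref, tolerance = 1e-10)

  rows <- matrix(rnorm(150), 3) + outer(c(1, 2, 3), ref)
  corrected <- spectra_matrix(msc(make_spectra(rows), reference = ref))
  for (i in 1:3) {
    ab <- oracle_simple_ols(rows[i, ], ref)
    expect_equal(unname(corrected[i, ]), (rows[i, ] - ab[["a"]]) / ab[["b"]],
                 tolerance = 1e-10)
  }

  # mean reference is attached for replay on new data
  fitted <- msc(make_spectra(rows))
  expect_equal(attr(fitted, "msc_reference"), unname(colMeans(rows)))
})

test_that("SNV and MSC are invariant to per-sample affine intensity distortion", {
  set.seed(44)
  base <- matrix(rnorm(300, 5), 5)
  alpha <- runif(5, 0.5, 2)
  beta <- rnorm(5)
  distorted <- base * alpha + beta

  expect_equal(spectra_matrix(snv(make_spectra(distorted))),
               spectra_matrix(snv(make_spectra(base))), tolerance = 1e-9)

  ref <- colMeans(base)
  expect_equal(spectra_matrix(msc(make_spectra(distorted), ref)),
               spectra_matrix(msc(make_spectra(base), ref)), tolerance = 1e-9)
})

test_that("preprocessing chains compose, freeze state, and validate", {
  set.seed(45)
  train <- make_spectra(matrix(rnorm(500, 10), 5))
  test <- make_spectra(matrix(rnorm(300, 10), 3))

  # single-step chain equals the bare transform
  pp <- fit_preprocess(train, "sg", sg_window = 7, sg_order = 2)
  expect_equal(pp$spectra, sg_smooth(train, 7, 2))
  expect_equal(apply_preprocess(pp, test), sg_smooth(test, 7, 2))

  # SG+SNV: output rows standardized
  out <- fit_preprocess(train, "SG+SNV")$spectra |> spectra_matrix()
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_true(all(abs(apply(out, 1, sd) - 1) < 1e-12))

  # MSC reference is learned on the training set and replayed on test data
  pp <- fit_preprocess(train, "SG+MSC")
  expect_equal(pp$state$msc_reference,
               unname(colMeans(spectra_matrix(sg_smooth(train, 11, 2)))))
  replay <- apply_preprocess(pp, test)
  direct <- msc(sg_smooth(test, 11, 2), pp$state$msc_reference)
  expect_equal(spectra_matrix(replay), spectra_matrix(direct))

  expect_error(fit_preprocess(train, ""), class = "plumfuse_parameter_error")
  expect_error(fit_preprocess(train, "SG+XYZ"), class = "plumfuse_parameter_error")
  # step errors carry the step index: a constant spectrum has zero slope
  # against the fitted MSC reference, failing at the chain's second step
  pp <- fit_preprocess(train, "SG+MSC")
  flat <- make_spectra(matrix(2, 2, 100))
  expect_error(apply_preprocess(pp, flat), regexp = "step 2",
               class = "plumfuse_chain_error")
  expect_error(fit_preprocess(make_spectra(matrix(2, 2, 100)), "SNV+SG"),
               regexp = "step 1", class = "plumfuse_chain_error")
})

test_that("calibration + preprocessing of noiseless simulations is deterministic", {
  ssc <- sample_ssc(6, seed = 10)
  fwd <- spectral_forward_model(scatter_multiplier_sd = 0,
                                additive_offset_sd = 0, noise_sd = 0,
                                ssc_equivalent_noise_sd = 0)
  run <- function() {
    raw <- simulate_spectra(ssc, fwd, seed = 3)
    refl <- calibrate_reflectance(raw$spectra, raw$dark, raw$white)
    fit_preprocess(refl, "SG+SNV")$spectra
  }
  expect_identical(run(), run())
})
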