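# Fit the pipeline twice on the same on-disk dataset, scrambling the spectra
# and images of the *test* samples before the second run. Every fitted object
# must be identical across the two runs if nothing leaks from the test
# partition into model development.
leakage_double_fit <- function(n = 40, seed = 2) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  simulate_dataset(dir, n_samples = n, seed = seed,
                   image_params = list(image_size = 32))
  cfg <- function() pipeline_config(
    seed = seed, selection = "cars",
    selection_args = list(n_runs = 10, max_latent = 5),
    paths = list(spectra = file.path(dir, "spectra.csv"),
                 dark = file.path(dir, "dark.csv"),
                 white = file.path(dir, "white.csv"),
                 ssc = file.path(dir, "ssc.csv"),
                 images = file.path(dir, "images")))
  run1 <- run_pipeline(cfg())

  # scramble the held-out samples' raw data
  split <- attr(run1, "split")
  spectra <- read_spectra_csv(file.path(dir, "spectra.csv"))
  m <- spectra_matrix(spectra)
  te <- match(split$test, spectra$sample_id)
  set.seed(seed + 1)
  for (i in te) m[i, ] <- m[i, sample(ncol(m))]
  write_spectra_csv(spectra_tbl(m, spectra_wavelengths(spectra),
                                spectra$sample_id),
                    file.path(dir, "spectra.csv"))
  for (id in split$test) {
    png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)),
                  file.path(dir, "images", paste0(id, ".png")))
  }
  run2 <- run_pipeline(cfg())
  list(run1 = run1, run2 = run2)
}

expect_no_leakage <- function(runs) {
  m1 <- attr(runs$run1, "models")
  m2 <- attr(runs$run2, "models")
  for (nm in c("spectral", "image", "fused")) {
    expect_identical(m1[[nm]]$fit$coefficients, m2[[nm]]$fit$coefficients)
    expect_identical(m1[[nm]]$fit$n_latent, m2[[nm]]$fit$n_latent)
    expect_identical(m1[[nm]]$pred_tr, m2[[nm]]$pred_tr)
  }
  expect_identical(m1$fused$fusion$spectral_weights,
                   m2$fused$fusion$spectral_weights)
  expect_identical(m1$fused$fusion$visual_weights,
                   m2$fused$fusion$visual_weights)
  expect_identical(attr(runs$run1, "selection")$selected,
                   attr(runs$run2, "selection")$selected)
  expect_identical(attr(runs$run1, "visual_standardizer"),
                   attr(runs$run2, "visual_standardizer"))
  # training metrics agree; test metrics differ because the data differ
  s1 <- as.data.frame(runs$run1)
  s2 <- as.data.frame(runs$run2)
  expect_identical(s1$r2_train, s2$r2_train)
}
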