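test_that("CARS decay schedule satisfies its boundary conditions", {
  r <- plumfuse:::cars_schedule(500, 50)
  expect_equal(r[1], 1)
  expect_equal(r[50], 2 / 500)
  expect_equal(plumfuse:::cars_keep_n(r[50], 500), 2L)  # final run keeps 2
  expect_equal(plumfuse:::cars_keep_n(r[1], 500), 500L)  # first run keeps all
  expect_true(all(diff(r) < 0))

  r2 <- plumfuse:::cars_schedule(120, 30)
  expect_equal(r2[1], 1, tolerance = 1e-12)
  expect_equal(r2[30], 2 / 120, tolerance = 1e-12)
})

test_that("CARS shrinks the retained set monotonically and is deterministic", {
  set.seed(60)
  n <- 60; p <- 40
  x <- matrix(rnorm(n * p), n, p)
  y <- as.vector(x[, c(5, 20)] %*% c(2, -1.5)) + rnorm(n, 0, 0.3)
  res <- cars_select(x, y, n_runs = 20, seed = 3)
  expect_s3_class(res, "selection_result")
  expect_gte(length(res$selected), 1)
  expect_true(all(res$selected >= 1 & res$selected <= p))
  expect_false(anyDuplicated(res$selected) > 0)
  expect_true(all(diff(res$trace$n_retained) <= 0))
  expect_identical(res, cars_select(x, y, n_runs = 20, seed = 3))
  expect_false(identical(res$selected,
                         cars_select(x, y, n_runs = 20, seed = 4)$selected))

  expect_error(cars_select(x[1:3, ], y[1:3], cv_folds = 5),
               class = "plumfuse_parameter_error")
  expect_error(cars_select(matrix(1, 20, 3), rnorm(20)),
               class = "plumfuse_degenerate_error")
})

test_that("CARS recovers known informative bands from synthetic spectra", {
  # response depends on 6 known wavelength bands only; over 20 seeds the
  # median recovered-band count should reach at least 4 of 6
  wl <- seq(600, 780)
  p <- length(wl)
  true_centers <- c(615, 650, 675, 700, 730, 765)
  true_idx <- match(true_centers, wl)
  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 120
    conc <- matrix(rnorm(n * 6), n, 6)
    shapes <- sapply(true_centers, function(cc) exp(-(wl - cc)^2 / (2 * 4^2)))
    x <- conc %*% t(shapes) + matrix(rnorm(n * p, 0, 0.02), n)
    y <- as.vector(conc %*% c(1, -1, 0.8, 1.2, -0.6, 0.9))
    sel <- cars_select(x, y, n_runs = 30, seed = s)
    # a band counts as recovered if a selected index lies within its width
    sum(vapply(true_idx, function(ti) any(abs(sel$selected - ti) <= 6), TRUE))
  }, 0)
  expect_gte(median(hits), 4)
})

test_that("SPA chains follow maximal orthogonal residual norms", {
  # orthogonal mean-zero columns with distinct norms chain in decreasing
  # norm order from any start (projection leaves the others untouched)
  set.seed(66)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(90), 10, 9))))[, 2:5]
  x <- q %*% diag(c(4, 9, 1, 6))
  chain <- plumfuse:::spa_chain(sweep(x, 2, colMeans(x)), start = 2, max_vars = 4)
  expect_equal(chain, c(2, 4, 1, 3))
  chain3 <- plumfuse:::spa_chain(sweep(x, 2, colMeans(x)), start = 3, max_vars = 4)
  expect_equal(chain3, c(3, 2, 4, 1))

  # a duplicated column is never added after its twin
  set.seed(61)
  xd <- matrix(rnorm(80), 20, 4)
  xd <- cbind(xd, xd[, 2])
  chain <- plumfuse:::spa_chain(sweep(xd, 2, colMeans(xd)), start = 2, max_vars = 5)
  expect_false(all(c(2, 5) %in% chain))

  # random matrix: chain matches a brute-force Gram-Schmidt argmax oracle
  set.seed(62)
  xr <- matrix(rnorm(200), 20, 10)
  xc <- sweep(xr, 2, colMeans(xr))
  for (start in 1:10) {
    chain <- plumfuse:::spa_chain(xc, start, max_vars = 5)
    sel <- start
    for (k in 2:5) {
      basis <- qr.Q(qr(xc[, sel, drop = FALSE]))
      resid <- xc - basis %*% crossprod(basis, xc)
      norms <- sqrt(colSums(resid^2))
      norms[sel] <- -Inf
      sel <- c(sel, which.max(norms))
    }
    expect_equal(chain, sel)
  }
})

test_that("SPA selection scores chains on a held-out split deterministically", {
  set.seed(63)
  n <- 40; p <- 12
  x <- matrix(rnorm(n * p), n, p)
  y <- as.vector(x[, c(3, 7, 11)] %*% c(1.5, -2, 1)) + rnorm(n, 0, 0.1)
  res <- spa_select(x, y, min_vars = 2, max_vars = 6, seed = 5)
  expect_s3_class(res, "selection_result")
  expect_true(length(res$selected) >= 2 && length(res$selected) <= 6)
  expect_identical(res, spa_select(x, y, min_vars = 2, max_vars = 6, seed = 5))
  # the informative trio should dominate the winning chain
  expect_gte(length(intersect(res$selected, c(3, 7, 11))), 2)
  expect_error(spa_select(x, y, min_vars = 0, max_vars = 6),
               class = "plumfuse_parameter_error")
  expect_error(spa_select(x, y, min_vars = 2, max_vars = 50),
               class = "plumfuse_parameter_error")
})

test_that("UVE retains a perfect predictor and rejects pure noise", {
  # y depends on column 4 exactly: it must survive at every seed
  for (s in 1:5) {
    set.seed(3000 + s)
    x <- matrix(rnorm(30 * 8), 30, 8)
    y <- x[, 4]
    res <- uve_select(x, y, n_latent = 3, seed = s)
    expect_true(4 %in% res$selected)
    expect_true(all(res$selected <= 8))   # never an appended noise column
  }

  # null response: the retained count collapses
  retained <- vapply(1:20, function(s) {
    set.seed(4000 + s)
    x <- matrix(rnorm(60 * 20), 60, 20)
    y <- rnorm(60)
    length(uve_select(x, y, n_latent = 5, seed = s)$selected)
  }, 0)
  expect_lte(median(retained), 1)
})

test_that("UVE reliability is invariant to rescaling a real column", {
  set.seed(64)
  x <- matrix(rnorm(25 * 6), 25, 6)
  y <- as.vector(x %*% c(1, 0, 0.5, 0, -1, 0)) + rnorm(25, 0, 0.2)
  r1 <- uve_select(x, y, n_latent = 3, seed = 9)
  x_scaled <- x
  x_scaled[, 3] <- 40 * x[, 3]
  r2 <- uve_select(x_scaled, y, n_latent = 3, seed = 9)
  expect_equal(r2$reliability, r1$reliability, tolerance = 1e-8)
  expect_identical(r2$selected, r1$selected)
})

test_that("selection results serialize to CSV with diagnostics", {
  set.seed(65)
  sp <- make_spectra(matrix(rnorm(300), 10), wl = seq(700, 729))
  y <- rnorm(10)
  res <- cars_select(sp, y, n_runs = 10, cv_folds = 3, seed = 1)
  expect_equal(res$wavelengths, seq(700, 729)[res$selected])

  path <- withr::local_tempfile(fileext = ".csv")
  write_selection_csv(res, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$index, res$selected)
  meta <- read_manifest(paste0(path, ".meta.txt"))
  expect_equal(meta[["method"]], "CARS")
})
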