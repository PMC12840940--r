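test_that("PLSR collapses to OLS in the univariate and full-rank limits", {
  set.seed(50)
  x1 <- matrix(rnorm(30), 30, 1)
  y1 <- 2 + 3 * x1[, 1] + rnorm(30, 0, 0.2)
  fit <- plsr_fit(x1, y1, n_latent = 1)
  ls <- oracle_ols_coef(x1, y1)
  expect_equal(predict(fit, x1), as.vector(cbind(1, x1) %*% ls),
               tolerance = 1e-10)

  x <- matrix(rnorm(200), 40, 5)
  y <- x %*% c(1, -1, 0.5, 2, 0) + rnorm(40, 0, 0.3)
  fit <- plsr_fit(x, y, n_latent = 5)
  ls <- oracle_ols_coef(x, y)
  expect_equal(fit$coefficients, ls[-1], tolerance = 1e-8)
  expect_equal(fit$intercept, ls[1], tolerance = 1e-8)
})

test_that("PLSR recovers low-rank structure and matches an iterative NIPALS oracle", {
  set.seed(51)
  scores <- matrix(rnorm(30), 10, 3)
  load <- matrix(rnorm(18), 3, 6)
  x <- scores %*% load
  y <- as.vector(scores %*% c(1, -2, 0.5))
  fit <- plsr_fit(x, y, n_latent = 3)
  expect_equal(cor(predict(fit, x), y)^2, 1, tolerance = 1e-8)
  expect_equal(fit$coefficients, oracle_nipals_coef(x, y, 3), tolerance = 1e-8)

  # shifting y shifts every prediction by the same constant
  fit2 <- plsr_fit(x, y + 5, n_latent = 3)
  expect_equal(predict(fit2, x), predict(fit, x) + 5, tolerance = 1e-8)

  expect_error(plsr_fit(x, y, n_latent = 11), class = "plumfuse_parameter_error")
  expect_error(plsr_fit(x, rep(1, 10), n_latent = 2),
               class = "plumfuse_degenerate_error")

  expect_equal(nrow(tidy(fit)), 6)
  expect_equal(glance(fit)$n_latent, 3)
})

test_that("coefficient paths reproduce smaller fits and drive CV selection", {
  set.seed(52)
  x <- matrix(rnorm(300), 30, 10)
  y <- as.vector(x %*% rnorm(10)) + rnorm(30, 0, 0.5)
  full <- plsr_fit(x, y, n_latent = 6)
  path <- plumfuse:::plsr_coef_path(full)
  for (a in c(1, 3, 6)) {
    expect_equal(path[, a], plsr_fit(x, y, n_latent = a)$coefficients,
                 tolerance = 1e-9)
  }

  # data with one latent dimension select one component
  t1 <- rnorm(40)
  x1 <- outer(t1, rnorm(8))
  y1 <- 2 * t1
  sel <- select_n_latent(x1 + matrix(rnorm(320, 0, 1e-8), 40), y1,
                         max_latent = 5, k_folds = 5, seed = 42)
  expect_equal(sel$n_latent, 1)

  sel1 <- select_n_latent(x, y, max_latent = 1, k_folds = 5, seed = 42)
  expect_equal(sel1$n_latent, 1)

  # determinism of the trace under a fixed seed
  a <- select_n_latent(x, y, max_latent = 6, k_folds = 5, seed = 42)
  b <- select_n_latent(x, y, max_latent = 6, k_folds = 5, seed = 42)
  expect_identical(a, b)
  expect_error(select_n_latent(x, y, k_folds = 50),
               class = "plumfuse_parameter_error")
})

test_that("train/test split is a seeded partition with round(ratio * n) training samples", {
  ids <- sprintf("s%03d", 1:120)
  sp <- train_test_split(ids, 0.7, seed = 1)
  expect_length(sp$train, 84)
  expect_length(sp$test, 36)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, train_test_split(ids, 0.7, seed = 1))
  expect_false(identical(sp, train_test_split(ids, 0.7, seed = 2)))
  expect_error(train_test_split(ids[1], 0.7, seed = 1),
               class = "plumfuse_parameter_error")
})

test_that("z-score standardizer freezes training parameters", {
  expect_equal(as.vector(zscore_apply(zscore_fit(matrix(c(2, 4, 6), 3, 1)),
                                      matrix(c(2, 4, 6), 3, 1))),
               c(-1, 0, 1))
  set.seed(53)
  xtr <- matrix(rnorm(80, 5, 2), 20, 4)
  std <- zscore_fit(xtr)
  z <- zscore_apply(std, xtr)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  # test data use the training parameters, not their own
  xte <- matrix(rnorm(40, 9, 1), 10, 4)
  expect_equal(zscore_apply(std, xte),
               sweep(sweep(xte, 2, colMeans(xtr)), 2, apply(xtr, 2, sd), `/`))
  expect_error(zscore_apply(std, xte[, 1:3]), class = "plumfuse_parameter_error")
  expect_error(zscore_fit(cbind(xtr, 7)), regexp = "5",
               class = "plumfuse_degenerate_error")
})

test_that("fusion weights match the least-squares oracle and respect blocks", {
  set.seed(54)
  zs <- scale(matrix(rnorm(150), 50, 3))
  zv <- scale(matrix(rnorm(100), 50, 2))
  beta_true <- c(2, -1, 0.5)
  y <- as.vector(zs %*% beta_true)    # exact in the spectral block only

  fw <- learn_fusion_weights(zs, zv, y, mode = "per_feature")
  ora <- oracle_ols_coef(cbind(zs, zv), y)[-1]
  expect_equal(c(fw$spectral_weights, fw$visual_weights), abs(ora),
               tolerance = 1e-8)
  expect_equal(fw$spectral_weights, abs(beta_true), tolerance = 1e-8)

  fused <- fuse(zs, zv, fw)
  expect_equal(ncol(fused), 5)
  expect_equal(fused[, 1:3], sweep(zs, 2, fw$spectral_weights, `*`),
               ignore_attr = TRUE)

  # identity weights reduce fusion to plain concatenation
  fw1 <- fw; fw1$spectral_weights <- rep(1, 3); fw1$visual_weights <- rep(1, 2)
  expect_equal(fuse(zs, zv, fw1), cbind(zs, zv))

  # zeroed visual weights make the fused model equal the spectral-only model
  fw0 <- fw; fw0$visual_weights <- c(0, 0)
  f0 <- fuse(zs, zv, fw0)
  y2 <- y + rnorm(50, 0, 0.1)
  m_f <- plsr_fit(f0, y2, n_latent = 3)
  m_s <- plsr_fit(sweep(zs, 2, fw0$spectral_weights, `*`), y2, n_latent = 3)
  expect_equal(predict(m_f, f0), predict(m_s, sweep(zs, 2, fw0$spectral_weights, `*`)),
               tolerance = 1e-8)

  expect_error(fuse(zs[, 1:2], zv, fw), class = "plumfuse_parameter_error")
})

test_that("per-block fusion down-weights a pure-noise visual block", {
  ratios <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    n <- 60
    t1 <- rnorm(n)
    zs <- scale(outer(t1, c(1, 0.8, -0.5)) + matrix(rnorm(3 * n, 0, 0.05), n))
    zv <- scale(matrix(rnorm(4 * n), n, 4))
    y <- 13 + t1 + rnorm(n, 0, 0.1)
    fw <- learn_fusion_weights(zs, zv, y, mode = "per_block")
    abs(fw$visual_weights[1]) / abs(fw$spectral_weights[1])
  }, 0)
  expect_lt(median(ratios), 0.2)
})

test_that("evaluation metrics follow their definitions", {
  perfect <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3), "test")
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$rpd, Inf)

  null <- evaluate_predictions(c(1, 2, 3, 4), rep(2.5, 4), "test")
  expect_equal(null$r2, 0)

  # RPD = sd(y) / RMSE: construct y with sd 1 and rmse 0.5 exactly
  y <- c(12, 13, 14) / sd(c(12, 13, 14))
  pred <- y + c(0.5, -0.5, 0.5)
  ev <- evaluate_predictions(y, pred, "test")
  expect_equal(ev$rpd, 2)
  expect_true(is.na(evaluate_predictions(y, pred, "train")$rpd))

  expect_error(evaluate_predictions(c(1, 1), c(1, 2)),
               class = "plumfuse_degenerate_error")
  expect_error(evaluate_predictions(1, 1), class = "plumfuse_parameter_error")
})
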