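#' Seeded train/test split of sample ids
#'
#' Disjoint, exhaustive, shuffle-based split; the training partition gets
#' `round(ratio * n)` samples.
#'
#' @param sample_ids Character vector of unique ids.
#' @param ratio Training fraction in (0, 1); 0.7 gives the 7:3 split used
#'   throughout.
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test`.
#' @examples
#' train_test_split(sprintf("s%02d", 1:10), 0.7, seed = 1)
#' @export
train_test_split <- function(sample_ids, ratio = 0.7, seed = 1) {
  n <- length(sample_ids)
  if (ratio <= 0 || ratio >= 1 || n < 2) {
    abort("need ratio in (0, 1) and >= 2 samples",
          class = "plumfuse_parameter_error")
  }
  n_train <- round(ratio * n)
  if (n_train < 1 || n_train >= n) {
    abort("split leaves an empty partition", class = "plumfuse_parameter_error")
  }
  perm <- with_seed(substream_seed(seed, "split"), sample(n))
  list(train = sample_ids[perm[seq_len(n_train)]],
       test = sample_ids[perm[(n_train + 1):n]])
}

#' Z-score standardization with frozen training parameters
#'
#' `zscore_fit()` learns per-feature means and sample SDs from training data;
#' `zscore_apply()` transforms any matching-width matrix with the frozen
#' parameters, so test data never leak into the standardization.
#'
#' @param x_train Numeric matrix or data frame (>= 2 rows).
#' @return `zscore_fit()`: an object of class `standardizer` with `center`
#'   and `scale`. `zscore_apply()`: a numeric matrix with standardized
#'   columns.
#' @export
zscore_fit <- function(x_train) {
  x <- as_feature_matrix(x_train)
  if (nrow(x) < 2) {
    abort("need >= 2 rows to fit a standardizer",
          class = "plumfuse_parameter_error")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  if (any(scale == 0)) {
    bad <- (colnames(x) %||% as.character(seq_len(ncol(x))))[which(scale == 0)[1]]
    abort(paste0("zero-SD training feature: ", bad),
          class = "plumfuse_degenerate_error")
  }
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' @rdname zscore_fit
#' @param standardizer A fitted `standardizer`.
#' @param x Matrix or data frame with the same number of features.
#' @export
zscore_apply <- function(standardizer, x) {
  stopifnot(inherits(standardizer, "standardizer"))
  x <- as_feature_matrix(x)
  if (ncol(x) != length(standardizer$center)) {
    abort("feature count does not match the fitted standardizer",
          class = "plumfuse_parameter_error")
  }
  sweep(sweep(x, 2, standardizer$center, `-`), 2, standardizer$scale, `/`)
}

#' Learn linear fusion weights for the spectral and visual blocks
#'
#' With `mode = "per_feature"` (the default), the standardized blocks are
#' concatenated and regressed on the response by ordinary least squares; the
#' absolute values of the per-feature coefficients become the weights (a sign
#' only flips a standardized feature, which the downstream PLSR absorbs, so
#' absolute values keep the emphasis interpretation). With
#' `mode = "per_block"`, a PLSR is fitted within each block, the response is
#' regressed on the two within-block prediction vectors, and the two absolute
#' scalar coefficients are broadcast across their blocks.
#'
#' @param z_spec,z_vis Standardized spectral and visual training blocks.
#' @param y Numeric training response.
#' @param mode `"per_feature"` or `"per_block"`.
#' @param n_latent_block Latent-variable cap for the within-block PLSR fits
#'   in `per_block` mode.
#' @return An object of class `fusion_spec` with `spectral_weights`,
#'   `visual_weights`, `mode`, and the raw OLS `coefficients`.
#' @export
learn_fusion_weights <- function(z_spec, z_vis, y, mode = c("per_feature", "per_block"),
                                 n_latent_block = 10) {
  mode <- match.arg(mode)
  z_spec <- as_feature_matrix(z_spec)
  z_vis <- as_feature_matrix(z_vis)
  y <- as.numeric(y)
  ps <- ncol(z_spec); pv <- ncol(z_vis)
  if (mode == "per_feature") {
    xx <- cbind(z_spec, z_vis)
    beta <- min_norm_ols(xx, y)
    spectral <- abs(beta[seq_len(ps)])
    visual <- abs(beta[ps + seq_len(pv)])
    coefs <- beta
  } else {
    fs <- plsr_fit(z_spec, y, n_latent = min(n_latent_block, nrow(z_spec) - 1, ps))
    fv <- plsr_fit(z_vis, y, n_latent = min(n_latent_block, nrow(z_vis) - 1, pv))
    preds <- cbind(predict(fs, z_spec), predict(fv, z_vis))
    beta <- min_norm_ols(preds, y)
    spectral <- rep(abs(beta[1]), ps)
    visual <- rep(abs(beta[2]), pv)
    coefs <- beta
  }
  if (all(c(spectral, visual) == 0)) {
    abort("all fusion weights are zero", class = "plumfuse_degenerate_error")
  }
  structure(list(spectral_weights = spectral, visual_weights = visual,
                 mode = mode, coefficients = coefs),
            class = "fusion_spec")
}

# OLS slopes (intercept dropped); falls back to the minimum-norm least-squares
# solution with a warning when the design is rank deficient
min_norm_ols <- function(x, y) {
  xx <- cbind(`(Intercept)` = 1, x)
  fit <- lm.fit(xx, y)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warn("rank-deficient fusion design; using the minimum-norm least-squares solution")
    sv <- svd(xx)
    keep <- sv$d > max(dim(xx)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], y)) / sv$d[keep])
    beta <- as.vector(beta)
  }
  unname(beta[-1])
}

#' Re-scale and concatenate the standardized blocks
#'
#' Multiplies each block's columns by its fusion weights and concatenates
#' them, spectral block first.
#'
#' @inheritParams learn_fusion_weights
#' @param spec A `fusion_spec` from [learn_fusion_weights()].
#' @return The fused numeric matrix, `ncol(z_spec) + ncol(z_vis)` columns.
#' @export
fuse <- function(z_spec, z_vis, spec) {
  stopifnot(inherits(spec, "fusion_spec"))
  z_spec <- as_feature_matrix(z_spec)
  z_vis <- as_feature_matrix(z_vis)
  if (ncol(z_spec) != length(spec$spectral_weights) ||
      ncol(z_vis) != length(spec$visual_weights)) {
    abort("block widths do not match the fusion spec",
          class = "plumfuse_parameter_error")
  }
  cbind(sweep(z_spec, 2, spec$spectral_weights, `*`),
        sweep(z_vis, 2, spec$visual_weights, `*`))
}

#' Regression performance metrics
#'
#' Computes `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`,
#' `RMSE = sqrt(mean((y - yhat)^2))`, and for the test partition the ratio of
#' performance to deviation `RPD = sd(y) / RMSE` (sample SD, `n - 1`
#' denominator, the dominant chemometrics convention).
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @param partition `"train"` or `"test"`; RPD is reported for `"test"` only.
#' @return A 1-row tibble: `partition`, `n`, `r2`, `rmse`, `rpd` (`NA` for
#'   the training partition, `Inf` when RMSE is 0).
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1.1, 2.0, 2.9), "test")
#' @export
evaluate_predictions <- function(y_true, y_pred, partition = c("test", "train")) {
  partition <- match.arg(partition)
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    abort("`y_true` and `y_pred` must have equal length >= 2",
          class = "plumfuse_parameter_error")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    abort("`y_true` has zero variance; R^2 and RPD are undefined",
          class = "plumfuse_degenerate_error")
  }
  rmse <- sqrt(mean((y_true - y_pred)^2))
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  rpd <- if (partition == "test") {
    if (rmse == 0) Inf else sd(y_true) / rmse
  } else NA_real_
  tibble(partition = partition, n = length(y_true), r2 = r2, rmse = rmse,
         rpd = rpd)
}
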