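#' Partial least squares regression (single response, NIPALS)
#'
#' Fits a PLSR model by sequential latent-component extraction with deflation:
#' for each component the X-weight vector is the (normalized) covariance
#' `X'y`, scores are `t = X w`, loadings `p = X't / t't`, and X is deflated by
#' `t p'` before the next component. Predictors are mean-centered internally
#' (optionally variance-scaled); the response is mean-centered. With a single
#' response each component is an exact one-step solution, so the fit is fully
#' deterministic. When `n_latent` equals the rank of centered X (full-rank
#' tall X, `n_latent = p`) the coefficients coincide with ordinary least
#' squares.
#'
#' @param x Numeric predictor matrix (samples x features) or a data frame of
#'   numeric columns; a wide spectral tibble's `sample_id` column is dropped
#'   automatically.
#' @param y Numeric response vector.
#' @param n_latent Number of latent variables, `1 <= n_latent <= min(n-1, p)`.
#' @param scale Logical; also divide predictors by their training SD.
#' @return An object of class `plsr_model` with elements `coefficients`
#'   (length p), `intercept`, `x_weights`, `x_loadings`, `y_loadings`,
#'   `x_center`, `x_scale`, `y_center`, `n_latent`.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x %*% c(1, -2, 0.5) + rnorm(20, 0, 0.1)
#' fit <- plsr_fit(x, y, n_latent = 3)
#' head(predict(fit, x))
#' @export
plsr_fit <- function(x, y, n_latent, scale = FALSE) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) {
    abort("`y` length must match rows of `x`", class = "plumfuse_parameter_error")
  }
  if (n_latent < 1 || n_latent > min(n - 1, p)) {
    abort("`n_latent` must be in [1, min(n - 1, p)]",
          class = "plumfuse_parameter_error")
  }
  if (sd(y) == 0) {
    abort("response has zero variance", class = "plumfuse_degenerate_error")
  }
  x_center <- colMeans(x)
  x_scale <- if (scale) apply(x, 2, sd) else rep(1, p)
  if (any(x_scale == 0)) {
    abort("zero-variance predictor cannot be scaled",
          class = "plumfuse_degenerate_error")
  }
  e <- sweep(sweep(x, 2, x_center, `-`), 2, x_scale, `/`)
  y_center <- mean(y)
  f <- y - y_center

  W <- P <- matrix(0, p, n_latent)
  q <- numeric(n_latent)
  a <- 0
  for (k in seq_len(n_latent)) {
    w <- crossprod(e, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break    # residual X carries no covariance with y
    w <- w / nw
    t_k <- as.vector(e %*% w)
    tt <- sum(t_k^2)
    if (tt < 1e-12) break
    p_k <- crossprod(e, t_k)[, 1] / tt
    q_k <- sum(f * t_k) / tt
    e <- e - tcrossprod(t_k, p_k)
    f <- f - t_k * q_k
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k
    a <- k
  }
  if (a == 0) {
    abort("no latent component could be extracted",
          class = "plumfuse_degenerate_error")
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  b_scaled <- W %*% solve(crossprod(P, W), q)
  coefficients <- as.vector(b_scaled) / x_scale
  structure(
    list(coefficients = coefficients,
         intercept = y_center - sum(x_center * coefficients),
         x_weights = W, x_loadings = P, y_loadings = q,
         x_center = x_center, x_scale = x_scale, y_center = y_center,
         n_latent = a, n_obs = n, feature_names = colnames(x)),
    class = "plsr_model"
  )
}

#' @rdname plsr_fit
#' @param object A fitted `plsr_model`.
#' @param newdata Matrix or data frame of predictors with `p` columns.
#' @param ... Unused.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  if (ncol(x) != length(object$coefficients)) {
    abort("`newdata` width does not match the fitted model",
          class = "plumfuse_parameter_error")
  }
  as.vector(x %*% object$coefficients) + object$intercept
}

# regression coefficients (on the original x scale) for every component count
# 1..A of a fitted model; column a reproduces a fit with n_latent = a
plsr_coef_path <- function(model) {
  A <- model$n_latent
  p <- length(model$coefficients)
  out <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- model$x_weights[, seq_len(a), drop = FALSE]
    Pa <- model$x_loadings[, seq_len(a), drop = FALSE]
    qa <- model$y_loadings[seq_len(a)]
    out[, a] <- as.vector(Wa %*% solve(crossprod(Pa, Wa), qa)) / model$x_scale
  }
  out
}

#' @export
print.plsr_model <- function(x, ...) {
  cat("PLSR model:", x$n_latent, "latent variable(s),",
      length(x$coefficients), "predictors,", x$n_obs, "samples\n")
  invisible(x)
}

#' @describeIn plsr_fit tidy(): one row per predictor with its regression
#'   coefficient.
#' @method tidy plsr_model
#' @export
tidy.plsr_model <- function(x, ...) {
  tibble(term = x$feature_names %||% paste0("x", seq_along(x$coefficients)),
         estimate = x$coefficients)
}

#' @describeIn plsr_fit glance(): one-row model summary.
#' @method glance plsr_model
#' @export
glance.plsr_model <- function(x, ...) {
  tibble(n_latent = x$n_latent, n_obs = x$n_obs,
         n_predictors = length(x$coefficients))
}

#' Choose the PLSR latent-variable count by k-fold cross-validation
#'
#' Shuffles samples with the given seed into `k_folds` folds, computes the
#' held-out RMSE for every candidate component count from one fit per fold
#' (NIPALS models are nested in the component count), and returns the count
#' minimizing mean RMSECV; ties go to the smallest count.
#'
#' @inheritParams plsr_fit
#' @param max_latent Upper bound on the candidate count (default 25).
#' @param k_folds Number of folds (default 5).
#' @param seed Shuffle seed (default 42).
#' @return A list with `n_latent` (chosen count) and `trace` (tibble with
#'   `n_latent`, `rmsecv`).
#' @export
select_n_latent <- function(x, y, max_latent = 25, k_folds = 5, seed = 42,
                            scale = FALSE) {
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  if (max_latent < 1 || k_folds < 2 || n < k_folds) {
    abort("need `max_latent` >= 1, `k_folds` >= 2 and n >= `k_folds`",
          class = "plumfuse_parameter_error")
  }
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  a_max <- min(max_latent, n - max(table(folds)) - 1, ncol(x))
  if (a_max < 1) {
    abort("folds leave too few samples to fit even one component",
          class = "plumfuse_parameter_error")
  }
  sq_err <- matrix(NA_real_, n, a_max)
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    fit <- plsr_fit(x[tr, , drop = FALSE], y[tr],
                    n_latent = min(a_max, sum(tr) - 1, ncol(x)), scale = scale)
    path <- plsr_coef_path(fit)
    xa <- x[!tr, , drop = FALSE]
    for (a in seq_len(ncol(path))) {
      b <- path[, a]
      pred <- as.vector(xa %*% b) + (fit$y_center - sum(fit$x_center * b))
      sq_err[!tr, a] <- (y[!tr] - pred)^2
    }
  }
  rmsecv <- sqrt(colMeans(sq_err, na.rm = TRUE))
  keep <- !is.nan(rmsecv)
  trace <- tibble(n_latent = seq_len(a_max)[keep], rmsecv = rmsecv[keep])
  list(n_latent = trace$n_latent[which.min(trace$rmsecv)], trace = trace)
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), "sample_id")]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
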