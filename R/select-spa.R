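#' Successive projections algorithm (SPA) wavelength selection
#'
#' From every candidate starting column, SPA grows a chain by repeatedly
#' appending the column with the largest norm after projection onto the
#' orthogonal complement of the span of the already-selected columns —
#' minimizing collinearity by construction (a duplicated column has zero
#' residual norm and is never added). Every `(start, length)` chain with
#' length in `[min_vars, max_vars]` is scored by the RMSE of an ordinary
#' least-squares fit on a seeded held-out validation split; the chain with
#' minimal validation RMSE wins (ties: shorter chain, then lower start
#' index).
#'
#' @param x Predictor matrix or wide spectral tibble (training set); columns
#'   are mean-centered before projection.
#' @param y Numeric response.
#' @param min_vars,max_vars Chain length range,
#'   `1 <= min_vars <= max_vars <= min(n - 1, p)`.
#' @param validation_fraction Fraction of samples held out for scoring
#'   (default 0.2).
#' @param seed Integer seed for the validation split.
#' @return A `selection_result` with the winning chain (in selection order in
#'   `$chain`, sorted in `$selected`) and a trace of the best RMSE per chain
#'   length.
#' @export
spa_select <- function(x, y, min_vars = 5, max_vars = 25,
                       validation_fraction = 0.2, seed = 1) {
  wl <- if (is.data.frame(x)) spectra_wavelengths(x) else NULL
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (min_vars < 1 || min_vars > max_vars || max_vars > min(n - 1, p)) {
    abort("need 1 <= min_vars <= max_vars <= min(n - 1, p)",
          class = "plumfuse_parameter_error")
  }
  split <- with_seed(substream_seed(seed, "spa"), {
    n_val <- max(1, round(validation_fraction * n))
    val <- sample(n, n_val)
    list(val = sort(val), train = setdiff(seq_len(n), sort(val)))
  })
  xc <- sweep(x, 2, colMeans(x), `-`)

  chains <- lapply(seq_len(p), function(start) spa_chain(xc, start, max_vars))

  best <- NULL
  for (start in seq_len(p)) {
    chain <- chains[[start]]
    for (len in min_vars:min(max_vars, length(chain))) {
      sel <- chain[seq_len(len)]
      rmse <- ols_holdout_rmse(x[, sel, drop = FALSE], y, split$train, split$val)
      if (is.null(best) || rmse < best$rmse - 1e-12 ||
          (abs(rmse - best$rmse) <= 1e-12 &&
             (len < best$len || (len == best$len && start < best$start)))) {
        best <- list(rmse = rmse, len = len, start = start, sel = sel)
      }
    }
  }
  trace <- tibble(length = best$len, rmse = best$rmse)
  new_selection_result("SPA", best$sel, wl, trace, seed,
                       extra = list(chain = best$sel))
}

# grow one projection chain: repeatedly append the unselected column with
# maximal residual norm after deflating against the selected columns' span
spa_chain <- function(xc, start, max_vars) {
  p <- ncol(xc)
  r <- xc
  chain <- integer(0)
  current <- start
  for (step in seq_len(min(max_vars, p))) {
    chain <- c(chain, current)
    v <- r[, current]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) break
    v <- v / nv
    r <- r - v %*% crossprod(v, r)          # project out the chosen column
    norms <- sqrt(colSums(r^2))
    norms[chain] <- -Inf
    if (length(chain) >= p || max(norms) < 1e-8) break
    current <- which.max(norms)
  }
  chain
}

ols_holdout_rmse <- function(x, y, train, val) {
  fit <- lm.fit(cbind(1, x[train, , drop = FALSE]), y[train])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- as.vector(cbind(1, x[val, , drop = FALSE]) %*% beta)
  sqrt(mean((y[val] - pred)^2))
}
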