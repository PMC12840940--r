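#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' CARS ranks wavelengths by the absolute PLSR regression coefficients fitted
#' on Monte-Carlo subsets of the calibration samples and shrinks the retained
#' set over `n_runs` runs in two moves per run: an *enforced* exponential
#' reduction — run `i` keeps at most `ceiling(r_i * p)` top-weighted
#' variables, where `r_i = a * exp(-k * i)` is pinned by `r_1 = 1` and
#' `r_N = 2/p` — followed by *adaptive reweighted sampling*, which resamples
#' that many variables with replacement with probability proportional to the
#' normalized coefficient weights (duplicates collapse). Each run's retained
#' set is scored by k-fold RMSECV of a PLSR on the full calibration set; the
#' set with minimal RMSECV wins (ties: fewer variables, then the earlier run).
#'
#' @param x Predictor matrix or wide spectral tibble (training set).
#' @param y Numeric response (degrees Brix).
#' @param n_runs Number of Monte-Carlo runs `N` (default 50).
#' @param calibration_fraction Fraction of samples drawn (without replacement)
#'   for each run's coefficient fit (default 0.8).
#' @param cv_folds Folds for the RMSECV score (default 5).
#' @param max_latent Latent-variable cap for the internal PLSR fits
#'   (default 10).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return A `selection_result`: list with `method`, `selected` (sorted
#'   indices into the wavelength grid), `wavelengths` (nm, when `x` is a
#'   spectral tibble), `trace` (tibble: run, retained count, rmsecv), `seed`.
#' @export
cars_select <- function(x, y, n_runs = 50, calibration_fraction = 0.8,
                        cv_folds = 5, max_latent = 10, seed = 1) {
  wl <- if (is.data.frame(x)) spectra_wavelengths(x) else NULL
  x <- as_feature_matrix(x)
  y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (n_runs < 2 || calibration_fraction <= 0 || calibration_fraction >= 1) {
    abort("need `n_runs` >= 2 and calibration_fraction in (0, 1)",
          class = "plumfuse_parameter_error")
  }
  if (n < cv_folds) {
    abort("fewer samples than cross-validation folds",
          class = "plumfuse_parameter_error")
  }
  if (p < 2 || all(apply(x, 2, sd) == 0)) {
    abort("need >= 2 non-constant predictors", class = "plumfuse_degenerate_error")
  }

  ratios <- cars_schedule(p, n_runs)
  n_cal <- max(2, round(calibration_fraction * n))
  retained <- seq_len(p)
  runs <- vector("list", n_runs)
  with_seed(substream_seed(seed, "cars"), {
    for (i in seq_len(n_runs)) {
      sub <- sample(n, n_cal)
      a_fit <- min(max_latent, n_cal - 1, length(retained))
      fit <- plsr_fit(x[sub, retained, drop = FALSE], y[sub], n_latent = a_fit)
      w <- abs(fit$coefficients)
      if (sum(w) == 0) w <- rep(1, length(w))
      w <- w / sum(w)

      keep_n <- min(cars_keep_n(ratios[i], p), length(retained))
      forced <- retained[order(w, decreasing = TRUE)[seq_len(keep_n)]]
      w_forced <- w[match(forced, retained)]
      retained <- sort(unique(forced[
        sample.int(keep_n, keep_n, replace = TRUE, prob = w_forced)]))

      cv_seed <- sample.int(.Machine$integer.max, 1)
      score <- cars_rmsecv(x[, retained, drop = FALSE], y, cv_folds,
                           min(max_latent, length(retained)), cv_seed)
      runs[[i]] <- list(retained = retained, rmsecv = score)
      if (length(retained) < 2) break
    }
  })
  runs <- runs[!vapply(runs, is.null, TRUE)]

  trace <- tibble(
    run = seq_along(runs),
    n_retained = vapply(runs, function(r) length(r$retained), 0L),
    rmsecv = vapply(runs, function(r) r$rmsecv, 0)
  )
  best <- with(trace, order(rmsecv, n_retained, run))[1]
  new_selection_result("CARS", runs[[best]]$retained, wl, trace, seed)
}

# retain-ratio schedule r_i = a * exp(-k i) with r_1 = 1, r_N = 2/p
# (endpoints pinned exactly so the boundary conditions are not subject to
# floating-point drift in exp/log)
cars_schedule <- function(p, n_runs) {
  k <- log(p / 2) / (n_runs - 1)
  a <- exp(k)
  r <- a * exp(-k * seq_len(n_runs))
  r[1] <- 1
  r[n_runs] <- 2 / p
  r
}

# variables kept by the enforced reduction at ratio r (guards the exact
# boundary products, e.g. (2/p) * p, against upward rounding)
cars_keep_n <- function(ratio, p) as.integer(ceiling(ratio * p - 1e-9))

cars_rmsecv <- function(x, y, k_folds, max_latent, seed) {
  n <- nrow(x)
  a_max <- max(1, min(max_latent, ncol(x)))
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  a_max <- min(a_max, n - max(table(folds)) - 1)
  err <- numeric(n)
  for (k in seq_len(k_folds)) {
    tr <- folds != k
    fit <- plsr_fit(x[tr, , drop = FALSE], y[tr],
                    n_latent = min(a_max, sum(tr) - 1))
    err[!tr] <- (y[!tr] - predict(fit, x[!tr, , drop = FALSE]))^2
  }
  sqrt(mean(err))
}

new_selection_result <- function(method, selected, wavelengths, trace, seed,
                                 extra = list()) {
  structure(
    c(list(method = method, selected = as.integer(sort(selected)),
           wavelengths = if (!is.null(wavelengths)) wavelengths[sort(selected)],
           trace = trace, seed = seed),
      extra),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, "selection:", length(x$selected), "variables retained\n")
  invisible(x)
}

#' @describeIn cars_select tidy(): one row per selected variable with its
#'   grid index (and wavelength when known).
#' @param x,... For `tidy()`: a `selection_result` and unused arguments.
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(index = x$selected,
         wavelength_nm = if (!is.null(x$wavelengths)) x$wavelengths else NA_real_)
}

#' Write a selection result as CSV plus a key=value diagnostics file
#'
#' @param result A `selection_result`.
#' @param path Output CSV path; diagnostics go to `<path>.meta.txt`.
#' @export
write_selection_csv <- function(result, path) {
  readr::write_csv(tidy(result), path)
  write_manifest(
    list(method = result$method, n_selected = length(result$selected),
         seed = result$seed,
         best_rmsecv = if (!is.null(result$trace)) min(result$trace$rmsecv) else NA),
    paste0(path, ".meta.txt"))
  invisible(path)
}
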