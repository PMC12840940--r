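# Independent reference implementations used as oracles. These deliberately
# use different algorithms from the package code paths they check.

# Savitzky-Golay by explicit per-window polynomial least squares
oracle_sg <- function(y, window, order) {
  n <- length(y)
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- if (i <= half) 1:window else if (i > n - half) (n - window + 1):n
         else (i - half):(i + half)
    fit <- lm(y[j] ~ poly(j, order, raw = TRUE))
    out[i] <- unname(predict(fit, data.frame(j = i)))
  }
  out
}

# simple-regression slope/intercept by the closed-form normal equations
oracle_simple_ols <- function(x, ref) {
  b <- sum((x - mean(x)) * (ref - mean(ref))) / sum((ref - mean(ref))^2)
  c(a = mean(x) - b * mean(ref), b = b)
}

# multiple OLS coefficients via explicit normal equations
oracle_ols_coef <- function(x, y) {
  xx <- cbind(1, x)
  as.vector(solve(t(xx) %*% xx, t(xx) %*% y))
}

# textbook iterative NIPALS (vector-y case run as iterated power steps),
# returning the regression coefficient vector for centered data
oracle_nipals_coef <- function(x, y, ncomp) {
  e <- scale(x, center = TRUE, scale = FALSE)
  f <- y - mean(y)
  ww <- pp <- NULL
  qq <- numeric(0)
  for (k in seq_len(ncomp)) {
    u <- f
    w_old <- rep(0, ncol(e))
    for (it in 1:500) {
      w <- as.vector(t(e) %*% u)
      w <- w / sqrt(sum(w^2))
      t_ <- as.vector(e %*% w)
      q <- sum(f * t_) / sum(t_^2)
      u_new <- f * q     # single response: u proportional to f
      if (sqrt(sum((w - w_old)^2)) < 1e-12) break
      w_old <- w
      u <- u_new
    }
    p_ <- as.vector(t(e) %*% t_) / sum(t_^2)
    e <- e - outer(t_, p_)
    f <- f - t_ * q
    ww <- cbind(ww, w); pp <- cbind(pp, p_); qq <- c(qq, q)
  }
  as.vector(ww %*% solve(t(pp) %*% ww, qq))
}

# GLCM properties by explicit enumeration of every pixel pair
oracle_glcm <- function(gray_levels, levels, distance) {
  offsets <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nr <- nrow(gray_levels); nc <- ncol(gray_levels)
  per_angle <- sapply(offsets, function(o) {
    dr <- o[1] * distance; dc <- o[2] * distance
    cm <- matrix(0, levels, levels)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + dr; j2 <- j + dc
      if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc) {
        a <- gray_levels[i, j] + 1; b <- gray_levels[i2, j2] + 1
        cm[a, b] <- cm[a, b] + 1
        cm[b, a] <- cm[b, a] + 1      # symmetric counting
      }
    }
    pm <- cm / sum(cm)
    dm <- abs(row(pm) - col(pm))
    c(sum(pm * dm^2), sum(pm * dm), sum(pm^2), sum(pm / (1 + dm^2)))
  })
  rowMeans(per_angle)
}

# streaming two-pass mean / population SD over pixels
oracle_channel_stats <- function(v) {
  m <- sum(v) / length(v)
  c(mean = m, sd = sqrt(sum((v - m)^2) / length(v)))
}

# small helper: wide spectral tibble from a plain matrix
make_spectra <- function(m, wl = seq_len(ncol(m)) + 399) {
  spectra_tbl(m, wl, sprintf("s%03d", seq_len(nrow(m))))
}
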