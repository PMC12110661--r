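# Independent oracles used across the suite: dense linear algebra for the
# Toeplitz quadratic forms and the HK posterior, explicit per-window
# polynomial fits for DFA, and a truncated MA(infinity) ARFIMA
# autocorrelation.

dense_quadforms <- function(rho, x) {
  R <- stats::toeplitz(rho)
  Ri <- solve(R)
  e <- rep(1, length(x))
  list(xRx = drop(x %*% Ri %*% x),
       eRe = drop(e %*% Ri %*% e),
       eRx = drop(e %*% Ri %*% x),
       logdetR = as.numeric(determinant(R, logarithm = TRUE)$modulus))
}

# Log posterior of H evaluated directly from its closed form with dense
# linear algebra (no Levinson recursion anywhere on this path).
dense_logpost <- function(h, x) {
  n <- length(x)
  rho <- fgn_acf(h, n - 1)$rho
  qf <- dense_quadforms(rho, x)
  -0.5 * qf$logdetR -
    0.5 * (n - 1) * log(qf$eRe * qf$xRx - qf$eRx^2) +
    (0.5 * n - 1) * log(qf$eRe)
}

# Per-window polynomial fits through explicit normal equations on the raw
# 1..s index, then the double average of squared residuals.
bruteforce_dfa_fluct <- function(y, scales, order) {
  vapply(scales, function(s) {
    n_win <- length(y) %/% s
    msr <- vapply(seq_len(n_win), function(v) {
      yw <- y[((v - 1) * s + 1):(v * s)]
      tt <- seq_len(s)
      X <- if (order == 1) cbind(1, tt) else cbind(1, tt, tt^2)
      beta <- solve(t(X) %*% X, t(X) %*% yw)
      mean((yw - X %*% beta)^2)
    }, numeric(1))
    sqrt(mean(msr))
  }, numeric(1))
}

# Autocovariance estimate about the known process mean (zero) with the
# known process variance (one): unbiased for the population rho_k, free of
# the O(n^(2H-2)) centering bias that affects mean-centered ACF estimates
# of long-range dependent series.
acf_known_mean <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(k) sum(x[1:(n - k)] * x[(k + 1):n]) / (n - k),
         numeric(1))
}

# Theoretical ARFIMA(1, d, 0) autocorrelation via a long truncation of the
# MA(infinity) representation: psi = psi_AR(1) convolved with the
# fractional-integration coefficients.
arfima_acf_oracle <- function(d, a1, lags, trunc = 5000L) {
  j <- seq_len(trunc - 1L)
  psi_d <- c(1, cumprod((j - 1 + d) / j))
  psi_ar <- a1^(0:(trunc - 1L))
  psi <- stats::convolve(psi_d, rev(psi_ar), type = "open")[1:trunc]
  g0 <- sum(psi^2)
  vapply(lags, function(k) sum(psi[1:(trunc - k)] * psi[(k + 1):trunc]) / g0,
         numeric(1))
}
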