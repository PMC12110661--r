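# Exact fractional Gaussian noise: autocorrelation and simulation.

check_hurst <- function(H) {
  if (length(H) != 1L || !is.numeric(H) || !is.finite(H) || H <= 0 || H >= 1)
    stop("Hurst exponent must be a single number strictly inside (0, 1)",
         call. = FALSE)
  as.numeric(H)
}

check_series <- function(x, min_n = 8L) {
  if (!is.numeric(x))
    stop("time series must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (anyNA(x) || !all(is.finite(x)))
    stop("time series must contain only finite values", call. = FALSE)
  if (length(x) < min_n)
    stop(sprintf("time series too short: need at least %d observations", min_n),
         call. = FALSE)
  x
}

#' Exact autocorrelation function of fractional Gaussian noise
#'
#' Computes the exact finite-lag autocorrelation of fGn,
#' \deqn{\rho_k = \left(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\right)/2,}
#' not the asymptotic power-law approximation. For \eqn{H = 0.5} all
#' positive lags are exactly zero (white noise); the sign of \eqn{\rho_k}
#' for \eqn{k \ge 1} equals the sign of \eqn{H - 0.5}.
#'
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param max_lag largest lag to compute (nonnegative integer).
#' @return An object of class `"fgn_acf"`: a list with elements `H`,
#'   `rho` (numeric vector of \eqn{\rho_0, \ldots, \rho_{max\_lag}},
#'   `rho[1] == 1`) and `max_lag`.
#' @examples
#' fgn_acf(0.9, 5)$rho
#' @export
fgn_acf <- function(H, max_lag) {
  H <- check_hurst(H)
  if (length(max_lag) != 1L || !is.numeric(max_lag) || is.na(max_lag) ||
      max_lag < 0 || max_lag != floor(max_lag))
    stop("`max_lag` must be a single nonnegative integer", call. = FALSE)
  max_lag <- as.integer(max_lag)
  g <- (0:(max_lag + 1L))^(2 * H)     # k^{2H}, k = 0..max_lag+1
  k <- seq_len(max_lag)
  rho <- c(1, 0.5 * (g[k + 2L] - 2 * g[k + 1L] + g[k]))
  structure(list(H = H, rho = rho, max_lag = max_lag), class = "fgn_acf")
}

#' @export
print.fgn_acf <- function(x, ...) {
  cat(sprintf("fGn autocorrelation: H = %g, lags 0..%d\n", x$H, x$max_lag))
  print(utils::head(x$rho, 8L))
  invisible(x)
}

#' Simulate fractional Gaussian noise (Davies-Harte)
#'
#' Exact Gaussian simulation of zero-mean, unit-variance fGn by circulant
#' embedding: the n x n Toeplitz autocovariance is embedded in a circulant
#' matrix of order `2*(n-1)` whose eigenvalues are obtained by FFT of its
#' first row; a complex Gaussian vector shaped by the square-root
#' eigenvalues is transformed back by FFT. The output has the theoretical
#' population moments (mean 0, variance 1, autocovariance [fgn_acf()]);
#' no empirical per-series standardization is applied.
#'
#' The RNG is consumed in a fixed, documented order: one real normal draw
#' for frequency 0, then a (real, imaginary) pair for each frequency
#' `1..n-2` in ascending order, then one real draw for the Nyquist
#' frequency. Identical `(H, n, seed)` therefore reproduce the series
#' bit-for-bit; the caller's RNG state is left untouched.
#'
#' Eigenvalues more negative than floating-point noise (below
#' `-1e-10 * max(|lambda|)`) abort with an error naming the offending
#' `(H, n)` rather than being clipped; for fGn on H in (0,1) the spectrum
#' is nonnegative in practice.
#'
#' @param H Hurst exponent in (0, 1).
#' @param n series length, at least 8.
#' @param seed integer seed; same seed, same series.
#' @return numeric vector of length `n`.
#' @examples
#' x <- simulate_fgn(0.8, 128, seed = 1)
#' @export
simulate_fgn <- function(H, n, seed) {
  H <- check_hurst(H)
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 8 || n != floor(n))
    stop("`n` must be a single integer >= 8", call. = FALSE)
  n <- as.integer(n)
  rho <- fgn_acf(H, n - 1L)$rho
  m <- 2L * (n - 1L)
  half <- n - 1L                       # Nyquist index (0-based m/2)
  circ <- c(rho, rho[(n - 1L):2L])     # first row of the circulant embedding
  lam <- Re(fft(circ))
  tol <- 1e-10 * max(abs(lam))
  if (min(lam) < -tol)
    stop(sprintf(
      "circulant embedding has a negative eigenvalue (%.3e) for H = %g, n = %d",
      min(lam), H, n), call. = FALSE)
  lam[lam < 0] <- 0                    # floating-point noise only, given tol

  draws <- with_seed(seed, {
    list(z0 = rnorm(1L),
         zz = if (half > 1L) rnorm(2L * (half - 1L)) else numeric(0),
         zh = rnorm(1L))
  })
  w <- complex(m)
  w[1L] <- sqrt(lam[1L]) * draws$z0
  if (half > 1L) {
    k <- seq_len(half - 1L)
    re <- draws$zz[2L * k - 1L]
    im <- draws$zz[2L * k]
    w[k + 1L] <- sqrt(lam[k + 1L] / 2) * complex(real = re, imaginary = im)
    w[m - k + 1L] <- Conj(w[k + 1L])
  }
  w[half + 1L] <- sqrt(lam[half + 1L]) * draws$zh
  Re(fft(w))[seq_len(n)] / sqrt(m)
}
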