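# Contamination models: six processes mixed into a base series at
# amplitude A.

CONTAMINANT_KINDS <- c("awgn", "fgn", "short_range", "cyclical", "linear",
                       "quadratic")

#' Contaminant specification
#'
#' Describes one contamination process and its amplitude. Kinds:
#' \describe{
#'   \item{awgn}{additive white Gaussian noise, zero mean, unit variance.}
#'   \item{fgn}{persistent fractional Gaussian noise with Hurst exponent
#'     `Hc` (default 0.9), zero mean, unit variance.}
#'   \item{short_range}{short-range correlations: an AR(1) core with
#'     coefficient `a1` fractionally integrated by \eqn{(1-B)^{-d}}
#'     (ARFIMA-style), empirically standardized (see
#'     [gen_short_range()]).}
#'   \item{cyclical}{harmonic trend \eqn{A\sin(2\pi t/\tau)} over the
#'     running index; `tau = 365` models a short-term cycle,
#'     `tau = 36500` a long-term one.}
#'   \item{linear}{trend \eqn{\pm A\, 0.005\, t}, 1-based index.}
#'   \item{quadratic}{trend \eqn{\pm A\, 0.000005\, t^2}, 1-based index.}
#' }
#' Parameters irrelevant to a kind are validated if supplied but ignored.
#'
#' @param kind one of `"awgn"`, `"fgn"`, `"short_range"`, `"cyclical"`,
#'   `"linear"`, `"quadratic"`.
#' @param amplitude mixing amplitude A in \[0, 1\].
#' @param tau cycle period (cyclical only; default 365).
#' @param sign +1 or -1 (linear/quadratic only; default +1).
#' @param Hc Hurst exponent of the fGn contaminant (default 0.9).
#' @param d fractional differencing parameter, `0 <= d < 0.5`
#'   (short_range; default 0.25).
#' @param a1 AR(1) coefficient, `|a1| < 1` (short_range; default 0.1).
#' @return An object of class `"contaminant_spec"`.
#' @examples
#' contaminant_spec("cyclical", amplitude = 0.5, tau = 365)
#' @export
contaminant_spec <- function(kind, amplitude, tau = NULL, sign = NULL,
                             Hc = 0.9, d = 0.25, a1 = 0.1) {
  kind <- match.arg(kind, CONTAMINANT_KINDS)
  if (length(amplitude) != 1L || !is.numeric(amplitude) ||
      is.na(amplitude) || amplitude < 0 || amplitude > 1)
    stop("`amplitude` must be a single number in [0, 1]", call. = FALSE)
  if (is.null(tau)) tau <- 365
  if (length(tau) != 1L || !is.numeric(tau) || is.na(tau) || tau <= 0)
    stop("`tau` must be a single positive number", call. = FALSE)
  if (is.null(sign)) sign <- 1
  if (!sign %in% c(-1, 1))
    stop("`sign` must be +1 or -1", call. = FALSE)
  Hc <- check_hurst(Hc)
  if (length(d) != 1L || !is.numeric(d) || is.na(d) || d < 0 || d >= 0.5)
    stop("`d` must satisfy 0 <= d < 0.5", call. = FALSE)
  if (length(a1) != 1L || !is.numeric(a1) || is.na(a1) || abs(a1) >= 1)
    stop("nonstationary AR parameter: need |a1| < 1", call. = FALSE)
  structure(list(kind = kind, amplitude = as.numeric(amplitude),
                 tau = as.numeric(tau), sign = as.numeric(sign),
                 Hc = Hc, d = as.numeric(d), a1 = as.numeric(a1)),
            class = "contaminant_spec")
}

#' @export
print.contaminant_spec <- function(x, ...) {
  extra <- switch(x$kind,
                  fgn = sprintf(", Hc = %g", x$Hc),
                  short_range = sprintf(", d = %g, a1 = %g", x$d, x$a1),
                  cyclical = sprintf(", tau = %g", x$tau),
                  linear = ,
                  quadratic = sprintf(", sign = %+d", as.integer(x$sign)),
                  "")
  cat(sprintf("contaminant: %s, A = %g%s\n", x$kind, x$amplitude, extra))
  invisible(x)
}

# Compact label identifying a contaminant family (kind plus the parameter
# that distinguishes families on the benchmark grid).
contaminant_label <- function(spec) {
  switch(spec$kind,
         cyclical = sprintf("cyclical_%s", format(spec$tau, scientific = FALSE)),
         linear = if (spec$sign > 0) "linear_pos" else "linear_neg",
         quadratic = if (spec$sign > 0) "quadratic_pos" else "quadratic_neg",
         spec$kind)
}

is_stochastic_kind <- function(kind) kind %in% c("awgn", "fgn", "short_range")

#' Simulate short-range correlations (fractionally integrated AR(1))
#'
#' Generates the short-range contaminant: an AR(1) process
#' \eqn{w_t = a_1 w_{t-1} + u_t} with iid standard normal innovations,
#' fractionally integrated by \eqn{(1-B)^{-d}} through its moving-average
#' expansion \eqn{\psi_j = \Gamma(j+d) / (\Gamma(j+1)\Gamma(d))}, truncated
#' at the available history. A 1000-sample burn-in is discarded and the
#' returned segment is standardized to zero sample mean and unit sample
#' variance, so that the mixing amplitude is comparable across contaminant
#' kinds. The AR(1) autocorrelation decays with time constant
#' \eqn{-1/\ln|a_1|}; with `d = 0` and `a1 = 0` the output is standardized
#' white noise.
#'
#' @param n output length.
#' @param d fractional differencing parameter, `0 <= d < 0.5`.
#' @param a1 AR(1) coefficient, `|a1| < 1`.
#' @param seed integer seed.
#' @param burn_in samples discarded before the returned segment.
#' @return numeric vector of length `n` with sample mean 0, sample sd 1.
#' @export
gen_short_range <- function(n, d = 0.25, a1 = 0.1, seed, burn_in = 1000L) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 8 || n != floor(n))
    stop("`n` must be a single integer >= 8", call. = FALSE)
  if (length(a1) != 1L || !is.numeric(a1) || is.na(a1) || abs(a1) >= 1)
    stop("nonstationary AR parameter: need |a1| < 1", call. = FALSE)
  if (length(d) != 1L || !is.numeric(d) || is.na(d) || d < 0 || d >= 0.5)
    stop("`d` must satisfy 0 <= d < 0.5", call. = FALSE)
  n <- as.integer(n)
  L <- n + as.integer(burn_in)
  u <- with_seed(seed, rnorm(L))
  w <- as.numeric(stats::filter(u, a1, method = "recursive"))
  if (d > 0) {
    j <- seq_len(L - 1L)
    psi <- c(1, cumprod((j - 1 + d) / j))   # psi_j = Gamma(j+d)/(Gamma(j+1)Gamma(d))
    s <- convolve(psi, rev(w), type = "open")[seq_len(L)]
  } else {
    s <- w
  }
  s <- s[(L - n + 1L):L]
  (s - mean(s)) / stats::sd(s)
}

#' Mix a contaminant into a time series
#'
#' Returns `y = x + A * contaminant` according to the spec's kind:
#' white Gaussian noise, persistent fGn (via [simulate_fgn()]), short-range
#' correlations (via [gen_short_range()]), or a deterministic cyclical
#' \eqn{A\sin(2\pi t/\tau)}, linear \eqn{\pm A\,0.005\,t} or quadratic
#' \eqn{\pm A\,0.000005\,t^2} trend over the 1-based running index
#' \eqn{t = 1..n}. Deterministic kinds consume no randomness and ignore
#' `seed`; stochastic kinds require it.
#'
#' @param x numeric base series (length >= 8).
#' @param spec a [contaminant_spec()].
#' @param seed integer seed for the stochastic kinds (awgn, fgn,
#'   short_range); must be independent of the stream that generated `x`.
#' @return numeric vector, same length as `x`.
#' @examples
#' x <- simulate_fgn(0.8, 64, seed = 1)
#' y <- contaminate(x, contaminant_spec("linear", 1))
#' y[64] - x[64]  # 0.005 * 64
#' @export
contaminate <- function(x, spec, seed = NULL) {
  x <- check_series(x)
  if (!inherits(spec, "contaminant_spec"))
    stop("`spec` must be a contaminant_spec object", call. = FALSE)
  n <- length(x)
  t <- seq_len(n)
  A <- spec$amplitude
  if (is_stochastic_kind(spec$kind) && is.null(seed))
    stop(sprintf("contaminant kind '%s' is stochastic and needs a seed",
                 spec$kind), call. = FALSE)
  switch(spec$kind,
         awgn = x + A * with_seed(seed, rnorm(n)),
         fgn = x + A * simulate_fgn(spec$Hc, n, seed),
         short_range = x + A * gen_short_range(n, spec$d, spec$a1, seed),
         cyclical = x + A * sin(2 * pi * t / spec$tau),
         linear = x + spec$sign * A * 0.005 * t,
         quadratic = x + spec$sign * A * 0.000005 * t^2,
         stop("unknown contaminant kind", call. = FALSE))
}
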