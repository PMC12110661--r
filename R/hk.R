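# Bayesian Hurst-Kolmogorov estimator.

#' Toeplitz quadratic forms via the Durbin/Levinson recursion
#'
#' For the symmetric positive-definite Toeplitz autocorrelation matrix
#' \eqn{R} defined by `acf` and a data vector `x` of matching length,
#' computes the four quantities that the HK posterior needs:
#' \eqn{x'R^{-1}x}, \eqn{e'R^{-1}e}, \eqn{e'R^{-1}x} (with \eqn{e} the ones
#' vector) and \eqn{\ln|R|}, in O(n^2) time and O(n) memory. The
#' log-determinant accumulates as the sum of log prediction-error variances
#' of the Durbin recursion; the quadratic forms accumulate as weighted
#' innovations of `x` and of the ones vector.
#'
#' @param acf an [fgn_acf()] object, or a plain numeric vector of
#'   autocorrelations \eqn{\rho_0, \ldots, \rho_{n-1}} with `acf[1] == 1`.
#' @param x numeric vector, same length as the autocorrelation sequence.
#' @return An object of class `"hk_quadforms"`: list with `xRx`, `eRe`,
#'   `eRx`, `logdetR`.
#' @examples
#' x <- rnorm(32)
#' toeplitz_forms(fgn_acf(0.7, 31), x)
#' @export
toeplitz_forms <- function(acf, x) {
  rho <- if (inherits(acf, "fgn_acf")) acf$rho else as.numeric(acf)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (length(rho) != length(x))
    stop("autocorrelation sequence and series must have equal length",
         call. = FALSE)
  qf <- hk_quadforms_cpp(rho, x)
  if (!qf$ok)
    stop("autocorrelation matrix is numerically non-positive-definite",
         call. = FALSE)
  structure(qf[c("xRx", "eRe", "eRx", "logdetR")], class = "hk_quadforms")
}

#' Log marginal posterior of the Hurst exponent
#'
#' Unnormalized log posterior density of \eqn{H} under the fGn likelihood
#' with noninformative (Jeffreys) location/scale priors, the location and
#' scale integrated out:
#' \deqn{\ln\pi(h \mid x) \propto -\tfrac12\ln|R|
#'   - \tfrac{n-1}{2}\ln\!\big(e'R^{-1}e \cdot x'R^{-1}x - (e'R^{-1}x)^2\big)
#'   + \big(\tfrac n2 - 1\big)\ln e'R^{-1}e,}
#' with \eqn{R = R(h)} the exact fGn autocorrelation matrix. The density is
#' invariant (up to a constant in \eqn{h}) under affine transforms of the
#' data. Numerical non-positive-definiteness of \eqn{R(h)} maps to `-Inf`.
#'
#' @param h candidate Hurst exponent in (0, 1).
#' @param x numeric series, length at least 8, nonconstant.
#' @return a single number (`-Inf` allowed).
#' @examples
#' x <- simulate_fgn(0.8, 64, seed = 1)
#' hk_log_posterior(0.8, x) - hk_log_posterior(0.5, x)
#' @export
hk_log_posterior <- function(h, x) {
  if (length(h) != 1L || !is.numeric(h) || !is.finite(h) || h <= 0 || h >= 1)
    stop("`h` must be a single number strictly inside (0, 1)", call. = FALSE)
  x <- check_series(x)
  if (stats::var(x) == 0) stop("degenerate series: zero variance", call. = FALSE)
  hk_logpost_cpp(h, x)
}

#' Sample the HK posterior of the Hurst exponent by accept-reject
#'
#' Draws `n_samples` values of \eqn{H} from the marginal posterior
#' [hk_log_posterior()] using accept-reject with a Uniform(0,1) proposal:
#' propose \eqn{h \sim U(0,1)}, draw \eqn{u \sim U(0,1)}, accept when
#' \eqn{\ln u \le \ln\pi(h\mid x) - \ln M}. The envelope constant
#' \eqn{\ln M} is the posterior log-density maximized over
#' \eqn{h \in [10^{-6}, 1-10^{-6}]} by bounded scalar optimization
#' (absolute tolerance 1e-6 in \eqn{h}) plus a 1e-9 safety margin, so the
#' acceptance test can never exceed the numerically found maximum.
#'
#' @param x numeric series, length at least 8, nonconstant.
#' @param n_samples number of posterior draws (>= 1).
#' @param seed integer seed; the proposal stream is consumed as (h, u)
#'   pairs, so identical `(x, n_samples, seed)` reproduce the samples
#'   exactly.
#' @param max_proposals proposal budget; exceeding it is an error carrying
#'   the envelope value and the best rejected log-density, never a silent
#'   truncation.
#' @return An object of class `"hk_posterior"`: list with `samples`
#'   (accepted draws, in acceptance order), `point_estimate` (their
#'   median; even counts use the midpoint of the central order statistics),
#'   `log_M`, `n_proposals`, `acceptance_rate`.
#' @examples
#' x <- simulate_fgn(0.8, 64, seed = 1)
#' post <- sample_hk_posterior(x, n_samples = 50, seed = 2)
#' post$point_estimate
#' @export
sample_hk_posterior <- function(x, n_samples, seed, max_proposals = 1e6) {
  x <- check_series(x)
  if (stats::var(x) == 0) stop("degenerate series: zero variance", call. = FALSE)
  if (length(n_samples) != 1L || !is.numeric(n_samples) || is.na(n_samples) ||
      n_samples < 1 || n_samples != floor(n_samples))
    stop("`n_samples` must be a single integer >= 1", call. = FALSE)
  n_samples <- as.integer(n_samples)

  opt <- stats::optimize(function(h) hk_logpost_cpp(h, x),
                         interval = c(1e-6, 1 - 1e-6),
                         maximum = TRUE, tol = 1e-6)
  if (!is.finite(opt$objective))
    stop("posterior log-density could not be maximized (non-finite envelope)",
         call. = FALSE)
  log_M <- opt$objective + 1e-9

  res <- with_seed(seed, hk_sample_cpp(x, n_samples, log_M, max_proposals))
  if (!isTRUE(res$ok))
    stop(sprintf(paste0(
      "accept-reject proposal budget (%g) exhausted after %d acceptances; ",
      "log_M = %.6g, best rejected log-density = %.6g"),
      max_proposals, length(res$samples), log_M, res$best_rejected),
      call. = FALSE)

  structure(list(samples = res$samples,
                 point_estimate = stats::median(res$samples),
                 log_M = log_M,
                 n_proposals = res$n_proposals,
                 acceptance_rate = n_samples / res$n_proposals),
            class = "hk_posterior")
}

#' @export
print.hk_posterior <- function(x, ...) {
  cat(sprintf("HK posterior: %d draws, point estimate (median) = %.4f\n",
              length(x$samples), x$point_estimate))
  cat(sprintf("  acceptance rate %.3f (%d proposals), log M = %.4f\n",
              x$acceptance_rate, as.integer(x$n_proposals), x$log_M))
  invisible(x)
}

#' HK point estimate of the Hurst exponent
#'
#' Thin wrapper around [sample_hk_posterior()] returning the posterior
#' median; the default of 100 posterior draws trades accuracy against
#' computation well, with little gained beyond ~50 draws.
#'
#' @inheritParams sample_hk_posterior
#' @return the posterior median, a single number in (0, 1).
#' @examples
#' x <- simulate_fgn(0.8, 64, seed = 1)
#' estimate_h_hk(x, seed = 2)
#' @export
estimate_h_hk <- function(x, n_samples = 100, seed) {
  sample_hk_posterior(x, n_samples = n_samples, seed = seed)$point_estimate
}
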