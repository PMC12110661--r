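# Detrended fluctuation analysis, first and second order.

#' Cumulative profile of a time series
#'
#' First-order integration of the mean-centered series:
#' \eqn{y_i = \sum_{k \le i} (x_k - \bar x)}. The final profile value is
#' zero up to rounding.
#'
#' @param x numeric series (any length; a constant series gives an
#'   all-zero profile).
#' @return numeric vector, same length as `x`.
#' @export
build_profile <- function(x) {
  x <- check_series(x, min_n = 1L)
  cumsum(x - mean(x))
}

#' Default DFA scale set
#'
#' The arithmetic scale sequence 4, 8, 12, ... up to the largest multiple
#' of 4 not exceeding `floor(n/2)` — the conventional bin-size range
#' `[4, N/2]`.
#'
#' @param n series length, at least 16 (so that two scales exist).
#' @return integer vector of scales.
#' @examples
#' default_scales(32)  # 4 8 12 16
#' @export
default_scales <- function(n) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n != floor(n))
    stop("`n` must be a single integer", call. = FALSE)
  if (n < 16) stop("too short for two DFA scales (need n >= 16)", call. = FALSE)
  seq.int(4L, (as.integer(n) %/% 2L) %/% 4L * 4L, by = 4L)
}

check_scales <- function(scales, n_profile, order) {
  if (!is.numeric(scales) || length(scales) < 2L)
    stop("need at least 2 scales", call. = FALSE)
  if (any(is.na(scales)) || any(scales != floor(scales)))
    stop("scales must be integers", call. = FALSE)
  scales <- as.integer(scales)
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing", call. = FALSE)
  if (scales[1L] < order + 2L)
    stop("smallest scale leaves no residual degrees of freedom", call. = FALSE)
  if (scales[1L] < 4L) stop("scales must be >= 4", call. = FALSE)
  if (max(scales) > n_profile %/% 2L)
    stop("largest scale exceeds floor(n/2)", call. = FALSE)
  scales
}

#' DFA fluctuation function
#'
#' For each scale `s`, partitions the profile into `floor(n/s)`
#' non-overlapping windows taken from the start (any trailing remainder is
#' discarded), removes a least-squares polynomial trend of degree `order`
#' from each window, and returns
#' \deqn{f(s) = \sqrt{\frac{1}{N_s}\sum_v \frac{1}{s}\sum_i r_{v,i}^2},}
#' the RMS of residuals double-averaged over window positions and windows.
#' Window fits use the within-window centered index as regressor, which
#' changes nothing mathematically but conditions the normal equations.
#'
#' @param y profile from [build_profile()].
#' @param scales strictly increasing integer scales, each between 4 and
#'   `floor(length(y)/2)`.
#' @param order polynomial detrending order, 1 or 2.
#' @return numeric vector of fluctuations, one per scale.
#' @export
dfa_fluctuations <- function(y, scales, order = 1L) {
  if (!is.numeric(y) || length(y) < 8L)
    stop("profile must be numeric with length >= 8", call. = FALSE)
  if (length(order) != 1L || !order %in% c(1L, 2L))
    stop("`order` must be 1 or 2", call. = FALSE)
  order <- as.integer(order)
  n <- length(y)
  scales <- check_scales(scales, n, order)
  vapply(scales, function(s) {
    n_win <- n %/% s
    Y <- matrix(y[seq_len(n_win * s)], nrow = s)
    t_c <- seq_len(s) - (s + 1) / 2
    X <- cbind(1, t_c, if (order == 2L) t_c^2)
    resid <- Y - X %*% solve(crossprod(X), crossprod(X, Y))
    sqrt(mean(resid^2))
  }, numeric(1))
}

#' Fit the DFA scaling exponent
#'
#' Ordinary least squares of `log(f)` on `log(scales)` (natural logs; the
#' base does not affect the slope). A zero fluctuation at any scale is a
#' degenerate input and an error.
#'
#' @param scales scale values used.
#' @param fluctuations fluctuation values, all strictly positive.
#' @return list with `h_hat` (slope) and `intercept`.
#' @examples
#' fit_scaling_exponent(c(4, 16), c(2, 4))$h_hat  # 0.5
#' @export
fit_scaling_exponent <- function(scales, fluctuations) {
  if (length(scales) != length(fluctuations) || length(scales) < 2L)
    stop("need at least 2 (scale, fluctuation) pairs", call. = FALSE)
  if (any(fluctuations <= 0))
    stop("degenerate fluctuation: zero (or negative) value", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, log(as.numeric(scales))),
                       log(as.numeric(fluctuations)))
  list(h_hat = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]))
}

#' Estimate the Hurst exponent by DFA
#'
#' Composes [build_profile()], [dfa_fluctuations()] on [default_scales()]
#' (unless `scales` overrides them) and [fit_scaling_exponent()].
#' Deterministic for fixed input.
#'
#' @param x numeric series, length at least 16.
#' @param order polynomial detrending order, 1 (default) or 2.
#' @param scales optional scale override (see [dfa_fluctuations()]).
#' @return An object of class `"dfa_estimate"`: list with `scales`,
#'   `fluctuations`, `order`, `h_hat`, `intercept`, `n`.
#' @examples
#' x <- simulate_fgn(0.7, 256, seed = 1)
#' estimate_h_dfa(x)$h_hat
#' @export
estimate_h_dfa <- function(x, order = 1L, scales = NULL) {
  x <- check_series(x, min_n = 16L)
  if (is.null(scales)) scales <- default_scales(length(x))
  y <- build_profile(x)
  f <- dfa_fluctuations(y, scales, order)
  fit <- fit_scaling_exponent(scales, f)
  structure(list(scales = as.integer(scales), fluctuations = f,
                 order = as.integer(order), h_hat = fit$h_hat,
                 intercept = fit$intercept, n = length(x)),
            class = "dfa_estimate")
}

#' @export
print.dfa_estimate <- function(x, ...) {
  cat(sprintf("DFA%d estimate: h = %.4f (n = %d, %d scales in [%d, %d])\n",
              x$order, x$h_hat, x$n, length(x$scales),
              min(x$scales), max(x$scales)))
  invisible(x)
}
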