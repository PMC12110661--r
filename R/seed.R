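# RNG plumbing shared by the stochastic generators.

as_seed <- function(seed) {
  if (length(seed) != 1L || !is.numeric(seed) || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  as.integer(seed)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)  # materialize a state to restore
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as_seed(seed))
  expr
}

#' Deterministic substream seed
#'
#' Derives a reproducible seed for one replicate of one Monte Carlo cell
#' from the master seed and the cell identity, by hashing the stringified
#' components with a polynomial rolling hash modulo the Mersenne prime
#' 2^31 - 1. The hash is plain integer arithmetic on the UTF-8 bytes of the
#' key, so it is stable across platforms and R versions, making every cell
#' independently reproducible and resumable.
#'
#' @param ... scalar components identifying the stream (master seed,
#'   estimator, contaminant label, H, N, A, replicate index, role tag, ...).
#'   Numeric components are formatted with `sprintf("%.10g")`.
#' @return a single integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @examples
#' substream_seed(42, "HK", "awgn", 0.8, 256, 0.5, 1, "x")
#' @export
substream_seed <- function(...) {
  parts <- vapply(list(...), function(v) {
    if (length(v) != 1L) stop("substream components must be scalars")
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  }, character(1))
  key <- paste(parts, collapse = "|")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
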