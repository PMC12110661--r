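# Monte Carlo harness: per-cell summaries over a (H, N, A, contaminant,
# estimator) grid, and the which-method-to-use decision map.

ESTIMATORS <- c("HK", "DFA1", "DFA2")

# Kind labels accepted in configs; plain kinds take tau/sign from the
# config-level defaults, suffixed labels pin them per family.
KIND_LABELS <- c("awgn", "fgn", "short_range",
                 "cyclical", "cyclical_365", "cyclical_36500",
                 "linear", "linear_pos", "linear_neg",
                 "quadratic", "quadratic_pos", "quadratic_neg")

kind_to_spec <- function(label, amplitude, tau = 365, sign = 1) {
  if (!label %in% KIND_LABELS)
    stop(sprintf("unknown contaminant kind '%s'", label), call. = FALSE)
  switch(label,
         cyclical_365 = contaminant_spec("cyclical", amplitude, tau = 365),
         cyclical_36500 = contaminant_spec("cyclical", amplitude, tau = 36500),
         linear_pos = contaminant_spec("linear", amplitude, sign = 1),
         linear_neg = contaminant_spec("linear", amplitude, sign = -1),
         quadratic_pos = contaminant_spec("quadratic", amplitude, sign = 1),
         quadratic_neg = contaminant_spec("quadratic", amplitude, sign = -1),
         contaminant_spec(label, amplitude, tau = tau, sign = sign))
}

apply_estimator <- function(estimator, y, seed) {
  switch(estimator,
         HK = estimate_h_hk(y, n_samples = 100, seed = seed),
         DFA1 = estimate_h_dfa(y, order = 1L)$h_hat,
         DFA2 = estimate_h_dfa(y, order = 2L)$h_hat,
         stop(sprintf("unknown estimator '%s'", estimator), call. = FALSE))
}

#' Run one Monte Carlo cell
#'
#' For each replicate: simulate an fGn series with the true Hurst exponent,
#' mix in the contaminant, estimate, and summarize. Replicate seeds are
#' derived deterministically from the master seed and the cell identity via
#' [substream_seed()] with separate role tags for the base series, the
#' contaminant and the estimator, so the contaminant stream is independent
#' of the stream that generated the base series and every cell is
#' reproducible in isolation.
#'
#' Replicates whose estimator fails (e.g. exhausted proposal budget) are
#' excluded from the summary and counted in `n_failures`; if more than 10%
#' of replicates fail the cell is marked failed (`mean_hhat` and the
#' dispersion columns become `NA`).
#'
#' @param estimator `"HK"`, `"DFA1"` or `"DFA2"`.
#' @param H_true true Hurst exponent of the simulated base series.
#' @param n series length.
#' @param spec a [contaminant_spec()].
#' @param n_reps number of replicates (>= 2).
#' @param master_seed integer master seed.
#' @param ci `"normal"` (mean +/- 1.96 SE, default) or `"percentile"`
#'   (2.5% and 97.5% quantiles of the replicate estimates).
#' @return a one-row data.frame with columns `estimator, contaminant,
#'   H_true, N, A, tau, sign, n_reps, n_failures, mean_hhat, sd_hhat,
#'   ci_low, ci_high`.
#' @examples
#' run_cell("DFA1", 0.5, 64, contaminant_spec("awgn", 0), 5, 42)
#' @export
run_cell <- function(estimator, H_true, n, spec, n_reps, master_seed,
                     ci = c("normal", "percentile")) {
  estimator <- match.arg(estimator, ESTIMATORS)
  ci <- match.arg(ci)
  if (length(n_reps) != 1L || !is.numeric(n_reps) || is.na(n_reps) || n_reps < 2)
    stop("`n_reps` must be a single integer >= 2", call. = FALSE)
  if (!inherits(spec, "contaminant_spec"))
    stop("`spec` must be a contaminant_spec object", call. = FALSE)
  n_reps <- as.integer(n_reps)
  lbl <- contaminant_label(spec)
  A <- spec$amplitude

  hhat <- vapply(seq_len(n_reps), function(r) {
    sx <- substream_seed(master_seed, estimator, lbl, H_true, n, A, r, "x")
    sc <- substream_seed(master_seed, estimator, lbl, H_true, n, A, r, "contam")
    se <- substream_seed(master_seed, estimator, lbl, H_true, n, A, r, "est")
    x <- simulate_fgn(H_true, n, sx)
    y <- if (is_stochastic_kind(spec$kind)) contaminate(x, spec, sc)
         else contaminate(x, spec)
    tryCatch(apply_estimator(estimator, y, se),
             error = function(e) NA_real_)
  }, numeric(1))

  est <- hhat[!is.na(hhat)]
  n_fail <- n_reps - length(est)
  failed <- n_fail > 0.1 * n_reps
  if (failed || length(est) < 2L) {
    m <- s <- lo <- hi <- NA_real_
  } else {
    m <- mean(est)
    s <- sd(est)
    if (ci == "normal") {
      half <- 1.96 * s / sqrt(length(est))
      lo <- m - half
      hi <- m + half
    } else {
      q <- unname(quantile(est, c(0.025, 0.975), type = 7))
      lo <- q[1L]
      hi <- q[2L]
    }
  }
  data.frame(estimator = estimator, contaminant = lbl, H_true = H_true,
             N = as.integer(n), A = A,
             tau = if (spec$kind == "cyclical") spec$tau else NA_real_,
             sign = if (spec$kind %in% c("linear", "quadratic")) spec$sign
                    else NA_real_,
             n_reps = n_reps, n_failures = as.integer(n_fail),
             mean_hhat = m, sd_hhat = s, ci_low = lo, ci_high = hi,
             stringsAsFactors = FALSE)
}

#' Build a benchmark configuration
#'
#' Collects and validates the axes of a Monte Carlo grid. Unknown arguments
#' and out-of-domain axis values are errors before any computation.
#'
#' @param H true Hurst exponents, each in (0, 1).
#' @param N series lengths, each >= 16.
#' @param A contamination amplitudes, each in \[0, 1\].
#' @param kinds contaminant kind labels; plain kinds (`"awgn"`, `"fgn"`,
#'   `"short_range"`, `"cyclical"`, `"linear"`, `"quadratic"`) use the
#'   config-level `tau`/`sign`, while suffixed labels
#'   (`"cyclical_365"`, `"cyclical_36500"`, `"linear_pos"`, `"linear_neg"`,
#'   `"quadratic_pos"`, `"quadratic_neg"`) pin the family parameter.
#' @param estimators subset of `c("HK", "DFA1", "DFA2")`.
#' @param n_reps replicates per cell (default 200; a full benchmark would
#'   use 1000).
#' @param master_seed integer master seed; the entire grid output is a pure
#'   function of the configuration including this seed.
#' @param tau,sign defaults for plain `"cyclical"` / trend kinds.
#' @param threshold decision-map accuracy threshold (default 0.1).
#' @param out optional default output CSV path for [run_grid()].
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(H, N, A, kinds, estimators = ESTIMATORS,
                       n_reps = 200L, master_seed, tau = 365, sign = 1,
                       threshold = 0.1, out = NULL) {
  H <- as.numeric(H)
  if (length(H) < 1L || any(!is.finite(H)) || any(H <= 0 | H >= 1))
    stop("config: H values must lie strictly inside (0, 1)", call. = FALSE)
  N <- as.numeric(N)
  if (length(N) < 1L || any(!is.finite(N)) || any(N < 16 | N != floor(N)))
    stop("config: N values must be integers >= 16", call. = FALSE)
  A <- as.numeric(A)
  if (length(A) < 1L || any(!is.finite(A)) || any(A < 0 | A > 1))
    stop("config: A values must lie in [0, 1]", call. = FALSE)
  kinds <- as.character(kinds)
  bad <- setdiff(kinds, KIND_LABELS)
  if (length(kinds) < 1L || length(bad) > 0L)
    stop(sprintf("config: unknown contaminant kind(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  estimators <- as.character(estimators)
  bad <- setdiff(estimators, ESTIMATORS)
  if (length(estimators) < 1L || length(bad) > 0L)
    stop(sprintf("config: unknown estimator(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (length(n_reps) != 1L || is.na(n_reps) || n_reps < 2)
    stop("config: n_reps must be >= 2", call. = FALSE)
  master_seed <- as_seed(master_seed)
  if (length(threshold) != 1L || !is.finite(threshold) || threshold <= 0)
    stop("config: threshold must be a positive number", call. = FALSE)
  structure(list(H = H, N = as.integer(N), A = A, kinds = kinds,
                 estimators = estimators, n_reps = as.integer(n_reps),
                 master_seed = master_seed, tau = as.numeric(tau),
                 sign = as.numeric(sign), threshold = as.numeric(threshold),
                 out = out),
            class = "run_config")
}

#' Read a benchmark configuration file
#'
#' Flat `key = value` text format: one key per line, `#` comments, axes as
#' comma-separated lists. Recognized keys: `H`, `N`, `A`, `kinds`,
#' `estimators`, `n_reps`, `master_seed`, `tau`, `sign`, `threshold`,
#' `out`. Unknown keys are an error before any computation.
#'
#' @param path configuration file.
#' @return An object of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  if (any(lengths(kv) != 2L))
    stop("config: every non-comment line must be 'key = value'", call. = FALSE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  known <- c("H", "N", "A", "kinds", "estimators", "n_reps", "master_seed",
             "tau", "sign", "threshold", "out")
  bad <- setdiff(keys, known)
  if (length(bad) > 0L)
    stop(sprintf("config: invalid key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(keys))
    stop("config: duplicated key", call. = FALSE)
  get_val <- function(k, default = NULL) {
    if (k %in% keys) vals[match(k, keys)] else default
  }
  num_list <- function(v) as.numeric(trimws(strsplit(v, ",")[[1L]]))
  chr_list <- function(v) trimws(strsplit(v, ",")[[1L]])
  for (k in c("H", "N", "A", "kinds", "master_seed"))
    if (!k %in% keys) stop(sprintf("config: missing key '%s'", k), call. = FALSE)
  run_config(H = num_list(get_val("H")),
             N = num_list(get_val("N")),
             A = num_list(get_val("A")),
             kinds = chr_list(get_val("kinds")),
             estimators = if (is.null(get_val("estimators"))) ESTIMATORS
                          else chr_list(get_val("estimators")),
             n_reps = if (is.null(get_val("n_reps"))) 200L
                      else as.numeric(get_val("n_reps")),
             master_seed = as.numeric(get_val("master_seed")),
             tau = if (is.null(get_val("tau"))) 365
                   else as.numeric(get_val("tau")),
             sign = if (is.null(get_val("sign"))) 1
                    else as.numeric(get_val("sign")),
             threshold = if (is.null(get_val("threshold"))) 0.1
                         else as.numeric(get_val("threshold")),
             out = get_val("out"))
}

#' Enumerate the cells of a configuration
#'
#' Expands the grid axes into one row per cell, in the canonical order used
#' by [run_grid()] (A varies fastest, then N, H, kind, estimator). Row
#' count is `|H| * |N| * |A| * |kinds| * |estimators|`.
#'
#' @param config a [run_config()].
#' @return data.frame with columns `estimator, kind, H, N, A`.
#' @export
expand_grid_cells <- function(config) {
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config object", call. = FALSE)
  g <- expand.grid(A = config$A, N = config$N, H = config$H,
                   kind = config$kinds, estimator = config$estimators,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("estimator", "kind", "H", "N", "A")]
}

#' Run a Monte Carlo benchmark grid
#'
#' Runs [run_cell()] for every cell of the configuration and returns (and
#' optionally writes) the stacked summary table. Because every cell seeds
#' itself from the master seed and its own identity, the output is a pure
#' function of the configuration, independent of execution order, and a
#' partially written output file can be resumed: cells already present in
#' `out` are skipped, and the completed table is rewritten in canonical
#' order.
#'
#' @param config a [run_config()] or path to a config file.
#' @param out output CSV path (default: the config's `out`, if any).
#' @param resume reuse rows already present in `out` (default TRUE).
#' @param verbose log one message per cell.
#' @return data.frame of cell summaries (columns as in [run_cell()]).
#' @export
run_grid <- function(config, out = NULL, resume = TRUE, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config"))
    stop("`config` must be a run_config object or a config file path",
         call. = FALSE)
  if (is.null(out)) out <- config$out
  cells <- expand_grid_cells(config)
  key_of <- function(d) paste(d$estimator, d$contaminant, sprintf("%.10g", d$H_true),
                              d$N, sprintf("%.10g", d$A), sep = "|")
  done <- NULL
  if (resume && !is.null(out) && file.exists(out)) {
    done <- read_results(out)
    done_keys <- key_of(done)
  } else {
    done_keys <- character(0)
  }

  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    spec <- kind_to_spec(cl$kind, cl$A, tau = config$tau, sign = config$sign)
    key <- paste(cl$estimator, contaminant_label(spec),
                 sprintf("%.10g", cl$H), cl$N, sprintf("%.10g", cl$A),
                 sep = "|")
    hit <- match(key, done_keys)
    if (!is.na(hit)) {
      rows[[i]] <- done[hit, , drop = FALSE]
      next
    }
    if (verbose)
      message(sprintf("[%d/%d] %s %s H=%g N=%d A=%g", i, nrow(cells),
                      cl$estimator, cl$kind, cl$H, cl$N, cl$A))
    rows[[i]] <- run_cell(cl$estimator, cl$H, cl$N, spec,
                          n_reps = config$n_reps,
                          master_seed = config$master_seed)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) write.csv(res, out, row.names = FALSE, quote = FALSE)
  res
}

#' Read a benchmark results CSV
#'
#' @param path CSV written by [run_grid()].
#' @return data.frame of cell summaries.
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Decision map: which estimator to use per condition
#'
#' For every (contaminant, H, N, A) cell, picks the estimator whose mean
#' estimate has the smallest absolute error `|mean_hhat - H_true|`,
#' provided that minimum does not exceed `threshold`; otherwise the verdict
#' is `"none"` (no method is acceptably accurate there). Exact ties break
#' in the order HK, DFA1, DFA2. Failed cells (`mean_hhat` missing) count as
#' infinitely wrong. All three estimators must be present for every cell.
#'
#' @param results data.frame from [run_grid()] (or [read_results()]).
#' @param threshold largest acceptable absolute error (default 0.1).
#' @return data.frame with columns `contaminant, H_true, N, A, best,
#'   min_abs_error`.
#' @export
decision_map <- function(results, threshold = 0.1) {
  need <- c("estimator", "contaminant", "H_true", "N", "A", "mean_hhat")
  if (!all(need %in% names(results)))
    stop("`results` must contain run_grid() columns", call. = FALSE)
  cell_id <- paste(results$contaminant, sprintf("%.10g", results$H_true),
                   results$N, sprintf("%.10g", results$A), sep = "|")
  out <- lapply(split(seq_len(nrow(results)), cell_id), function(idx) {
    sub <- results[idx, ]
    if (!setequal(sub$estimator, ESTIMATORS) || nrow(sub) != 3L)
      stop(sprintf(
        "incomplete cell (need HK, DFA1, DFA2): contaminant=%s H=%g N=%d A=%g",
        sub$contaminant[1L], sub$H_true[1L], sub$N[1L], sub$A[1L]),
        call. = FALSE)
    sub <- sub[match(ESTIMATORS, sub$estimator), ]  # tie-break order
    err <- abs(sub$mean_hhat - sub$H_true)
    err[is.na(err)] <- Inf
    best_i <- which.min(err)  # first minimum wins: HK > DFA1 > DFA2
    data.frame(contaminant = sub$contaminant[1L], H_true = sub$H_true[1L],
               N = sub$N[1L], A = sub$A[1L],
               best = if (err[best_i] <= threshold) ESTIMATORS[best_i]
                      else "none",
               min_abs_error = err[best_i], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$contaminant, res$H_true, res$N, res$A), ]
  rownames(res) <- NULL
  res
}
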