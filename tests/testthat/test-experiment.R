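demo_config <- function(...) {
  run_config(H = c(0.3, 0.8), N = 64, A = c(0, 1),
             kinds = c("awgn", "linear_pos"),
             estimators = c("HK", "DFA1", "DFA2"),
             n_reps = 5, master_seed = 42, ...)
}

test_that("substream seeds are stable, scalar and within set.seed range", {
  s1 <- substream_seed(42, "HK", "awgn", 0.8, 256, 0.5, 1, "x")
  s2 <- substream_seed(42, "HK", "awgn", 0.8, 256, 0.5, 1, "x")
  expect_identical(s1, s2)
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
  expect_false(substream_seed(42, "HK", "awgn", 0.8, 256, 0.5, 1, "x") ==
               substream_seed(42, "HK", "awgn", 0.8, 256, 0.5, 1, "contam"))
  expect_false(substream_seed(1, "a") == substream_seed(2, "a"))
})

test_that("run_cell is a pure function of its arguments", {
  spec <- contaminant_spec("awgn", 0.5)
  c1 <- run_cell("DFA1", 0.5, 64, spec, n_reps = 10, master_seed = 7)
  c2 <- run_cell("DFA1", 0.5, 64, spec, n_reps = 10, master_seed = 7)
  expect_identical(c1, c2)
  c3 <- run_cell("DFA1", 0.5, 64, spec, n_reps = 10, master_seed = 8)
  expect_false(identical(c1$mean_hhat, c3$mean_hhat))
  expect_true(c1$ci_low <= c1$mean_hhat && c1$mean_hhat <= c1$ci_high)
})

test_that("a zero-amplitude cell reproduces the uncontaminated replicates", {
  spec <- contaminant_spec("awgn", 0)
  cell <- run_cell("DFA1", 0.6, 128, spec, n_reps = 10, master_seed = 11)
  manual <- vapply(1:10, function(r) {
    sx <- substream_seed(11, "DFA1", "awgn", 0.6, 128, 0, r, "x")
    estimate_h_dfa(simulate_fgn(0.6, 128, sx))$h_hat
  }, numeric(1))
  expect_equal(cell$mean_hhat, mean(manual), tolerance = 1e-12)
  expect_equal(cell$sd_hhat, sd(manual), tolerance = 1e-12)
})

test_that("percentile intervals bracket the mean", {
  spec <- contaminant_spec("awgn", 0.3)
  cell <- run_cell("DFA2", 0.5, 64, spec, n_reps = 40, master_seed = 3,
                   ci = "percentile")
  expect_true(cell$ci_low <= cell$mean_hhat && cell$mean_hhat <= cell$ci_high)
})

test_that("HK cell recovers H = 0.8 at n = 256 without contamination", {
  cell <- run_cell("HK", 0.8, 256, contaminant_spec("awgn", 0),
                   n_reps = 100, master_seed = 1)
  expect_identical(cell$n_failures, 0L)
  expect_lt(abs(cell$mean_hhat - 0.8), 0.05)
})

test_that("configs validate axes before any computation", {
  expect_error(run_config(H = 1.2, N = 64, A = 0, kinds = "awgn",
                          master_seed = 1), "inside \\(0, 1\\)")
  expect_error(run_config(H = 0.5, N = 8, A = 0, kinds = "awgn",
                          master_seed = 1), ">= 16")
  expect_error(run_config(H = 0.5, N = 64, A = 2, kinds = "awgn",
                          master_seed = 1), "\\[0, 1\\]")
  expect_error(run_config(H = 0.5, N = 64, A = 0, kinds = "ramp",
                          master_seed = 1), "unknown contaminant")
  expect_error(run_config(H = 0.5, N = 64, A = 0, kinds = "awgn",
                          estimators = "MLE", master_seed = 1),
               "unknown estimator")
})

test_that("grid expansion enumerates |H|x|N|x|A|x|kinds|x|estimators| cells", {
  one <- run_config(H = 0.5, N = 64, A = 0, kinds = "awgn",
                    estimators = "HK", n_reps = 2, master_seed = 1)
  expect_identical(nrow(expand_grid_cells(one)), 1L)
  full <- run_config(H = seq(0.1, 0.9, 0.1), N = c(32, 64, 128, 256, 512, 1024),
                     A = seq(0, 1, 0.1), kinds = "awgn",
                     estimators = c("HK", "DFA1", "DFA2"),
                     n_reps = 1000, master_seed = 1)
  expect_identical(nrow(expand_grid_cells(full)), 1782L)
})

test_that("config files round-trip through the flat key=value format", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "H = 0.3,0.8", "N = 64", "A = 0,1",
               "kinds = awgn,linear_pos", "estimators = HK,DFA1,DFA2",
               "n_reps = 5", "master_seed = 42"), path)
  cfg <- read_run_config(path)
  expect_identical(cfg$H, c(0.3, 0.8))
  expect_identical(cfg$kinds, c("awgn", "linear_pos"))
  expect_identical(cfg$n_reps, 5L)
  writeLines(c("H = 0.5", "N = 64", "A = 0", "kinds = awgn",
               "master_seed = 1", "reps = 10"), path)
  expect_error(read_run_config(path), "invalid key")
})

test_that("the demo grid runs, writes CSV, and resumes by skipping", {
  cfg <- demo_config()
  out <- tempfile(fileext = ".csv")
  res <- run_grid(cfg, out = out)
  expect_identical(nrow(res), 24L)
  expect_identical(names(res),
                   c("estimator", "contaminant", "H_true", "N", "A", "tau",
                     "sign", "n_reps", "n_failures", "mean_hhat", "sd_hhat",
                     "ci_low", "ci_high"))
  back <- read_results(out)
  expect_equal(back$mean_hhat, res$mean_hhat, tolerance = 1e-12)
  # resume: rows already on disk are reused verbatim
  t_res <- system.time(res2 <- run_grid(cfg, out = out, resume = TRUE))
  expect_equal(res2$mean_hhat, res$mean_hhat, tolerance = 1e-12)
  expect_lt(t_res["elapsed"], 5)
})

test_that("decision map picks the most accurate admissible estimator", {
  row <- function(est, H, err) {
    data.frame(estimator = est, contaminant = "awgn", H_true = H, N = 64L,
               A = 0.5, tau = NA_real_, sign = NA_real_, n_reps = 10L,
               n_failures = 0L, mean_hhat = H + err, sd_hhat = 0.1,
               ci_low = H + err - 0.1, ci_high = H + err + 0.1,
               stringsAsFactors = FALSE)
  }
  tbl <- rbind(row("HK", 0.5, 0.05), row("DFA1", 0.5, 0.2),
               row("DFA2", 0.5, 0.3))
  dm <- decision_map(tbl)
  expect_identical(dm$best, "HK")
  expect_equal(dm$min_abs_error, 0.05)

  tbl <- rbind(row("HK", 0.5, 0.2), row("DFA1", 0.5, -0.15),
               row("DFA2", 0.5, 0.3))
  expect_identical(decision_map(tbl)$best, "none")

  tbl <- rbind(row("HK", 0.5, 0.08), row("DFA1", 0.5, 0.08),
               row("DFA2", 0.5, 0.2))
  expect_identical(decision_map(tbl)$best, "HK")  # tie-break HK > DFA1 > DFA2

  tbl <- rbind(row("HK", 0.5, 0.05), row("DFA1", 0.5, 0.2))
  expect_error(decision_map(tbl), "incomplete cell")
})

test_that("failed replicates are excluded and reported", {
  # a constant series makes the HK estimator error; forcing failures via a
  # tiny proposal budget is awkward here, so check the bookkeeping columns
  # on a healthy cell instead and the failure policy downstream via NA
  cell <- run_cell("DFA1", 0.4, 64, contaminant_spec("awgn", 0.2),
                   n_reps = 5, master_seed = 2)
  expect_identical(cell$n_failures, 0L)
  tbl <- rbind(
    data.frame(estimator = "HK", contaminant = "awgn", H_true = 0.5, N = 64L,
               A = 0.5, tau = NA_real_, sign = NA_real_, n_reps = 10L,
               n_failures = 5L, mean_hhat = NA_real_, sd_hhat = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_),
    data.frame(estimator = "DFA1", contaminant = "awgn", H_true = 0.5, N = 64L,
               A = 0.5, tau = NA_real_, sign = NA_real_, n_reps = 10L,
               n_failures = 0L, mean_hhat = 0.55, sd_hhat = 0.1,
               ci_low = 0.45, ci_high = 0.65),
    data.frame(estimator = "DFA2", contaminant = "awgn", H_true = 0.5, N = 64L,
               A = 0.5, tau = NA_real_, sign = NA_real_, n_reps = 10L,
               n_failures = 0L, mean_hhat = 0.7, sd_hhat = 0.1,
               ci_low = 0.6, ci_high = 0.8))
  dm <- decision_map(tbl)
  expect_identical(dm$best, "DFA1")  # the failed HK cell counts as worst
})
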