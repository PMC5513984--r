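# Adaptive staircase engine and simulated musician observer.

test_that("observer maps misalignment onto response categories", {
  m <- simulated_musician(true_p = 0.500, window_ms = 10, lapse = 0)
  # a presented P-value inside the acceptance window sounds good
  expect_equal(respond(m, 0.505), "good")
  expect_equal(respond(m, 0.495), "good")
  # below the window the syllable lags its grid slot -> "delayed",
  # which the schedule answers by increasing the P-value
  expect_equal(respond(m, 0.470), "delayed")
  # above the window the syllable precedes its slot -> "early"
  expect_equal(respond(m, 0.530), "early")
  expect_error(simulated_musician(0.5, window_ms = -1), "window")
  expect_error(simulated_musician(0.5, lapse = 0.5), "lapse")
})

test_that("runs are monotone single-step sequences and borders bracket", {
  cfg <- staircase_config()
  m <- simulated_musician(0.500, window_ms = 10, lapse = 0, seed = 2)
  st <- run_stage(0.450, 1000, m, cfg)
  lg <- st$log
  step_s <- 1000 / cfg$rate
  for (r in unique(lg$run)) {
    p <- lg$presented_s[lg$run == r]
    if (length(p) > 1) {
      d <- diff(p)
      expect_true(all(abs(abs(d) - step_s) < 1e-12))
      expect_true(all(d > 0) || all(d < 0))   # one direction per run
    }
  }
  expect_equal(max(lg$run), cfg$n_runs)
  expect_gte(max(st$borders), 0.500 - 0.010 - step_s)
  expect_lte(min(st$borders), 0.500 + 0.010 + step_s)
  expect_gte(st$estimate, min(lg$presented_s))
  expect_lte(st$estimate, max(lg$presented_s))
  expect_error(run_stage(0.45, 0, m, cfg), "positive")
})

test_that("the step sizes have their conventional millisecond values", {
  cfg <- staircase_config()
  expect_equal(round(1000 * cfg$coarse_step / cfg$rate, 1), 22.7)
  expect_equal(round(1000 * cfg$fine_step / cfg$rate, 2), 11.34)
})

test_that("non-convergence hits the trial cap", {
  cfg <- staircase_config(max_trials = 20)
  m <- simulated_musician(10, window_ms = 5, lapse = 0)
  expect_error(run_stage(0.5, 1000, m, cfg), "converge")
})

test_that("noiseless estimation error is within one fine step", {
  tok <- fixture_token()
  cfg <- staircase_config()
  errs <- vapply(1:100, function(s) {
    m <- simulated_musician(tok$p1, window_ms = 10, lapse = 0, seed = s)
    abs(estimate_pcenter(tok, 1, m, cfg)$estimate - tok$p1)
  }, numeric(1))
  expect_lte(max(errs), cfg$fine_step / cfg$rate + 1e-12)
})

test_that("zero-window limit stays within one fine step", {
  tok <- fixture_token()
  cfg <- staircase_config()
  for (s in 1:10) {
    m <- simulated_musician(tok$p2, window_ms = 0, lapse = 0, seed = s)
    est <- estimate_pcenter(tok, 2, m, cfg)$estimate
    expect_lte(abs(est - tok$p2), cfg$fine_step / cfg$rate + 1e-12)
  }
})

test_that("estimation accuracy is insensitive to the acceptance window", {
  # the border average cancels the window half-width, so the error is
  # dominated by step-grid quantization: shrinking the window leaves the
  # mean absolute error flat (and always well under one fine step) rather
  # than strictly improving it
  tok <- fixture_token()
  cfg <- staircase_config()
  fine_s <- cfg$fine_step / cfg$rate
  mean_err <- vapply(c(30, 15, 5), function(w) {
    mean(vapply(1:40, function(s) {
      m <- simulated_musician(tok$p1, window_ms = w, lapse = 0, seed = s)
      abs(estimate_pcenter(tok, 1, m, cfg)$estimate - tok$p1)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(mean_err <= fine_s / 2))
})

test_that("trial logs export as CSV with the expected schema", {
  tok <- fixture_token()
  res <- estimate_pcenter(tok, 1, simulated_musician(tok$p1, 10, seed = 3))
  f <- tempfile(fileext = ".csv")
  export_trial_log(res, f)
  lg <- read.csv(f)
  expect_true(all(c("trial", "presented_s", "presented_samples",
                    "response", "run", "stage") %in% names(lg)))
  expect_equal(nrow(lg), nrow(res$log))
  unlink(f)
})
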