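# Two-stage adaptive staircase for P-center estimation, exercised against a
# simulated musician observer.
#
# The observer judges, for a word aligned to an isochronous beat grid by the
# current P-value, whether the target syllable sounds delayed, too early, or
# good. A P-value placed *before* the true P-center makes the syllable lag
# the grid slot it is aligned to, so the "delayed" judgement calls for an
# *increase* of the P-value; symmetrically "too early" calls for a decrease.
# The engine operates on timeline arithmetic only — audible rendering is not
# required for estimation.

#' Staircase configuration
#'
#' @param rate sampling rate in samples/s used to convert step sizes.
#' @param coarse_step stage-1 step in samples (1,000 samples = 22.7 ms).
#' @param fine_step stage-2 step in samples (500 samples = 11.3 ms; note
#'   500/44,100 is 11.34 ms by exact arithmetic).
#' @param n_runs runs per stage (a run is a maximal sequence of
#'   same-direction steps); the schedule repeats twice, i.e. 4 runs.
#' @param reversal_criterion consecutive opposite-category responses that
#'   terminate a run.
#' @param max_trials per-stage trial cap guarding against oscillation.
#' @param init_offset_ms half-width of the seeded uniform offset emulating
#'   the coarse visual first estimate.
#' @return a `wrrc_staircase_config` list.
#' @export
staircase_config <- function(rate = 44100, coarse_step = 1000,
                             fine_step = 500, n_runs = 4,
                             reversal_criterion = 2, max_trials = 200,
                             init_offset_ms = 60) {
  if (fine_step <= 0 || coarse_step <= 0 || fine_step >= coarse_step)
    stop("need 0 < fine_step < coarse_step", call. = FALSE)
  structure(list(rate = rate, coarse_step = coarse_step,
                 fine_step = fine_step, n_runs = n_runs,
                 reversal_criterion = reversal_criterion,
                 max_trials = max_trials, init_offset_ms = init_offset_ms),
            class = "wrrc_staircase_config")
}

#' Simulated musician observer
#'
#' A stand-in for the professional musicians who judged beat-word alignment:
#' responds "good" whenever the presented P-value is within `window_ms` of
#' the true P-center, otherwise reports the direction of misalignment; with
#' probability `lapse` the response is replaced by a uniformly random one.
#'
#' @param true_p true P-center time in seconds.
#' @param window_ms half-width of the acceptance ("it sounds good") region.
#' @param lapse random-response probability in \[0, 0.2\].
#' @param seed integer seed for lapses and quasi-random direction choices.
#' @return a `wrrc_musician` object.
#' @export
simulated_musician <- function(true_p, window_ms = 10, lapse = 0,
                               seed = 1L) {
  if (window_ms < 0) stop("`window_ms` must be >= 0", call. = FALSE)
  if (lapse < 0 || lapse > 0.2)
    stop("`lapse` must lie in [0, 0.2]", call. = FALSE)
  structure(list(true_p = true_p, window_ms = window_ms, lapse = lapse,
                 seed = seed, rng = local_rng(seed)),
            class = "wrrc_musician")
}

#' Observer response to one presentation
#'
#' @param musician a [simulated_musician()].
#' @param presented_p presented P-value in seconds.
#' @return one of `"early"`, `"delayed"`, `"good"`. A presented value below
#'   `true_p` means the syllable lags its grid slot and is judged
#'   `"delayed"`; above, `"early"`.
#' @export
respond <- function(musician, presented_p) {
  w <- musician$window_ms / 1000
  ans <- if (presented_p < musician$true_p - w) "delayed"
         else if (presented_p > musician$true_p + w) "early"
         else "good"
  if (musician$lapse > 0 && musician$rng$runif(1) < musician$lapse)
    ans <- c("early", "delayed", "good")[musician$rng$sample_int(3L, 1L)]
  ans
}

# Direction implied by a response: "delayed" -> increase the P-value,
# "early" -> decrease, "good" -> seeded quasi-random choice.
response_direction <- function(response, musician) {
  switch(response,
         delayed = 1L,
         early = -1L,
         good = if (musician$rng$runif(1) < 0.5) 1L else -1L)
}

#' Run one staircase stage
#'
#' Executes the direction-reversal schedule: step in the direction implied
#' by the first response until the opposite-category response occurs for
#' `reversal_criterion` consecutive presentations, then reverse; a maximal
#' same-direction sequence is one run, and the stage ends after `n_runs`
#' runs. Each run's border value is the last presented value before the
#' terminal opposite-response streak — the observed edge of the "good"
#' region. The stage estimate averages the border values of the final two
#' runs.
#'
#' @param start_p starting P-value in seconds.
#' @param step step size in samples.
#' @param musician a [simulated_musician()].
#' @param config a [staircase_config()].
#' @return list with `borders` (final two runs' border values, seconds),
#'   `estimate` (their mean) and `log` (data.frame: trial, presented_s,
#'   presented_samples, response, run, direction).
#' @export
run_stage <- function(start_p, step, musician, config = staircase_config()) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  step_s <- step / config$rate
  p <- start_p
  run <- 1L
  dir <- 0L                 # unset until first response
  opp_streak <- 0L
  run_border <- rep(NA_real_, config$n_runs)
  log_p <- numeric(0); log_r <- character(0)
  log_run <- integer(0); log_dir <- integer(0)

  for (trial in seq_len(config$max_trials)) {
    r <- respond(musician, p)
    if (dir == 0L) dir <- response_direction(r, musician)
    log_p <- c(log_p, p); log_r <- c(log_r, r)
    log_run <- c(log_run, run); log_dir <- c(log_dir, dir)

    opposite <- (dir == 1L && r == "early") || (dir == -1L && r == "delayed")
    if (opposite) {
      opp_streak <- opp_streak + 1L
    } else {
      opp_streak <- 0L
      run_border[run] <- p
    }
    if (opp_streak >= config$reversal_criterion) {
      if (run == config$n_runs) break
      run <- run + 1L
      dir <- -dir
      opp_streak <- 0L
      # provisional border at the reversal point, overwritten by the run's
      # own non-opposite responses (relevant only under lapses)
      run_border[run] <- p
    }
    p <- p + dir * step_s
  }
  if (run < config$n_runs || opp_streak < config$reversal_criterion)
    stop("staircase failed to converge within the trial cap", call. = FALSE)

  borders <- run_border[c(config$n_runs - 1L, config$n_runs)]
  list(borders = borders, estimate = mean(borders),
       log = data.frame(trial = seq_along(log_p), presented_s = log_p,
                        presented_samples = round(log_p * config$rate),
                        response = log_r, run = log_run, direction = log_dir,
                        stringsAsFactors = FALSE))
}

#' Two-stage P-center estimate for one syllable of a word token
#'
#' Stage 1 steps coarsely (1,000 samples) from an initial estimate emulating
#' visual inspection of the envelope (true P-center plus a seeded uniform
#' offset within ±`init_offset_ms`); the average of its final border pair
#' seeds stage 2, which repeats the schedule with the fine step (500
#' samples). The final estimate is the stage-2 border average.
#'
#' @param word a `wrrc_word_token`.
#' @param syllable which P-center to estimate, 1 or 2.
#' @param musician a [simulated_musician()] whose `true_p` should be the
#'   token's corresponding ground truth (see [simulated_musician()]).
#' @param config a [staircase_config()].
#' @return list of class `wrrc_staircase_result`: `estimate` (s), `true_p`,
#'   `stage_borders` (2 x 2), `log` (combined trial log with a `stage`
#'   column).
#' @export
estimate_pcenter <- function(word, syllable,
                             musician = simulated_musician(
                               if (syllable == 1L) word$p1 else word$p2),
                             config = staircase_config()) {
  stopifnot(inherits(word, "wrrc_word_token"), syllable %in% c(1L, 2L))
  start <- musician$true_p +
    musician$rng$runif(1, -config$init_offset_ms, config$init_offset_ms) / 1000
  s1 <- run_stage(start, config$coarse_step, musician, config)
  s2 <- run_stage(s1$estimate, config$fine_step, musician, config)
  s1$log$stage <- 1L
  s2$log$stage <- 2L
  lg <- rbind(s1$log, s2$log)
  lg$trial <- seq_len(nrow(lg))
  structure(list(estimate = s2$estimate, true_p = musician$true_p,
                 stage_borders = rbind(stage1 = s1$borders,
                                       stage2 = s2$borders),
                 log = lg),
            class = "wrrc_staircase_result")
}

#' @export
print.wrrc_staircase_result <- function(x, ...) {
  cat(sprintf(
    "<wrrc_staircase_result> estimate %.4f s (true %.4f s, error %+.2f ms, %d trials)\n",
    x$estimate, x$true_p, 1000 * (x$estimate - x$true_p), nrow(x$log)))
  invisible(x)
}

#' Export a staircase trial log as CSV
#'
#' @param result a `wrrc_staircase_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trial_log <- function(result, path) {
  stopifnot(inherits(result, "wrrc_staircase_result"))
  utils::write.csv(result$log, path, row.names = FALSE)
  invisible(path)
}
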