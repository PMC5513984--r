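# Synthetic stimulus materials: beat tones, bisyllabic word tokens with
# ground-truth P-centers, and multitalker-babble emulation.

#' Synthesize a beat tone
#'
#' The priming beat is a brief pure tone, by default 15 ms at 1,000 Hz, with
#' 2 ms raised-cosine onset/offset ramps to avoid clicks. The beat's nominal
#' time in a timeline is its onset sample.
#'
#' @param duration_ms tone duration in milliseconds (> 0).
#' @param freq_hz tone frequency in Hz (must be below Nyquist).
#' @param rate sampling rate in samples/s.
#' @param peak peak amplitude after ramping.
#' @param ramp_ms raised-cosine ramp duration at each end.
#' @return a `wrrc_audio` buffer of `round(duration_ms/1000 * rate)` samples.
#' @export
synth_beat <- function(duration_ms = 15, freq_hz = 1000, rate = 44100,
                       peak = 0.9, ramp_ms = 2) {
  if (!is.numeric(duration_ms) || duration_ms <= 0)
    stop("`duration_ms` must be positive", call. = FALSE)
  if (!is.numeric(freq_hz) || freq_hz <= 0 || freq_hz >= rate / 2)
    stop("`freq_hz` must be positive and below Nyquist (rate/2)",
         call. = FALSE)
  n <- round(duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1L) / rate
  s <- sin(2 * pi * freq_hz * t)
  nr <- min(round(ramp_ms / 1000 * rate), floor(n / 2))
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    s[seq_len(nr)] <- s[seq_len(nr)] * ramp
    s[n + 1L - seq_len(nr)] <- s[n + 1L - seq_len(nr)] * ramp
  }
  audio_buffer(peak * s / max(abs(s)), rate = rate)
}

# Asymmetric raised-cosine burst envelope with compact support: a fast
# cosine rise over `rise` of the duration, then a slower cosine fall.  The
# envelope crosses 50% of its peak exactly halfway up the rise, which is the
# landmark used to operationalize the P-center of a synthetic syllable.
syllable_envelope <- function(dur_s, rate, rise = 0.3) {
  n <- round(dur_s * rate)
  tr <- max(2L, round(rise * n))
  tf <- n - tr
  env <- numeric(n)
  i <- seq_len(tr)
  env[i] <- 0.5 * (1 - cos(pi * i / tr))
  j <- seq_len(tf)
  env[tr + j] <- 0.5 * (1 + cos(pi * j / tf))
  env
}

# Harmonic vowel-like carrier with seeded f0 and phases, peak-normalized.
vowel_carrier <- function(n, rate, f0, phases, n_harm = 8) {
  t <- (seq_len(n) - 1L) / rate
  s <- numeric(n)
  for (h in seq_len(n_harm)) {
    if (h * f0 >= rate / 2) break
    s <- s + sin(2 * pi * h * f0 * t + phases[h]) / h
  }
  s / max(abs(s))
}

# First sample index (1-based) at which `env` reaches 50% of the peak at
# `peak_idx`, scanning left from the peak.
rise_landmark <- function(env, peak_idx) {
  half <- 0.5 * env[peak_idx]
  i <- peak_idx
  while (i > 1L && env[i - 1L] >= half) i <- i - 1L
  i
}

#' Synthesize a bisyllabic word token with known P-centers
#'
#' Emulates a spoken bisyllabic word as two vowel-like syllable bursts under
#' rise-fall envelopes. The P-center of each syllable is operationalized as
#' the time its amplitude envelope first reaches 50% of the syllable's peak,
#' measured on the rendered sample grid, so the ground truth stored in the
#' token is exact by construction. The stressed syllable is 4 dB higher in
#' peak amplitude and 1.3 times longer.
#'
#' @param ipi_s inter-P-center interval in seconds; must lie in the observed
#'   word-material range \[0.224, 0.434\].
#' @param stress stressed syllable index, 1 or 2.
#' @param seed integer seed governing f0, phases and micro-variation.
#' @param rate sampling rate in samples/s.
#' @param word_id token label.
#' @param base_dur_s base (unstressed) syllable duration in seconds.
#' @param base_peak base (unstressed) syllable peak amplitude.
#' @return an object of class `wrrc_word_token`: fields `audio`
#'   (`wrrc_audio`), `envelope` (composite amplitude envelope, same length),
#'   `p1`, `p2` (P-center times in seconds from token start), `ipi`,
#'   `stress`, `word_id`.
#' @export
synth_word_token <- function(ipi_s, stress, seed = 1L, rate = 44100,
                             word_id = sprintf("w_%03d", seed %% 1000L),
                             base_dur_s = 0.18, base_peak = 0.45) {
  if (!is.numeric(ipi_s) || length(ipi_s) != 1L ||
      ipi_s < 0.224 || ipi_s > 0.434)
    stop("`ipi_s` must lie in [0.224, 0.434] seconds", call. = FALSE)
  if (!stress %in% c(1L, 2L))
    stop("`stress` must be 1 or 2", call. = FALSE)

  rng <- local_rng(seed)
  f0 <- rng$runif(1, 200, 255)
  phases1 <- rng$runif(8, 0, 2 * pi)
  phases2 <- rng$runif(8, 0, 2 * pi)

  stress_gain <- 10^(4 / 20)
  dur1 <- base_dur_s * if (stress == 1L) 1.3 else 1
  dur2 <- base_dur_s * if (stress == 2L) 1.3 else 1
  pk1 <- base_peak * if (stress == 1L) stress_gain else 1
  pk2 <- base_peak * if (stress == 2L) stress_gain else 1

  env1 <- syllable_envelope(dur1, rate) * pk1
  env2 <- syllable_envelope(dur2, rate) * pk2
  l1 <- rise_landmark(env1, which.max(env1))
  l2 <- rise_landmark(env2, which.max(env2))

  lead <- round(0.05 * rate)
  start1 <- lead + 1L
  # place burst 2 so the landmark separation is exactly round(ipi * rate)
  start2 <- start1 + (l1 - 1L) + round(ipi_s * rate) - (l2 - 1L)
  tail <- round(0.04 * rate)
  n <- start2 + length(env2) - 1L + tail

  env <- numeric(n)
  env[start1:(start1 + length(env1) - 1L)] <- env1
  idx2 <- start2:(start2 + length(env2) - 1L)
  env[idx2] <- env[idx2] + env2

  sig <- numeric(n)
  c1 <- vowel_carrier(length(env1), rate, f0, phases1)
  c2 <- vowel_carrier(length(env2), rate, f0 * rng$runif(1, 0.92, 1.08),
                      phases2)
  sig[start1:(start1 + length(env1) - 1L)] <- c1 * env1
  sig[idx2] <- sig[idx2] + c2 * env2
  sig <- pmax(-1, pmin(1, sig))

  p1 <- (start1 + l1 - 2L) / rate     # 0-based sample time of landmark
  p2 <- (start2 + l2 - 2L) / rate
  stopifnot(abs((p2 - p1) - ipi_s) <= 1 / rate)

  structure(list(audio = audio_buffer(sig, rate), envelope = env,
                 p1 = p1, p2 = p2, ipi = p2 - p1,
                 stress = as.integer(stress), word_id = word_id),
            class = "wrrc_word_token")
}

#' @export
print.wrrc_word_token <- function(x, ...) {
  cat(sprintf(
    "<wrrc_word_token> %s: p1 = %.4f s, p2 = %.4f s (IPI %.1f ms), stress %d\n",
    x$word_id, x$p1, x$p2, 1000 * x$ipi, x$stress))
  invisible(x)
}

#' Re-measure the P-centers of a rendered word token
#'
#' Locates the two peaks of the token's amplitude envelope (split at the
#' inter-syllable minimum) and returns, for each, the time the envelope first
#' reaches 50% of that peak — the same landmark used at synthesis, so
#' recovery is exact by construction.
#'
#' @param token a `wrrc_word_token`.
#' @return numeric vector `c(p1, p2)` in seconds.
#' @export
measure_pcenters <- function(token) {
  stopifnot(inherits(token, "wrrc_word_token"))
  env <- token$envelope
  rate <- token$audio$rate
  pk1 <- which.max(env)
  # search for the second peak outside the first burst's neighborhood
  guard <- round(0.08 * rate)
  mask <- env
  mask[max(1L, pk1 - guard):min(length(env), pk1 + guard)] <- -Inf
  pk2 <- which.max(mask)
  pks <- sort(c(pk1, pk2))
  (c(rise_landmark(env, pks[1]), rise_landmark(env, pks[2])) - 1L) / rate
}

#' Generate a 16-word list with the experiment's stress ratio
#'
#' Draws inter-P-center intervals from a truncated normal distribution
#' (rejection sampling) matching the word material's observed statistics —
#' mean 329 ms, SD 55 ms, truncated to \[224, 434\] ms — and assigns exactly
#' `n_stress1` first-syllable-stressed tokens, order shuffled by `seed`.
#'
#' @param n_words number of tokens (default 16).
#' @param n_stress1 number of first-syllable-stressed tokens (default 11,
#'   i.e. 68.75%).
#' @param ipi_mean_s,ipi_sd_s truncated-normal location/scale in seconds.
#' @param ipi_bounds truncation bounds in seconds.
#' @param seed integer seed governing the whole list.
#' @param list_id list label.
#' @param rate sampling rate passed to [synth_word_token()].
#' @return an object of class `wrrc_word_list`: list with `tokens` (list of
#'   `wrrc_word_token`) and `list_id`.
#' @export
make_word_list <- function(n_words = 16, n_stress1 = 11,
                           ipi_mean_s = 0.329, ipi_sd_s = 0.055,
                           ipi_bounds = c(0.224, 0.434),
                           seed = 1L, list_id = "list1", rate = 44100) {
  if (n_stress1 > n_words)
    stop("`n_stress1` cannot exceed `n_words`", call. = FALSE)
  rng <- local_rng(seed)
  ipis <- numeric(n_words)
  k <- 0L
  while (k < n_words) {
    x <- rng$rnorm(1, ipi_mean_s, ipi_sd_s)
    if (x >= ipi_bounds[1] && x <= ipi_bounds[2]) {
      k <- k + 1L
      ipis[k] <- x
    }
  }
  stresses <- rng$sample(c(rep(1L, n_stress1), rep(2L, n_words - n_stress1)))
  token_seeds <- rng$sample_int(2^30, n_words)
  tokens <- vector("list", n_words)
  for (i in seq_len(n_words)) {
    tokens[[i]] <- synth_word_token(
      ipis[i], stresses[i], seed = token_seeds[i], rate = rate,
      word_id = sprintf("%s_w%02d", list_id, i))
  }
  structure(list(tokens = tokens, list_id = list_id),
            class = "wrrc_word_list")
}

#' @export
print.wrrc_word_list <- function(x, ...) {
  st <- vapply(x$tokens, `[[`, integer(1), "stress")
  cat(sprintf("<wrrc_word_list> %s: %d tokens (%d stress-1, %d stress-2)\n",
              x$list_id, length(x$tokens), sum(st == 1L), sum(st == 2L)))
  invisible(x)
}

# FFT brick-wall bandpass; returns a real signal with energy restricted to
# [f_lo, f_hi] Hz.
fft_bandpass <- function(x, rate, f_lo, f_hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)                       # fold to [0, rate/2]
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Synthesize a multitalker-babble stand-in
#'
#' Emulates cafeteria babble as the sum of `n_streams` independent
#' amplitude-modulated speech-band (100–8,000 Hz) noise streams, each
#' modulated at syllabic rates (2–8 Hz). The summed track is normalized so
#' its overall RMS equals `plateau_rms`; averaging across streams makes the
#' track approximately stationary (250 ms-window RMS within about 20% of
#' the plateau value).
#'
#' @param duration_s track duration in seconds (> 0).
#' @param n_streams number of independent talker streams (>= 2).
#' @param seed integer seed.
#' @param rate sampling rate in samples/s.
#' @param plateau_rms target RMS of the normalized track.
#' @param mod_depth modulation depth of each stream's syllabic envelope.
#' @return an object of class `wrrc_babble`: `audio` (`wrrc_audio`) and
#'   `plateau_rms`.
#' @export
synth_babble <- function(duration_s, n_streams = 8, seed = 1L, rate = 44100,
                         plateau_rms = 0.05, mod_depth = 0.5) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive", call. = FALSE)
  if (n_streams < 2) stop("`n_streams` must be >= 2", call. = FALSE)
  rng <- local_rng(seed)
  n <- round(duration_s * rate)
  mix <- numeric(n)
  for (k in seq_len(n_streams)) {
    carrier <- fft_bandpass(rng$rnorm(n), rate, 100, min(8000, rate / 2 - 1))
    m <- fft_bandpass(rng$rnorm(n), rate, 2, 8)
    m <- m / stats::sd(m)
    envl <- pmax(0, 1 + mod_depth * m)
    mix <- mix + carrier * envl
  }
  mix <- mix * (plateau_rms / sqrt(mean(mix^2)))
  mix <- pmax(-1, pmin(1, mix))
  structure(list(audio = audio_buffer(mix, rate), plateau_rms = plateau_rms),
            class = "wrrc_babble")
}

#' @export
print.wrrc_babble <- function(x, ...) {
  cat(sprintf("<wrrc_babble> %.2f s @ %g Hz, plateau RMS %.4f\n",
              audio_duration(x$audio), x$audio$rate, x$plateau_rms))
  invisible(x)
}
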