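# Per-trial stimulus timelines for the three conditions.
#
# Every trial is a 4-beat priming sequence followed by a word in babble,
# aligned on the word's P-centers. Conditions differ only in how the four
# intervals (3 inter-beat + last-beat-to-first-P-center) are arranged;
# their total is always 4 * IPI, so condition never changes the stimulus
# duration.

# Sign patterns of the six interval-distortion types used in the
# non-rhythm condition: each row has two shortened (-) and two lengthened
# (+) intervals, so the total of the four intervals is preserved.
NR_SIGNS <- matrix(c(-1, -1, +1, +1,
                     -1, +1, -1, +1,
                     -1, +1, +1, -1,
                     +1, -1, -1, +1,
                     +1, -1, +1, -1,
                     +1, +1, -1, -1),
                   nrow = 6, byrow = TRUE,
                   dimnames = list(LETTERS[1:6], NULL))

#' Condition specification
#'
#' @param condition `"RH"` (rhythmic, synchronized), `"NR"` (non-rhythm:
#'   intervals distorted ±30%), or `"UnSc"` (isochronous beats 10% faster
#'   than the word rhythm).
#' @param nr_type distortion type `"A"`–`"F"`, required iff `condition`
#'   is `"NR"`.
#' @param unsc_factor inter-beat-interval multiplier for `"UnSc"`.
#' @param distortion fractional interval distortion for `"NR"`.
#' @return a `wrrc_condition_spec` list.
#' @export
condition_spec <- function(condition = c("RH", "NR", "UnSc"), nr_type = NULL,
                           unsc_factor = 0.9, distortion = 0.30) {
  condition <- match.arg(condition)
  if (condition == "NR") {
    if (is.null(nr_type) || !nr_type %in% LETTERS[1:6])
      stop("NR condition requires `nr_type` in A..F", call. = FALSE)
  } else if (!is.null(nr_type)) {
    stop("`nr_type` is only meaningful for the NR condition", call. = FALSE)
  }
  structure(list(condition = condition, nr_type = nr_type,
                 unsc_factor = unsc_factor, distortion = distortion),
            class = "wrrc_condition_spec")
}

#' Ordinal distortion-type assignment
#'
#' Non-rhythm trials take distortion types in presentation order, cycling
#' A, B, C, D, E, F, A, ...
#'
#' @param nr_trial_index 0-based index of the NR presentation.
#' @return a type letter `"A"`–`"F"`.
#' @export
assign_nr_type <- function(nr_trial_index) {
  if (any(nr_trial_index < 0)) stop("index must be >= 0", call. = FALSE)
  LETTERS[(as.integer(nr_trial_index) %% 6L) + 1L]
}

#' Build the event timeline of one trial
#'
#' Time zero is the first beat's onset. The word is fixed with its first
#' P-center at 4 IPI (and so its second at 5 IPI); conditions rearrange the
#' beats only:
#' \itemize{
#'   \item RH: beats at 0, 1, 2, 3 IPI — beats and P-centers form one
#'     isochronous pulse.
#'   \item NR: the four intervals are IPI(1 ± 0.30) with signs given by the
#'     distortion type; two + and two − per type keep the total at 4 IPI.
#'   \item UnSc: beats at 0, 0.9, 1.8, 2.7 IPI — isochronous but 10% fast,
#'     leaving a 1.3 IPI gap to the first P-center; the extrapolated grid
#'     misses both P-centers.
#' }
#' Babble starts 1.5 IPI before the first P-center, fades in linearly over
#' 1 IPI (ramp ends 0.5 IPI before it), stays constant, and stops abruptly
#' `babble_tail_s` after the word ends.
#'
#' @param word a `wrrc_word_token`.
#' @param spec a [condition_spec()].
#' @param babble_tail_s babble continuation after word end, seconds.
#' @return a `wrrc_timeline` list: `beat_onsets` (4), `p_centers` (2),
#'   `intervals` (4: three inter-beat + last-beat-to-P1), `babble_on`,
#'   `ramp_end`, `babble_off`, `word_start`, `word_end`, `last_beat_gap`,
#'   `ipi`, `condition`, `nr_type`, `word_id`.
#' @export
build_timeline <- function(word, spec, babble_tail_s = 0.25) {
  stopifnot(inherits(word, "wrrc_word_token"),
            inherits(spec, "wrrc_condition_spec"))
  ipi <- word$ipi
  p1 <- 4 * ipi
  p2 <- p1 + ipi
  intervals <- switch(spec$condition,
    RH   = rep(ipi, 4),
    NR   = ipi * (1 + spec$distortion * NR_SIGNS[spec$nr_type, ]),
    UnSc = c(rep(spec$unsc_factor * ipi, 3),
             p1 - 3 * spec$unsc_factor * ipi))
  beats <- c(0, cumsum(intervals[1:3]))
  word_start <- p1 - word$p1
  word_end <- word_start + audio_duration(word$audio)
  structure(list(
    beat_onsets = beats, p_centers = c(p1, p2), intervals = intervals,
    babble_on = p1 - 1.5 * ipi, ramp_end = p1 - 0.5 * ipi,
    babble_off = word_end + babble_tail_s,
    word_start = word_start, word_end = word_end,
    last_beat_gap = p1 - beats[4], ipi = ipi,
    condition = spec$condition,
    nr_type = if (is.null(spec$nr_type)) NA_character_ else spec$nr_type,
    word_id = word$word_id), class = "wrrc_timeline")
}

#' @export
print.wrrc_timeline <- function(x, ...) {
  cat(sprintf("<wrrc_timeline> %s [%s%s] IPI %.1f ms\n", x$word_id,
              x$condition, if (is.na(x$nr_type)) "" else
                paste0("/", x$nr_type), 1000 * x$ipi))
  cat(sprintf("  beats: %s ms; P-centers: %s ms\n",
              paste(sprintf("%.1f", 1000 * x$beat_onsets), collapse = ", "),
              paste(sprintf("%.1f", 1000 * x$p_centers), collapse = ", ")))
  cat(sprintf("  babble %0.1f -> ramp %0.1f -> off %0.1f ms\n",
              1000 * x$babble_on, 1000 * x$ramp_end, 1000 * x$babble_off))
  invisible(x)
}

#' Render and mix one stimulus
#'
#' Places the beat tone at each beat onset and the word token so its
#' P-centers land on the timeline's P-center times, then adds babble whose
#' gain is set from the rendered segment so that
#' `20*log10(word RMS / babble plateau RMS)` equals `sbr_db` exactly: word
#' RMS is taken over the word's extent, babble plateau RMS over the
#' constant (post-ramp) portion. The babble fades in linearly over 1 IPI
#' and stops abruptly. The mixture is peak-normalized with `headroom_db`
#' of headroom (component tracks are scaled identically, so the SBR is
#' preserved and auditable from the rendered tracks).
#'
#' @param timeline a `wrrc_timeline`.
#' @param word the `wrrc_word_token` the timeline was built from.
#' @param babble a `wrrc_babble` at least as long as the babble span.
#' @param beat a beat `wrrc_audio` (default [synth_beat()]).
#' @param sbr_db target signal-to-babble ratio in dB.
#' @param headroom_db peak headroom of the normalized mixture.
#' @return a `wrrc_stimulus`: `audio` (mixture), `word_track`,
#'   `babble_track`, `beat_track` (aligned components), `timeline`,
#'   `sbr_db`.
#' @export
mix_stimulus <- function(timeline, word, babble, beat = synth_beat(),
                         sbr_db = 1.3, headroom_db = 3) {
  stopifnot(inherits(timeline, "wrrc_timeline"),
            inherits(word, "wrrc_word_token"),
            inherits(babble, "wrrc_babble"))
  rate <- word$audio$rate
  if (beat$rate != rate || babble$audio$rate != rate)
    stop("all components must share one sampling rate", call. = FALSE)
  n <- ceiling(timeline$babble_off * rate)

  at <- function(t) round(t * rate) + 1L
  place <- function(track, samples, t0) {
    i <- at(t0)
    idx <- i:(i + length(samples) - 1L)
    track[idx] <- track[idx] + samples
    track
  }

  word_track <- numeric(n)
  word_track <- place(word_track, word$audio$samples, timeline$word_start)

  beat_track <- numeric(n)
  for (b in timeline$beat_onsets)
    beat_track <- place(beat_track, beat$samples, b)

  i_on <- at(timeline$babble_on)
  i_ramp <- at(timeline$ramp_end)
  need <- n - i_on + 1L
  if (length(babble$audio$samples) < need)
    stop("babble track too short for this timeline", call. = FALSE)
  seg <- babble$audio$samples[seq_len(need)]
  env <- c(seq(0, 1, length.out = i_ramp - i_on + 1L),
           rep(1, n - i_ramp))
  i_w0 <- at(timeline$word_start)
  i_w1 <- min(n, at(timeline$word_end))
  word_rms <- sqrt(mean(word_track[i_w0:i_w1]^2))
  plateau_rms <- sqrt(mean(seg[(i_ramp - i_on + 1L):need]^2))
  gain <- word_rms / (plateau_rms * 10^(sbr_db / 20))
  babble_track <- numeric(n)
  babble_track[i_on:n] <- seg * env * gain

  mix <- word_track + babble_track + beat_track
  scale <- 10^(-headroom_db / 20) / max(abs(mix))
  if (!is.finite(scale)) stop("rendering error: silent mixture",
                              call. = FALSE)
  mix <- mix * scale
  if (max(abs(mix)) > 1) stop("rendering error: clipping", call. = FALSE)
  structure(list(audio = audio_buffer(mix, rate),
                 word_track = word_track * scale,
                 babble_track = babble_track * scale,
                 beat_track = beat_track * scale,
                 timeline = timeline, sbr_db = sbr_db),
            class = "wrrc_stimulus")
}

#' Measure the signal-to-babble ratio of a rendered stimulus
#'
#' Recomputes `20*log10(word RMS / babble plateau RMS)` from the rendered
#' component tracks: word RMS over the word extent, babble RMS over the
#' constant plateau (ramp end to babble offset).
#'
#' @param stimulus a `wrrc_stimulus`.
#' @return measured SBR in dB.
#' @export
measure_sbr <- function(stimulus) {
  stopifnot(inherits(stimulus, "wrrc_stimulus"))
  tl <- stimulus$timeline
  rate <- stimulus$audio$rate
  n <- length(stimulus$audio$samples)
  idx_w <- (round(tl$word_start * rate) + 1L):min(n, round(tl$word_end * rate) + 1L)
  idx_b <- (round(tl$ramp_end * rate) + 1L):n
  20 * log10(sqrt(mean(stimulus$word_track[idx_w]^2)) /
             sqrt(mean(stimulus$babble_track[idx_b]^2)))
}

#' @export
print.wrrc_stimulus <- function(x, ...) {
  cat(sprintf("<wrrc_stimulus> %s [%s] %.2f s, SBR %.2f dB (measured %.2f)\n",
              x$timeline$word_id, x$timeline$condition,
              audio_duration(x$audio), x$sbr_db, measure_sbr(x)))
  invisible(x)
}
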