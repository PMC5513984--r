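# Full-session assembly: 3 lists x 16 words -> 48 randomized trials.

#' Randomized 48-trial session design
#'
#' Generates the presentation design used by the listener simulator and the
#' exporter: one 16-word list per condition, all 48 trials shuffled by
#' `seed`, and non-rhythm distortion types assigned A..F cycling in
#' presentation order.
#'
#' @param seed integer seed for the presentation order.
#' @param condition_map conditions for lists 1–3 (counterbalancing knob).
#' @param word_ids optional 3 x 16 matrix-like list of word labels.
#' @return data.frame with columns `trial`, `list_id`, `word_index`,
#'   `word_id`, `condition`, `nr_type`.
#' @export
design_manifest <- function(seed = 1L,
                            condition_map = c("RH", "NR", "UnSc"),
                            word_ids = NULL) {
  stopifnot(length(condition_map) == 3,
            all(sort(condition_map) == c("NR", "RH", "UnSc")))
  rng <- local_rng(seed)
  d <- data.frame(
    list_id = rep(sprintf("list%d", 1:3), each = 16),
    word_index = rep(1:16, times = 3),
    condition = rep(condition_map, each = 16),
    stringsAsFactors = FALSE)
  d$word_id <- if (is.null(word_ids))
    sprintf("%s_w%02d", d$list_id, d$word_index)
  else unlist(word_ids)
  d <- d[rng$sample_int(48L, 48L), ]
  d$trial <- seq_len(48L)
  d$nr_type <- NA_character_
  is_nr <- d$condition == "NR"
  d$nr_type[is_nr] <- assign_nr_type(seq_len(sum(is_nr)) - 1L)
  rownames(d) <- NULL
  d[, c("trial", "list_id", "word_index", "word_id", "condition", "nr_type")]
}

#' Build and export a complete 48-stimulus session
#'
#' Assigns one word list per condition, builds every trial's timeline,
#' optionally renders and writes the mixed waveforms as WAV, and writes a
#' manifest (presentation order, condition, distortion type, timeline and
#' ground truth) as CSV and JSON.
#'
#' @param lists list of three `wrrc_word_list` objects.
#' @param seed integer seed (presentation order and babble).
#' @param out_dir output directory (created if missing).
#' @param sbr_db signal-to-babble ratio in dB.
#' @param condition_map conditions assigned to lists 1–3.
#' @param write_audio if `FALSE`, write the manifest only (fast).
#' @param beat beat tone buffer.
#' @return the manifest data.frame, invisibly; columns as
#'   [design_manifest()] plus `ipi`, `stress`, `p1`, `p2` (absolute trial
#'   times), `beat1`–`beat4`, `babble_on`, `ramp_end`, `babble_off`,
#'   `last_beat_gap`, `wav`.
#' @export
export_session <- function(lists, seed = 1L, out_dir, sbr_db = 1.3,
                           condition_map = c("RH", "NR", "UnSc"),
                           write_audio = TRUE, beat = synth_beat()) {
  if (length(lists) != 3 ||
      !all(vapply(lists, inherits, logical(1), "wrrc_word_list")))
    stop("`lists` must be three wrrc_word_list objects", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ids <- lapply(lists, function(l)
    vapply(l$tokens, `[[`, character(1), "word_id"))
  man <- design_manifest(seed, condition_map, word_ids = ids)
  # word ids carry the source list's label as "<list_id>_wNN"
  man$list_id <- sub("_w[0-9]+$", "", man$word_id)

  rng <- local_rng(seed + 1L)
  extra <- data.frame(ipi = numeric(48), stress = integer(48),
                      p1 = numeric(48), p2 = numeric(48),
                      beat1 = numeric(48), beat2 = numeric(48),
                      beat3 = numeric(48), beat4 = numeric(48),
                      babble_on = numeric(48), ramp_end = numeric(48),
                      babble_off = numeric(48), last_beat_gap = numeric(48),
                      wav = NA_character_)
  list_of <- function(cond) lists[[match(cond, condition_map)]]
  for (i in seq_len(48L)) {
    row <- man[i, ]
    tok <- list_of(row$condition)$tokens[[row$word_index]]
    spec <- condition_spec(row$condition,
                           nr_type = if (is.na(row$nr_type)) NULL
                                     else row$nr_type)
    tl <- build_timeline(tok, spec)
    extra$ipi[i] <- tl$ipi
    extra$stress[i] <- tok$stress
    extra$p1[i] <- tl$p_centers[1]; extra$p2[i] <- tl$p_centers[2]
    extra[i, c("beat1", "beat2", "beat3", "beat4")] <- as.list(tl$beat_onsets)
    extra$babble_on[i] <- tl$babble_on
    extra$ramp_end[i] <- tl$ramp_end
    extra$babble_off[i] <- tl$babble_off
    extra$last_beat_gap[i] <- tl$last_beat_gap
    if (write_audio) {
      bab <- synth_babble(tl$babble_off - tl$babble_on + 0.05,
                          seed = rng$sample_int(2^30, 1L),
                          rate = tok$audio$rate)
      stim <- mix_stimulus(tl, tok, bab, beat = beat, sbr_db = sbr_db)
      f <- file.path(out_dir, sprintf("trial_%02d_%s_%s.wav", i,
                                      row$condition, row$word_id))
      wav_write(stim$audio, f)
      extra$wav[i] <- basename(f)
    }
  }
  man <- cbind(man, extra)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(man)
}
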