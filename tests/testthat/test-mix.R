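# Stimulus rendering, SBR calibration and session export.

make_stim <- function(cond = condition_spec("RH"), sbr = 1.3, seed = 7) {
  tok <- fixture_token(0.300, 1, seed)
  tl <- build_timeline(tok, cond)
  bab <- synth_babble(tl$babble_off - tl$babble_on + 0.05, seed = 3)
  list(stim = mix_stimulus(tl, tok, bab, sbr_db = sbr), tl = tl, tok = tok)
}

test_that("measured SBR hits the target within 0.1 dB", {
  for (sbr in c(1.3, -2, 5)) {
    s <- make_stim(sbr = sbr)
    expect_lt(abs(measure_sbr(s$stim) - sbr), 0.1)
  }
})

test_that("babble ramp is linear from zero to the plateau", {
  s <- make_stim()
  rate <- s$stim$audio$rate
  bt <- s$stim$babble_track
  i_on <- round(s$tl$babble_on * rate) + 1L
  i_ramp <- round(s$tl$ramp_end * rate) + 1L
  expect_identical(bt[i_on], 0)                  # envelope 0 at onset
  expect_true(all(bt[1:(i_on - 1L)] == 0))       # silent before onset
  # RMS in a window just after ramp end matches the plateau level
  plateau <- sqrt(mean(bt[i_ramp:length(bt)]^2))
  w <- round(0.1 * rate)
  post <- sqrt(mean(bt[i_ramp:(i_ramp + w)]^2))
  expect_lt(abs(post - plateau) / plateau, 0.25)
  # half-way up the ramp the expected envelope is 0.5 of the plateau
  mid0 <- (i_on + i_ramp) %/% 2L
  mid <- sqrt(mean(bt[(mid0 - w %/% 2):(mid0 + w %/% 2)]^2))
  expect_lt(abs(mid / plateau - 0.5), 0.15)
})

test_that("condition does not change the stimulus duration", {
  durs <- vapply(
    list(condition_spec("RH"), condition_spec("NR", "C"),
         condition_spec("UnSc")),
    function(sp) length(make_stim(sp)$stim$audio$samples), numeric(1))
  expect_lte(max(durs) - min(durs), 1)
})

test_that("mixing guards its preconditions and never clips", {
  tok <- fixture_token(0.300, 1, 7)
  tl <- build_timeline(tok, condition_spec("RH"))
  short <- synth_babble(0.2, seed = 1)
  expect_error(mix_stimulus(tl, tok, short), "too short")
  s <- make_stim()
  expect_lte(max(abs(s$stim$audio$samples)), 10^(-3 / 20) + 1e-9)
})

test_that("a session holds 48 trials, 16 per condition, types cycling", {
  man <- design_manifest(seed = 5)
  expect_equal(nrow(man), 48)
  expect_equal(as.vector(table(man$condition)), rep(16L, 3))
  nr <- man$nr_type[man$condition == "NR"]      # presentation order
  expect_equal(nr, rep(c("A", "B", "C", "D", "E", "F"), length.out = 16))
  expect_true(all(is.na(man$nr_type[man$condition != "NR"])))
  expect_identical(man, design_manifest(seed = 5))
  expect_false(identical(man$word_id, design_manifest(seed = 6)$word_id))
})

test_that("export_session writes waveforms and a coherent manifest", {
  lists <- lapply(1:3, function(i)
    make_word_list(seed = 100 + i, list_id = sprintf("list%d", i)))
  out <- file.path(tempdir(), "wrrc_session")
  man <- export_session(lists, seed = 9, out_dir = out, write_audio = TRUE)
  expect_equal(nrow(man), 48)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(all(file.exists(file.path(out, man$wav))))
  # timelines embedded in the manifest respect the babble geometry
  expect_equal(man$ramp_end - man$babble_on, man$ipi, tolerance = 1e-9)
  expect_equal(man$p1 - man$ramp_end, 0.5 * man$ipi, tolerance = 1e-9)
  # a rendered file round-trips as audio
  w <- wav_read(file.path(out, man$wav[1]))
  expect_equal(w$rate, 44100)
  expect_gt(audio_duration(w), 1)
  # identical seed reproduces the manifest exactly
  out2 <- file.path(tempdir(), "wrrc_session2")
  man2 <- export_session(lists, seed = 9, out_dir = out2,
                         write_audio = FALSE)
  expect_identical(man$word_id, man2$word_id)
  expect_identical(man$nr_type, man2$nr_type)
  unlink(c(out, out2), recursive = TRUE)
})
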