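# Synthetic audio materials: beat, word tokens, word lists, babble.

test_that("beat tone has the specified length, frequency and guards", {
  b <- synth_beat(15, 1000, 44100)
  expect_equal(length(b$samples), 662)          # round(0.015 * 44100)
  expect_lt(abs(spectral_peak(b) - 1000), 1)    # well under one padded bin
  expect_lte(max(abs(b$samples)), 0.9 + 1e-12)
  expect_error(synth_beat(0, 1000), "positive")
  expect_error(synth_beat(-3, 1000), "positive")
  expect_error(synth_beat(15, 23000, 44100), "Nyquist")
})

test_that("word tokens honor the IPI contract and stress marking", {
  rate <- 44100
  tok <- fixture_token(0.300, 1, 7)
  expect_s3_class(tok, "wrrc_word_token")
  expect_lte(abs((tok$p2 - tok$p1) - 0.300), 1 / rate)
  expect_gt(tok$p1, 0)
  expect_lt(tok$p2, audio_duration(tok$audio))

  # stressed second syllable has the higher burst peak
  tok2 <- synth_word_token(0.329, 2, seed = 1)
  n <- length(tok2$envelope)
  mid <- which.min(tok2$envelope[round(n * 0.25):round(n * 0.75)]) +
    round(n * 0.25) - 1L
  expect_gt(max(tok2$envelope[mid:n]), max(tok2$envelope[1:mid]))

  expect_error(synth_word_token(0.100, 1, 0), "0.224")
  expect_error(synth_word_token(0.500, 1, 0), "0.224")
  expect_error(synth_word_token(0.300, 3, 0), "stress")
})

test_that("P-center ground truth is recovered exactly from the envelope", {
  for (seed in 1:20) {
    ipi <- 0.224 + (0.434 - 0.224) * (seed - 1) / 19
    tok <- synth_word_token(ipi, 1L + seed %% 2L, seed = seed)
    m <- measure_pcenters(tok)
    expect_lte(abs(m[1] - tok$p1), 1 / 44100)
    expect_lte(abs(m[2] - tok$p2), 1 / 44100)
  }
})

test_that("rendering is reproducible and seed-sensitive", {
  a <- synth_word_token(0.3, 1, seed = 11)
  b <- synth_word_token(0.3, 1, seed = 11)
  c <- synth_word_token(0.3, 1, seed = 12)
  expect_identical(a$audio$samples, b$audio$samples)
  expect_false(identical(a$audio$samples, c$audio$samples))
})

test_that("word lists have exactly 11/5 stress counts and bounded IPIs", {
  for (seed in c(1, 42, 99)) {
    wl <- make_word_list(seed = seed)
    st <- vapply(wl$tokens, `[[`, integer(1), "stress")
    expect_equal(sum(st == 1L), 11)
    expect_equal(sum(st == 2L), 5)
    ipis <- vapply(wl$tokens, `[[`, numeric(1), "ipi")
    expect_true(all(ipis >= 0.224 - 1e-4 & ipis <= 0.434 + 1e-4))
  }
  expect_error(make_word_list(n_words = 4, n_stress1 = 11), "exceed")
})

test_that("pooled IPIs match the truncated-normal mean", {
  # symmetric truncation at +-1.91 SD leaves the mean at 0.329; the
  # Monte-Carlo SE over 100 lists is ~1.3 ms, well inside +-10 ms
  ipis <- unlist(lapply(1:100, function(s) {
    wl <- make_word_list(seed = s)
    vapply(wl$tokens, `[[`, numeric(1), "ipi")
  }))
  expect_lt(abs(mean(ipis) - 0.329), 0.010)
})

test_that("babble is stationary, seeded, and modulated at syllabic rates", {
  bb <- synth_babble(5, 8, seed = 3)
  s <- bb$audio$samples
  rate <- bb$audio$rate
  win <- round(0.25 * rate)
  starts <- seq(1, length(s) - win, by = win %/% 2)
  w_rms <- vapply(starts, function(i) sqrt(mean(s[i:(i + win - 1)]^2)),
                  numeric(1))
  expect_true(all(abs(w_rms - bb$plateau_rms) <= 0.2 * bb$plateau_rms))

  bb2 <- synth_babble(5, 8, seed = 4)
  expect_false(identical(s, bb2$audio$samples))
  expect_identical(s, synth_babble(5, 8, seed = 3)$audio$samples)

  # modulation spectrum: envelope energy concentrated at 2-8 Hz
  env <- abs(s)
  env <- env - mean(env)
  n <- length(env)
  mag <- Mod(stats::fft(env))[2:(n %/% 2)]
  f <- (2:(n %/% 2) - 1) * rate / n
  pk <- f[which.max(mag[f < 30])]
  expect_gte(pk, 2); expect_lte(pk, 8)

  expect_error(synth_babble(-1, 8), "positive")
  expect_error(synth_babble(1, 1), ">= 2")
})
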