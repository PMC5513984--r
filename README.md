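# wrrc

Rhythmic priming of word-in-babble recognition: P-center-aligned stimulus
construction, adaptive staircase psychophysics, a simulated listener
cohort, syllable-level scoring, and a nonparametric analysis pipeline —
runnable end to end with zero external data.

## The problem

Dynamic attending theory holds that an isochronous beat sequence entrains
periodic attention, so speech arriving *on the beat* should be recognized
better in noise. The experiment this package implements tests that in a
word-recognition paradigm: a bisyllabic word in multitalker babble is
preceded by four 15 ms / 1,000 Hz beats whose grid either continues into
the word's perceptual centers (P-centers) (**RH**), is distorted ±30% per
interval so no rhythm is perceived (**NR**, six duration-preserving
patterns A–F), or is isochronous but 10% fast so the beat grid misses the
word (**UnSc**). With the first beat at 0 and inter-beat interval IBI tied
to the word's inter-P-center interval IPI, the first P-center always falls
at 4·IPI, so condition never changes stimulus duration. Babble starts
1.5 IPI before the first P-center, fades in linearly over 1 IPI, and the
word is mixed at a signal-to-babble ratio of 1.3 dB.

Each of 26 simulated children (10 boys, 16 girls) hears 48 randomized
trials (16 per condition) and yields nine measures: condition totals RH,
NR, UnSc (0–32; one point per correct syllable) and the
syllable-position splits RH1, RH2, NR1, NR2, UnSc1, UnSc2 (0–16). The
analysis is fully nonparametric: a skew/kurtosis z-screen, Friedman
omnibus tests (totals, first syllables, second syllables), pairwise
post-hocs at Bonferroni-adjusted α = 0.017/0.003, Mann–Whitney sex
contrasts, and Spearman correlations with shared-variance percentages.

The package also implements the two-stage adaptive staircase with which
the word P-centers are located (coarse 1,000-sample / fine 500-sample
steps, direction reversal after 2 consecutive opposite judgements, 4 runs
per stage, border-value averaging), exercised against simulated musician
observers with a configurable acceptance window and lapse rate.

## Worked example

```r
library(wrrc)

# one word token with exact ground-truth P-centers
tok <- synth_word_token(ipi_s = 0.300, stress = 1, seed = 7)
tok
#> <wrrc_word_token> w_007: p1 = 0.0851 s, p2 = 0.3851 s (IPI 300.0 ms), stress 1

# its rhythm-condition trial: beats at 0/300/600/900 ms, P-centers at 4 and 5 IPI
tl <- build_timeline(tok, condition_spec("RH"))
tl
#> <wrrc_timeline> w_007 [RH] IPI 300.0 ms
#>   beats: 0.0, 300.0, 600.0, 900.0 ms; P-centers: 1200.0, 1500.0 ms
#>   babble 750.0 -> ramp 1050.0 -> off 1943.0 ms

# render it in babble at 1.3 dB SBR
bab  <- synth_babble(tl$babble_off - tl$babble_on + 0.05, seed = 3)
stim <- mix_stimulus(tl, tok, bab)
stim
#> <wrrc_stimulus> w_007 [RH] 1.94 s, SBR 1.30 dB (measured 1.30)
wav_write(stim$audio, "trial.wav")

# recover the P-center with the staircase against a simulated musician
res <- estimate_pcenter(tok, 1, simulated_musician(tok$p1, window_ms = 10, seed = 5))
res
#> <wrrc_staircase_result> estimate 0.0888 s (true 0.0851 s, error +3.71 ms, 36 trials)

# simulate and analyse a full 26-child cohort
st <- run_simulated_study(seed = 2)
st$report
#> == Analysis report (n = 26: 10 male, 16 female) ==
#> Normality screen: 6 of 9 measures within z in (-1.96, 1.96)
#>
#> Omnibus (Friedman):
#>   total      chi2(2) = 27.723, p = 0.000 *
#>   syllable1  chi2(2) = 9.791, p = 0.007 *
#>   syllable2  chi2(2) = 18.020, p = 0.000 *
#> ...
```

The omnibus lines read as χ²(df) with the asymptotic p; starred rows are
significant at the α shown in the section header (post-hoc and
correlation families use the Bonferroni-adjusted 0.017). In this seed the
rhythm condition beats both controls on the totals while NR vs UnSc stays
null — the qualitative pattern the calibrated simulator is built around.

A full 48-stimulus session (WAV files plus CSV/JSON manifest):

```r
lists <- lapply(1:3, function(k) make_word_list(seed = k, list_id = paste0("list", k)))
man   <- export_session(lists, seed = 1, out_dir = "session")
```

Command-line wrappers live in `inst/cli/wrrc.R`
(`build-session`, `simulate`, `analyze`).

## Layout

- `R/synth.R`, `R/audio.R` — tokens, beats, babble, WAV I/O
- `R/staircase.R` — staircase engine and simulated musician
- `R/timeline.R`, `R/session.R` — condition timelines, mixing, session export
- `R/listener.R`, `R/scoring.R` — simulated cohort and the nine measures
- `R/stats.R`, `R/report.R` — test battery and the structured report
- `vignettes/wrrc-methods.Rmd` — model, calibration and design rationale
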