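Package: wrrc
Title: Rhythmic Priming of Word-in-Babble Recognition: Stimuli, Simulation and Analysis
Version: 0.1.0
Authors@R: person("WRRC", "Maintainers", email = "wrrc@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a word recognition in babble
    experiment in which each target word is preceded by a short sequence of
    beats that is either rhythmic and synchronized with the word's perceptual
    centers (P-centers), rhythmically distorted, or isochronous but
    unsynchronized. Provides P-center-aligned stimulus synthesis (beat tones,
    bisyllabic word tokens with ground-truth P-centers, multitalker-babble
    emulation, signal-to-babble calibrated mixing), a two-stage adaptive
    staircase for P-center estimation exercised against simulated musician
    observers, a synthetic listener cohort whose syllable recognition follows
    a dynamic-attending effect structure, syllable-level scoring into nine
    output measures, and a nonparametric statistical pipeline (skew/kurtosis
    normality screen, Friedman omnibus, Bonferroni-corrected pairwise
    post-hocs, Mann-Whitney sex contrasts, Spearman correlations with shared
    variance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
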