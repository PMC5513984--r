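---
title: "Methods: rhythmic priming of word-in-babble recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythmic priming of word-in-babble recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The experiment this package implements

A bisyllabic target word is embedded in multitalker babble and preceded by
four brief beats (15 ms, 1,000 Hz pure tones). The alignment between the
beat grid and the word's two perceptual centers (P-centers — the subjective
moments of occurrence of the syllables) defines three conditions:

* **RH** (rhythm): beats and P-centers form one isochronous pulse. With the
  first beat at time zero and inter-beat interval (IBI) equal to the word's
  inter-P-center interval (IPI), the first P-center falls at 4·IPI and the
  second at 5·IPI — the word continues the beat.
* **NR** (non-rhythm): the four intervals (three IBIs plus last-beat→P1) are
  each distorted by ±30%, in one of six sign patterns (A–F), every pattern
  containing two `+` and two `−` so the total of the four intervals — and
  hence the stimulus duration — is untouched. Patterns are assigned
  ordinally (first NR presentation gets A, the second B, …, cycling).
* **UnSc** (unsynchronized): beats are isochronous but 10% fast
  (IBI = 0.9·IPI) while the word stays fixed at 4·IPI, so the extrapolated
  beat grid (5th beat at 3.6·IPI) misses both P-centers.

Dynamic attending theory predicts that entrainment to the isochronous,
synchronized sequence places the syllables at attentional peaks and should
improve recognition in noise — the effect structure the synthetic listener
cohort encodes.

Babble geometry is identical in all conditions: onset 1.5 IPI before the
first P-center, linear fade-in over exactly 1 IPI (ramp ends 0.5 IPI before
P1), constant plateau, abrupt stop 250 ms (configurable) after the word
ends. The signal-to-babble ratio is 1.3 dB.

### Anchoring choices

The word is placed by its P-centers, not its onset. Fixing the first beat at
time zero and the word at 4·IPI makes the UnSc condition *lengthen* the
last-beat→word gap to 1.3·IPI; the alternative (slower beats) would push
the last beat into the word for late P-centers, which is why faster beats
are the right reading. The last-beat gap is condition-dependent — a known
confound of the design — so every timeline logs it.

## Synthetic word tokens and the P-center convention

Real recordings are replaced by synthetic bisyllabic tokens: two vowel-like
harmonic bursts (seeded f0 in 200–255 Hz, 8 harmonics at 1/h amplitudes)
under asymmetric raised-cosine envelopes (30% rise, 70% fall). P-centers
are behavioural constructs; for synthetic tokens we need an exact,
measurable stand-in, and we use the time the syllable envelope first
reaches 50% of its peak — a common envelope-landmark convention that falls
exactly halfway up the cosine rise. The landmark is measured on the
rendered sample grid at synthesis time and stored as ground truth, so
re-measuring the envelope recovers it exactly, and the burst placement
guarantees p2 − p1 equals the requested IPI within one sample.

Stress is marked acoustically: the stressed syllable gets +4 dB peak and
×1.3 duration (arbitrary but fixed and configurable). Lists of 16 words
carry exactly 11 first-syllable-stressed and 5 second-syllable-stressed
tokens (the 68.75/31.25% split of the source material). IPIs are drawn by
rejection from a normal with mean 329 ms and SD 55 ms truncated to
[224, 434] ms — the distribution observed in the original word material;
the truncation is symmetric (±1.91 SD), so the truncated mean stays at
329 ms.

Babble is emulated as the sum of eight independent speech-band
(100–8,000 Hz) noise streams, each amplitude-modulated by 2–8 Hz band-pass
noise (syllabic rates) at depth 0.5. Averaging across streams keeps any
250 ms window's RMS within ±20% of the plateau value. This reproduces the
long-term spectrum and modulation statistics that matter for energetic
masking, but none of the informational content of real cafeteria babble.

### SBR convention

The 1.3 dB signal-to-babble ratio is realized as
`20·log10(word RMS / babble plateau RMS)` with word RMS taken over the
word's extent and babble RMS over the constant post-ramp plateau. The
mixing gain is computed from the very samples that end up in the rendered
plateau, so the measured SBR of a rendered stimulus equals the target to
numerical precision; the mixture is then peak-normalized with 3 dB
headroom (component tracks scaled identically, preserving the SBR).
Physical presentation level (60 dBA in a classroom) is a loudspeaker
calibration outside digital scope.

## The P-center staircase

The adaptive procedure the original musicians performed is implemented as
timeline arithmetic against a simulated observer. One stage presents the
word aligned to the beat grid by the current P-value and steps it by a
fixed amount — 1,000 samples (22.7 ms at 44.1 kHz) in the coarse stage,
500 samples in the fine stage. (The fine step is 11.34 ms by exact
arithmetic; the source text quotes both 12.2 and 11.9 ms.) The first
response sets the direction: *delayed* → increase, *too early* → decrease,
*good* → seeded quasi-random. A *run* is a maximal same-direction sequence;
it ends when the opposite category is reported on 2 consecutive
presentations, and the stage ends after 4 runs. Each run's *border value*
is the last presented value before the terminal opposite streak — the
observed edge of the "good" region — and the stage estimate averages the
borders of the final two runs. Stage 1 starts from a simulated visual
estimate (truth plus a seeded uniform offset within ±60 ms, consistent
with the reported ≤90 ms total adjustment range); its estimate seeds stage
2, whose border average is the final estimate.

The simulated musician accepts anything within `window_ms` of the true
P-center and otherwise reports the direction of misalignment; with
probability `lapse` the response is replaced by a random one. A trial cap
(200/stage) turns pathological oscillation into an explicit failure.

Two properties of this schedule are worth stating because they differ from
naive intuition:

* Because the acceptance window half-width enters the upper and lower
  borders with opposite signs, it cancels in the border average. The
  estimation error is therefore dominated by step-grid quantization and is
  essentially *flat* in the window (~1.5–2.3 ms mean absolute error for
  windows 5–30 ms under a lapse-free observer, always under one fine
  step). Shrinking the window does not monotonically improve accuracy;
  the test suite asserts the flat-and-bounded behaviour.
* Two independent simulated observers disagree only through lapses, grid
  alignment and seeded starts — about 3–4 ms on average at window 15 ms,
  lapse 0.05. The 17 ms disagreement reported between the two human
  musicians includes stable perceptual-bias differences that a memoryless
  symmetric oracle deliberately does not model; the acceptance check is
  therefore an order-of-magnitude comparison, not a calibration match.

## The synthetic listener cohort

No acoustic decoding is attempted: a listener is a Bernoulli response
model whose per-syllable success probability is the inverse logit of
`base + δ(condition, syllable) [+ sex term]`, mixed with a fair guess at a
2% lapse rate. This is the simplest structure that can encode the
dynamic-attending effect pattern; the source analysis reports only medians
and test outcomes, not a response model.

Calibration targets, fixed before any acceptance run and not revisited:

* Condition totals (of 32): RH 24.5, NR 22, UnSc 22 — the reported
  population medians. The NR baseline gives `base = logit(22/32)`.
* Each condition's total is split across syllable positions in proportion
  to the reported syllable medians (13:11, 12:10, 12:9), weighting the
  rhythm advantage toward the first syllable. (The medians are not
  additive — 13 + 11 = 24 ≠ 24.5 — which is why totals take priority.)
* The female advantage on second-syllable rhythm scores enters as one
  logit term (the gap between the sex-specific medians 11.5 and 10 of 16);
  the male offset of that cell is solved numerically so the 10:16
  sex-weighted population mean stays on target.
* Between-subject variation is a normal perturbation of `base` with SD
  0.25 logits, chosen so the simulated total-score SD lands near 3.1
  points, the dispersion printed for the rhythm condition read as an SD.
  The printed dispersions are unlabeled; were they IQRs, a smaller SD
  would follow. This single reading materially affects the power analysis
  below.

Syllable outcomes are independent given the profile; word-level 2-point
scoring is exactly the syllable sum, so no within-word correlation term is
needed for the nine measures.

**What a green test establishes, and what it does not.** The generator
reproduces the calibrated cell means, the sex composition (10 boys, 16
girls), nominal type-I error of the downstream omnibus under the null, and
the qualitative sign pattern of the condition effects. It does not
reproduce item effects (all words within a condition share one
probability), serial/fatigue effects, response-sheet spelling noise beyond
a symmetric lapse, or any acoustic dependence on the actual rendered
stimuli.

**Power at the calibrated effects is marginal by construction.** With
n = 26 and between-group post-hocs at α = 0.017, the joint event
{omnibus p < 0.05, RH > NR and RH > UnSc both flagged} occurs in ≈51% of
simulated cohorts (measured over 1,000 worlds). The acceptance criterion
asks for a majority; the stated world sits on that knife edge, and the
acceptance test estimates the rate over 1,000 cohorts rather than gambling
on a 200-cohort draw. The NR-vs-UnSc pair is flagged in <1% of cohorts,
matching the reported null contrast.

## Statistical battery

All tests use mid-ranks and the standard tie corrections, two-sided
p-values, and exact/enumerative null distributions at small n
(asymptotic otherwise, matching common software):

* **Normality screen**: adjusted Fisher–Pearson skewness (G1) and excess
  kurtosis (G2) over their small-sample SEs; a measure "passes" iff both
  z-values lie in (−1.96, 1.96). Requires n ≥ 8.
* **Friedman omnibus** on (RH, NR, UnSc), then the first-syllable and
  second-syllable triples; tie-corrected χ² with df = 2. For n ≤ 8 the
  p-value is exact: the statistic depends on a permuted table only through
  the column rank sums, so the null is enumerated by convolving each
  row's six equally likely rank assignments.
* **Pairwise post-hocs**: all three condition pairs at
  `round(α/3, 3)` — 0.017 at nominal 0.05, 0.003 at 0.01. The default
  test is the two-group Kruskal–Wallis (χ² form, as in the original
  post-hocs); Mann–Whitney and a paired Wilcoxon signed-rank variant are
  selectable. Applying between-group tests to within-subject scores is a
  fidelity choice, not a statistical recommendation.
* **Sex contrasts**: Mann–Whitney U (exact enumeration when both groups
  ≤ 8) on all nine measures.
* **Correlations**: Spearman ρ between condition totals (α = 0.017 under
  Bonferroni), with syllable-level follow-ups for any pair reaching
  uncorrected 0.05; shared variance is 100·ρ² to one decimal and the
  unexplained percentage is computed as its exact complement. For n ≤ 8
  the p-value enumerates all n! orderings.

Post-hoc families are only run when their omnibus is significant,
mirroring the original analysis flow; a report therefore contains at most
nine post-hoc rows.

## Numerical and degenerate-input conventions

All synthesis at 44,100 Hz (the quoted "22,050 kHz" recording rate is read
as 22,050 Hz and not used; resampling is avoided entirely). Beat tones get
2 ms raised-cosine ramps; a beat's nominal time is its onset sample.
Constant samples short-circuit to "normal" in the screen (z = 0), p = 1 in
Friedman/Mann–Whitney, and ρ = 0, p = 1 in correlations. Seeded generators
never touch the session RNG (each carries its own stream). The staircase
rejects non-convergence rather than returning a silent estimate.

## Known limitations

* The listener model is phenomenological; nothing connects the rendered
  audio to the simulated responses.
* The babble stand-in has no linguistic content, so informational masking
  is absent.
* Classroom acoustics (reverberation, presentation level) are out of
  scope; stimuli are digital waveforms with 3 dB headroom.
* The isolated parametric F-test reported for the stressed/unstressed
  contrast in the source analysis is not part of the battery; the
  nonparametric pipeline covers the stress stratification instead.
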