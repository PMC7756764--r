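---
title: "Measuring vocal stereotypy duration from session audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vocal stereotypy duration from session audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmeter)
```

## The measurement problem

Behavior analysts who monitor vocal stereotypy — repetitive, acontextual or
unintelligible vocalizations common in autistic children — usually score
session recordings by hand, marking each second as containing the behavior or
not (partial-interval recording with 1-s intervals). The session-level
quantity of clinical interest is the *engagement percentage*: the percent of
a session's seconds scored as occurrences. Hand-scoring is accurate but
expensive; an hour of audio takes well over an hour of observer time, and a
second observer is needed for interobserver agreement.

`vocalmeter` automates this measurement. A compact neural network classifies
each second of audio as occurrence / non-occurrence; per-second predictions
aggregate to session engagement; and three cross-validation protocols
quantify how well the automated measure agrees with an observer, both within
sessions (accuracy, Cohen's kappa) and across sessions (the session-by-session
engagement correlation, with 0.80 the conventional "strong" benchmark).

## The pipeline

### Audio standardization

All audio is standardized to 22,050 Hz mono 16-bit PCM. Multi-channel input
is mixed by channel average; other sampling rates are converted by
Fourier-domain resampling (brickwall band-limitation followed by exact
reconstruction on the new grid), which is numerically exact for band-limited
content and preserves duration to within one sample period. Only whole
seconds are analyzed — samples beyond the last full second are dropped,
because the labels are per-second and a trailing fraction has none. Second
`k` covers the half-open sample interval `[k·sr, (k+1)·sr)`, 0-based.

### Features: 10 frames × 26 log mel-filterbank energies

Each second is cut into ten non-overlapping 0.1-s frames. Each frame is
pre-emphasized (coefficient 0.97), zero-padded to a 4,096-point FFT (the next
power of two above the 2,205-sample frame, so nothing is truncated), and its
power spectrum is pooled by a bank of 26 triangular filters spaced evenly on
the mel scale, `mel(f) = 2595·log10(1 + f/700)`, from 0 Hz to Nyquist.
Energies are floored at 1e-10 before the log so silence maps to a finite
value. That yields 260 features per second (10 × 26), the input width of the
classifier.

Two conventions deserve a note. First, the per-frame representation is the
26 *log filterbank energies*, not 13 cepstral coefficients: 26 is the
standard filterbank size of the common speech-features toolkits, and it is
the only reading under which 10 × 26 = 260 comes out exactly. A
`cepstral = TRUE` switch applies an orthonormal DCT-II on top for sensitivity
analysis. Second, frames use a rectangular window; window choice, FFT size,
pre-emphasis, and band edges are all configurable in `feature_config()`.

### The classifier

A fully connected 260 → 128 → 1 network (ReLU hidden layer, sigmoid output)
maps each second's features to an occurrence probability; seconds at or
above the 0.5 threshold are classified as occurrences (ties go to 1).
Training minimizes binary cross-entropy by mini-batch gradient descent
(batch 256) with the Adam optimizer at its canonical defaults (step 0.001,
β₁ = 0.9, β₂ = 0.999). Because sessions contain far more silence than
stereotypy, each class is weighted by `n / (2·n_class)`, which equalizes the
total weighted mass of positive and negative seconds. Inverted dropout at
rate 0.2 is applied to the input and hidden layers during training only.

After every epoch, Cohen's kappa of the thresholded predictions on the
pooled validation seconds is computed; training stops once kappa has not
improved for 10 consecutive epochs, and the parameters of the earliest
best-kappa epoch are restored. Whether to restore best or keep last-epoch
weights was a genuinely open choice; restoring is the default because the
stopping criterion is explicitly "the best validation kappa", and a
`restore_best = FALSE` switch preserves the alternative. A hard cap of 500
epochs is a safety net. All randomness — initialization (uniform Glorot),
batch shuffling, dropout masks — derives from one integer seed, so training
is bit-reproducible.

ReLU is a choice worth flagging: the hidden activation is not dictated by
the design we reproduce, and any sigmoidal alternative would serve; ReLU is
the standard default for this architecture generation and trains faster.

### Agreement metrics

* **Accuracy** — agreeing seconds over total seconds. Easily inflated by
  class imbalance: predicting "never" on a session with 0.3% engagement
  scores 99.7%.
* **Cohen's kappa** — `(p_o − p_e) / (1 − p_e)` from the 2×2 contingency,
  correcting for chance agreement. When both raters are constant and
  identical, `p_e = 1` and kappa is undefined; the package returns `NA` and
  surfaces the count of such sessions rather than silently substituting 0
  or 1.
* **Session-by-session correlation** — Pearson correlation between
  predicted and observed engagement percentages across sessions, the
  headline validity measure. Pearson (not Spearman) is the default because
  the 0.80 benchmark comes from product-moment conventions; a Spearman
  option exists.
* **Kappa-vs-engagement correlation** — the deflation diagnostic discussed
  below.

Pooled kappa over concatenated seconds and the mean of per-session kappas
are different statistics, and the package computes both (`kappa_pooled`,
`kappa_mean` in protocol aggregates): low-engagement sessions drag the mean
down without much affecting the pooled value.

### Cross-validation protocols

* **Between-participant** (`between_splits()`): one rotation per
  participant; the rotation's test set is all of that participant's
  sessions, validation is all sessions of one other participant, training
  the remaining six (of eight). Validation participants follow the cyclic
  successor of the test participant — any collision-free permutation
  satisfies the design; cyclic is the simplest auditable one. The
  music-exclusion variant drops music-condition sessions everywhere before
  splitting and applies to this analysis only.
* **Within-participant** (`within_splits()`): one rotation per session; the
  remaining sessions are shuffled (seeded) and divided 83/17 into training
  and validation, with validation count `max(1, round(0.17·n))` so small
  participants still get a validation set. Three sessions is the minimum
  (1 train / 1 validation / 1 test).
* **Hybrid** (`hybrid_splits()`): like within-participant but with a 67/33
  split, and the training set is doubled by sampling individual seconds
  uniformly without replacement from all other participants' sessions
  pooled — exactly as many as the within-participant training seconds, so
  the final training set is 50% within-participant. The 33% validation
  share (vs 17% in the within analysis) is kept as two distinct,
  per-analysis constants rather than reconciled. If the other-participant
  pool is too small, sampling falls back to replacement with a warning.

Every rotation's model is trained from scratch with a seed derived from the
top-level seed via a counter scheme (`derive_seed()`), so whole protocol
runs are reproducible and any single rotation can be replayed in isolation.
No test second ever appears in its own rotation's training or validation
material, enforced at second granularity.

## The synthetic corpus generator

No recordings ship with the package; `generate_corpus()` builds a labelled
corpus with the statistical structure the pipeline assumes, and every stage
is tested against it.

* **Background**: pink (1/f) noise — closer to home-recording ambience than
  white noise — at −30 dBFS RMS.
* **Vocal events**: harmonic stacks at a participant-specific fundamental
  (drawn per event from the profile's f0 range) with slow vibrato, spectral
  emphasis near a participant-specific formant center, raised-cosine
  attack/decay, and log-normal durations (median 0.5–1.4 s across default
  profiles). Default event level is +15 dB over the background RMS: high
  enough that test failures indicate pipeline defects rather than genuinely
  hard audio.
* **Event placement**: an alternating renewal process — log-normal event
  durations, exponential gaps. A second is labelled 1 if any event overlaps
  any fraction of it, so the expected fraction of *labelled* seconds
  exceeds the raw duty cycle; the gap mean is calibrated by root-finding on
  the closed-form unlabelled-second probability
  `g·exp(−1/g) / (E[d] + g)`, keeping realized engagement unbiased across
  the whole 0–80% target range (about ±3 percentage points SD at 300 s).
* **Music condition**: a surrogate of 3–5 harmonic voices playing a
  pentatonic note pattern with periodic onsets at +5 dB over the noise. The
  pattern (voices, pitches, octave) is drawn once *per participant* and
  recurs across that participant's music sessions, with only the starting
  note and phase varying per session. This mirrors the treatment being
  *preferred* music — the same material plays session after session. An
  earlier design drew a fresh pattern per session; that made every test
  session's music acoustically novel, a harder condition than the procedure
  it emulates, and `session_spec(music_pattern_seed = NULL)` still provides
  it.
* **Default schedule** (per participant, 10 sessions): five no-music
  sessions with engagement targets spread 20–65% (baseline-like) and five
  music sessions at 0.5–16% (treatment-like), the near-zero sessions
  deliberately exercising the kappa-deflation regime.

What the generator does *not* emulate: real speech (events are harmonic
stacks, far more stereotyped than actual vocalizations), sibling voices and
other confounding speakers, varying microphone distance, room acoustics, or
copyrighted music. Passing the synthetic recovery tests therefore shows the
pipeline is implemented correctly and can recover engagement under
controlled, favorable acoustics — it does not certify performance on real
home recordings, where the published experience is markedly noisier.

## Kappa deflation at low engagement

A detector with *constant* per-second error rates produces per-session
kappas that depend strongly on the session's engagement. At 0.3% engagement,
an all-negative prediction differs from the observer by 0.3 percentage
points of engagement yet scores kappa 0. The expectation can be computed
directly from the 2×2 table: with sensitivity 0.7 and false-alarm rate 0.02,
expected kappa rises steeply from near 0 at sub-1% prevalence to about 0.73
around 30%, then declines mildly toward 60% (kappa is symmetric in the two
classes, so the rare-negative regime deflates it too). Two consequences
shape the package's diagnostics:

* the deflation correlation (per-session kappa vs observed engagement) is
  demonstrated on an engagement grid concentrated at the low end
  (0.5–60%), which is also where treatment sessions live;
* a detector with *zero* false alarms shows no deflation at low prevalence
  (precision stays perfect), so `simulate_detector()` defaults to a small
  nonzero false-alarm rate (0.02) alongside the 0.3 miss rate.

## Problem sizes and numerical choices

The standard synthetic evaluation uses 8 participants × 10 sessions × 120 s
(9,600 labelled seconds, 80 trained models for the hybrid protocol), a size
chosen so a full protocol run completes in minutes on one CPU while leaving
every participant enough sessions for the within/hybrid designs. Where only
label streams matter the sizes grow, since no audio is synthesized: 300-s
sessions for placement calibration, and 24 sessions of 600 s per participant
for the deflation analysis (near-zero-engagement sessions need enough
seconds to carry more than a couple of positive labels, or the per-participant
correlation drowns in sampling noise).

Degenerate inputs are handled explicitly rather than silently: sessions
shorter than one second featurize to a 0-row matrix; one-class training
labels are an error (class balancing is impossible — merge more data);
undefined kappa propagates as `NA` with counts; correlations over constant
vectors return `NA`. Probabilities are clamped to `[1e-12, 1 − 1e-12]`
inside the cross-entropy, and logits to ±500 inside the sigmoid, so training
never produces non-finite loss from saturation.
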