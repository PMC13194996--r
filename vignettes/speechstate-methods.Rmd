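---
title: "Detecting speech state from sparse intracranial recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting speech state from sparse intracranial recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A practical speech brain–computer interface needs a gating front-end: a
detector that decides, continuously and causally, whether its user is
currently speaking. `speechstate` implements such a detector for sparse
depth-electrode (stereo-EEG-like) recordings that sample both cortical and
subcortical gray matter, together with everything required to study it:
a synthetic-data generator that emulates a sentence-reading paradigm, the
preprocessing and channel-selection chain, a compact 1-D convolutional
classifier, causal continuous decoding, robustness ablations, and a
gradient-saliency analysis of regional contributions.

Because clinical recordings of this kind cannot be redistributed, the
package treats the synthetic generator as a first-class module: every
stage of the analysis is exercised end-to-end on generated cohorts whose
statistical structure mirrors what the real task produces.

# The paradigm and the generator

Each trial has three phases: preparation (1.5–2.0 s, uniform), a reading
phase in which the sentence must be completed within 10 s, and an
inter-trial rest of 2–3 s. A session is 100 unique sentences, each read
three times (300 trials). `generate_schedule()` lays these trials on a
global timeline; each sentence receives 8–14 syllables (drawn once per
sentence so repetitions agree), syllables last 0.20–0.35 s, and with
probability 0.3 two consecutive syllables are separated by a 0.2–0.6 s
intra-sentence pause. A short latency of 0.1–0.3 s separates the fixation
offset from the first syllable onset. These sentence-level values are not
dictated by the protocol; they were chosen once as typical of fluent
Mandarin sentence reading (roughly ten characters at three to four
syllables per second) and are exposed in `paradigm_config()`.

The binary ground truth follows the labeling rule used throughout the
package: *rest* is any time before the first syllable onset of a trial
(preparation, pre-speech latency) or after the last syllable offset
(inter-trial rest); *speech* spans first syllable onset through last
syllable offset inclusive, **including** intra-sentence pauses. A gating
module should stay engaged across pauses — disengaging mid-sentence would
truncate fluent communication — so pauses are deliberately speech.

## Signal model

Per channel, `synthesize_recording()` builds

\[
x(t) \;=\; b(t) \;+\; \sum_k a\,\sin(2\pi f_k t + \phi_k)
\;+\; g(t)\,\mathrm{snr}\,\bigl(w_{lf}\,u(t) + w_{hga}\,v(t)\bigr),
\]

* `b(t)`: unit-variance \(1/f^\alpha\) Gaussian background
  (default \(\alpha = 1\)), synthesized by frequency-domain shaping. Real
  recordings have no single canonical noise model; a power-law background
  is the standard stand-in for local field potentials.
* Powerline harmonics at 50/100/150/200 Hz with random phase and
  amplitude 0.15 relative to the background, so the notch bank has real
  work to do.
* On *informative* channels only: `u` is 2–30 Hz band-limited noise
  (low-frequency state modulation) and `v` is 75–150 Hz band-limited noise
  (high-gamma power increase), both unit variance, weighted 0.6/0.8 and
  gated by `g(t)` — the ground-truth state smoothed by a 50 ms
  raised-cosine ramp. Physiological transitions are not step functions,
  and instantaneous gating would produce filter-ringing artifacts that a
  classifier could exploit; the ramp removes that shortcut.
* `snr` scales the gated components relative to the unit-sd background.

An audio *envelope* (one raised-cosine bump per syllable) is emitted in
place of an acoustic waveform — enough to drive the labeling rule and the
audio–neural independence screen, which only needs a synchronized
envelope. No speech synthesis is attempted.

What the generator does **not** emulate: spatial correlation between
channels (each channel's noise is independent), volume conduction,
artifacts (movement, epileptiform events), non-stationarity across a
session, and any real phonetic content. Passing tests on synthetic
cohorts therefore demonstrates that the *pipeline machinery* is correct
and that the detector can exploit state-dependent spectral structure when
present — not that a given clinical recording will reach the same
accuracy.

# Preprocessing

`filter_signal()` implements two feature streams: *broadband* (4th-order
Butterworth low-pass at 200 Hz) and *high-gamma* (band-pass 75–150 Hz),
each followed by notch biquads (RBJ design, Q = 30) at 50/100/150/200 Hz.
Offline segmentation uses zero-phase forward–backward filtering; the
continuous-decoding path uses strictly causal forward-only filtering so
that no future sample can influence a prediction. Filter family and order
are the package's choice — the protocol names only the cutoffs.

Z-scoring is per channel, with statistics frozen on the **training-split
samples** and re-applied to evaluation and streaming data; computing them
on the full recording would leak evaluation statistics into the scaling.
Zero-variance channels are flagged and removed, never silently passed.
Standardization happens after filtering; the two orders differ only by a
scale factor per channel, but standardizing last keeps the classifier's
input variance exactly one under either signal mode.

Decimation from 2,000 Hz to 500 Hz keeps every 4th sample after the
200 Hz low-pass. The 500 Hz rate nominally requires content below 250 Hz;
the retained band (≤ 200 Hz) satisfies it, so no additional anti-alias
filter is inserted.

`label_and_segment()` slices each trial into non-overlapping 100 ms
windows (50 samples at 500 Hz). Windows that straddle the speech
onset or offset boundary are dropped from the discretized dataset: the
labeling rule gives them no clean class, and in streaming mode the
final-time-point rule resolves them anyway. Because speech and rest
windows are imbalanced (utterances outlast the rest phases), the majority
class is randomly subsampled (seeded) within each split so that the 50%
chance baseline is exact.

# Channel selection

For every channel, each trial contributes one paired observation: mean
4–150 Hz power after speech onset versus the immediately preceding
silence, matched in duration (capped at the available pre-onset span).
Power is the mean of Welch PSD bins (1 s Hann windows, 50% overlap —
ample resolution for a 4 Hz lower band edge) in linear units; a
two-sided paired t-test per channel is corrected with Benjamini–Hochberg
FDR at 5%. Degenerate channels whose paired differences are all zero get
`p = 1` by convention. Regardless of significance, white-matter contacts
and occipital (visual) channels are excluded, with the reason recorded.
The subjective visual-inspection screen used on real data is replaced by
the objective zero-variance rule; no re-referencing is applied.

# The classifier

A deliberately plain 1-D CNN over the `(C, 50)` segment:

| stage | operation | output channels | temporal length (T = 50) |
|---|---|---|---|
| stem | conv k15, stride 4, same-pad | 32 | 13 |
| block 1 | conv k7 + maxpool 2 + dropout 0.1 | 64 | 6 |
| block 2 | conv k5 + maxpool 2 + dropout 0.1 | 128 | 3 |
| block 3 | conv k5 + maxpool 2 + dropout 0.1 | 256 | 1 |
| head | global average pool + linear | 1 logit | — |

ReLU follows every convolution; there is no normalization layer. Same
padding is forced by arithmetic: valid convolutions cannot carry T = 50
through three pooling stages. The max-pool kernel is 2 (only the stride
is dictated); dropout sits after each pool, not after the stem. The
single sigmoid logit with binary cross-entropy is the two-class softmax's
cheaper twin.

Training (all defaults in `train_config()`): Adam, lr 0.001,
\(\beta_1 = 0.9\), \(\beta_2 = 0.999\), weight decay 0.005, batch 48,
cosine decay \(lr(e) = 0.5\,lr_0\,(1 + \cos(\pi e/E))\) with `e` counted
from 0, at most 80 epochs, early stopping after 5 epochs without
validation-loss improvement, best-validation checkpoint returned. The
engine is the package's own C++ implementation (im2col + BLAS GEMM
forward/backward in double precision); its gradients are verified against
central finite differences in the test-suite, which is the contract that
also underwrites the saliency map.

Two choices were genuinely open:

* **Validation set.** The protocol early-stops "on the validation set"
  without defining one. Using the held-out evaluation sentences would let
  model selection peek at the test data, so 15% of the *training*
  sentences are carved out for early stopping instead.
* **Class balance.** How imbalance was handled is unstated; balanced
  subsampling (above) makes the chance level exactly 50%, which every
  comparison in the package assumes.

# Splitting and evaluation

Splits are at the sentence level: all repetitions of a sentence land on
one side, 80/20, seeded. `assert_no_leakage()` runs inside every
experiment, not only in tests. Discretized accuracy is the fraction of
correctly classified balanced evaluation segments.

Continuous decoding slides a 100 ms window in 5 ms steps across each
held-out trial. At 500 Hz a 5 ms step is 2.5 samples, which cannot be
honored exactly; window starts live on the 5 ms grid in *seconds* and are
mapped to the nearest sample, producing alternating 2/3-sample hops that
preserve the printed step and the 95% overlap on average. Each window is
classified independently (threshold 0.5, no smoothing or hysteresis) and
scored against the ground-truth state at its **final** time point, so
labeling is causal. Because adjacent windows share 95% of their span,
window-level accuracies are massively dependent; accuracy is therefore
aggregated *per sentence trial* and only distributions over sentences are
reported, never pooled window counts. A tripwire test poisons all samples
beyond a cutoff with NaN and verifies predictions before the cutoff are
unchanged.

`compare_conditions()` wraps the standard tests used on such results:
one-way ANOVA with Tukey HSD, two-way fixed-effects ANOVA with
interaction plus Bonferroni-corrected simple effects, one-sample t-tests
against the 50% baseline, and Welch two-sample t-tests with Bonferroni
correction across strata. Zero-variance degenerate inputs return `p = 1`
rather than erroring.

# Ablations and saliency

`run_ablation()` retrains the full pipeline from scratch per condition
and seed, with identical split seeds across conditions so comparisons are
paired. Three kinds: random channel dropout (fractions 0/0.1/0.3/0.5,
removed set redrawn per seed), exclusion of the classical speech-region
set (angular gyrus; superior, middle, inferior frontal gyri; superior,
middle, inferior temporal gyri; precentral gyrus), and restriction to one
anatomical domain (cortical or subcortical).

`compute_saliency()` scores channel `c` as
\(\zeta(c) = \frac{1}{T}\sum_t |\partial \mathcal{L} / \partial x_{t,c}|\),
the time-averaged absolute gradient of each segment's own binary
cross-entropy loss with respect to its input, averaged across segments
and min–max normalized to [0, 1] across channels. Three unstated details
are fixed as follows: the average runs over all evaluation-split segments
of *both* classes (a `classes` flag exposes speech-only or rest-only
averaging), normalization is within a run across channels, and regional
aggregation is the unweighted mean over a region's channels, ranked
descending. Gradients are computed with dropout disabled.

# Numerical choices and degenerate inputs

* Filters: Butterworth order 4 everywhere; notch Q = 30; zero-phase
  filtering pads with odd-symmetric signal extensions (about three filter
  lengths) to suppress edge transients.
* The 1/f synthesis and the test-suite's Hilbert-envelope oracle pad FFTs
  to highly composite lengths; mixed-radix FFTs degrade to quadratic cost
  on awkward lengths.
* Ties in max-pooling resolve to the earlier sample; BH rejection uses
  the step-up rule's `<=` at the boundary.
* Welch windows shrink to the signal length for short intervals; trials
  shorter than one window are skipped with a warning in continuous mode,
  as are trials without syllables during segmentation.
* All randomness flows through explicit seeds; a global experiment seed
  derives per-stage sub-seeds by stage-name hashing, so any stage can be
  reproduced in isolation. Training is bit-reproducible for a fixed seed
  under single-threaded BLAS.

# Problem sizes used in the shipped analyses

The package's own verification runs use scaled-down cohorts chosen to
keep a full run on a laptop-class single core comfortable while leaving
the claims' structure intact:

* High-SNR reference cohort (accuracy and continuous decoding): 30
  sentences × 3 repetitions, 40 channels of which 12 are informative at
  snr 2, 30-epoch budget with early stopping, 5 sentence splits.
* Region-exclusion cohort: as above, but informative channels split 6/6
  between the classical speech regions and other gray matter.
* Directional continuous-decoding property: 8 sentences × 2 repetitions,
  10 channels (4 informative, snr 2), 20 sentence splits.

At snr 2 the gated components triple a channel's variance during speech,
which is an easy regime by design: these runs verify machinery and
direction (above chance; continuous below discretized; robustness to
exclusion), not clinical effect sizes.

# Known limitations

* Channels are statistically independent in the generator; nothing about
  cross-channel redundancy on real montages is tested.
* The region labels attached to synthetic channels are bookkeeping, not
  anatomy: regional saliency rankings on synthetic data validate the
  aggregation arithmetic only.
* The continuous decoder classifies each window independently; no
  temporal smoothing, hysteresis, or latency calibration is provided.
* EDF import/export is not implemented; the package's own on-disk
  container (`write_recording()`) and TSV annotations are the interchange
  formats.
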