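---
title: "Simulating and decoding motor-imagery EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mibmi)
```

mibmi implements a complete motor-imagery (MI) brain–machine-interface
analysis chain over synthetic sensorimotor EEG: a generator with
event-related desynchronization/synchronization (ERD/ERS) structure, the
standard preprocessing chain, three classifier families, fivefold
cross-validation, information-transfer-rate and spectral-SNR metrics, and a
replay of the online sliding-window control scheme against a cued game.
This vignette explains the underlying models, every tunable parameter that
matters, and the design decisions that were genuinely open — so that a
reader can judge what a passing test suite does and does not establish.

## The synthetic EEG model

No public recordings accompany the protocol this pipeline targets, so the
generator is a first-class, tested component. Each recording (one trial) is
a six-channel signal at 500 Hz over the montage Fz, C5, C3, C4, C6, POz
(reference Cz, mastoid ground), built per channel as a sum of:

* **1/f background** — Gaussian noise spectrally shaped to
  `f^(-background_exponent)` (default exponent 1), at `noise_scale` µV RMS
  per channel (default 10 µV), plus a *shared* pink process at
  `common_scale` (default 8 µV) added identically to every channel. The
  shared term stands in for reference and far-field activity common to the
  montage.
* **Band-limited rhythms** — for each band (mu 8–12 Hz, beta 18–26 Hz,
  alpha 8–13 Hz) a unit-RMS band-filtered white-noise process per channel,
  scaled by a baseline amplitude (`oscillation_amplitudes`, defaults mu
  6 µV, beta 4 µV, alpha 5 µV) and by the active class's (channel, band)
  multiplier. Band-filtered noise rather than pure sinusoids: real
  sensorimotor rhythms have finite bandwidth, and Welch peaks of pure tones
  would be unrealistically sharp for ERD estimation tests.
* **Volume-conduction leakage** — each channel additionally records
  `leakage` (default 0.55) times every other channel's rhythm. This is the
  generator's stand-in for source mixing at the scalp: per-channel
  band-power contrasts remain sign-correct but are diluted, while the
  mixture stays linearly separable, so a *learned spatial filter* can demix
  what per-channel features see only through the blur. Without this term,
  per-channel band power is an essentially sufficient statistic and no
  spatial method could be expected to dominate.
* optionally, a shared stationary alpha-band process
  (`common_alpha_amp`, default 0) and mains interference (off by default).

Class structure enters only through amplitude multipliers
(`class_profile`): multipliers < 1 are ERD, > 1 ERS, and envelopes
cross-fade over 0.5 s at class boundaries so no discontinuity or filter
ring-down contaminates transition windows (the 2 s onset discard makes the
exact fade length immaterial downstream). The default somatotopy: left-hand
imagery suppresses mu/beta on C4 and C6 (multiplier `erd = 0.6`),
right-hand on C3 and C5, foot imagery suppresses Fz mu/beta with mild
(0.84) bilateral mu involvement, and eyes closure amplifies POz alpha by
`ers = 2.5`. All of it is overridable per class, channel and band.

The ERD depth 0.6 and ERS gain 2.5 follow conventional effect sizes;
`noise_scale`, `common_scale` and `leakage` were then fixed — once — so
that the four-class task at 4 s windows sits near 90 % separability for the
best classifier: non-trivial, but clearly above chance. These values are
the package's study conditions; tests do not move them.

**What the generator does not emulate:** eye-blink/EMG artifacts,
electrode drift and impedance changes, non-stationarity across a session,
realistic forward-model geometry (leakage is uniform, not
distance-dependent), inter-subject variability beyond the noise seed, and
the subject-side dynamics of performing imagery on cue. Passing tests
therefore establish that the *machinery* is correct and that the documented
directional effects hold under a plausible signal model — not that any
accuracy number transfers to human recordings.

Determinism: a recording is a pure function of (`sim_config$seed`,
`subject_id`, `trial_id`). Identical inputs give byte-identical output.

## Preprocessing

The conditioning chain is: decimate 500 → 250 Hz (causal order-8
Butterworth anti-alias low-pass with cutoff at a quarter of the target
rate — far above the 33 Hz analysis edge, far below the new Nyquist — then
keep every second sample); band-pass 4–33 Hz with a third-order Butterworth;
global rescale; segmentation into labeled windows.

Three decisions deserve justification:

* **Causal (forward-only) filtering by default.** The online path must be
  causal, and offline cross-validation is meant to estimate the online
  system, so the offline default matches it. Zero-phase filtering is
  available behind `zero_phase = TRUE` but off by default.
* **Rescaling scope.** The amplitude normalization maps the global minimum
  and maximum *of a whole recording, all channels jointly* to [−1, 1] — not
  per window and not per channel — because inter-channel amplitude ratios
  are exactly what a spatial classifier exploits. Rescaling happens before
  windowing. In cross-validation the extrema are pooled over the training
  recordings only and applied frozen to the held-out recording (and to the
  streaming path), so no look-ahead leaks in.
* **Discard placement.** 2 s are dropped at the start of every class
  segment (reaction time to the cue). With 60 s segments, 4 s windows and
  50 % overlap this yields the bookkeeping the protocol implies: 28 windows
  per segment, 112 per trial, 560 per subject, 2240 per four-subject
  session. Window start times are quantized to whole samples.

## Spectral features

`welch_psd` is an averaged modified periodogram: demeaned Hann-tapered
segments, 50 % overlap, one-sided density scaling (its integral approximates
the variance). The 512-point Hann convention is used for classification
features; for 1 s and 2 s windows (250/500 samples < 512) the taper is
clipped to the window and zero-padded to a 512-point FFT so the frequency
grid — and hence the feature layout — is identical across window lengths.
`psda_features` concatenates, per window, each channel's PSD bins inside
4–33 Hz (59 bins × 6 channels = 354 features). The exact overlap and
detrending conventions of this estimator family vary between
implementations; 50 % overlap and per-segment demeaning are the
conventional defaults and are exposed as arguments.

`erd_ers_map` reports, per (class, channel, band), the relative change of
mean band power against a reference. The protocol has no rest condition, so
the default reference is the pooled mean of the other three classes
(configurable). Band power integrates the Welch grid by the trapezoid rule.

## Classifier families

Three families, trained per subject:

* **Spatial-first CNN.** Layer 1 is a spatial convolution — a kernel
  spanning all 6 channels with temporal extent 1 — producing 12 virtual
  channels; then two temporal convolution blocks (kernel 9, 16 maps, batch
  normalization, ELU, average pooling by 4, dropout 0.5), a dense softmax.
  About 10⁴ parameters. The spatial-first constraint is the family's
  defining property: the network can cancel shared components and demix
  leaked sources *before* any nonlinearity.
* **Temporal-first ("standard") CNN.** The generic-CNN baseline at the same
  budget and training protocol, with the one defining difference: no kernel
  spans channels anywhere in the convolutional stack (depthwise layer 1
  with 2 kernels per channel, per-map trunk); channels meet only at the
  dense layer. This isolates learned spatial filtering as the experimental
  variable. It can still weigh per-channel envelope features — which is
  why its deficit is one of estimation efficiency, not of principle.
* **PSDA + cubic SVM.** The 354-dimensional Welch feature vector,
  standardized column-wise on training folds only, into a multiclass SVM
  with a degree-3 polynomial kernel (one-vs-one). Regularization constant
  defaults to 1 (exposed); the kernel offset is 1.

CNN training: minibatch Adam (step 5·10⁻³) on categorical cross-entropy,
batch 64, at most 200 epochs with early stopping when validation accuracy
has not improved for 20 consecutive epochs; the best-validation-epoch
weights are returned. Training is exactly reproducible from its seed (C++
RNG drives initialization, shuffling and dropout). The step size and
dropout rate were chosen for this compact architecture by watching
convergence on the default task; dropout at 0.5 in particular is what makes
a model trained on four recordings generalize to a fifth rather than
memorize realizations. Batch-norm uses batch statistics in training and
running averages at inference.

There is no deep-learning framework dependency: forward, backward
(verified against finite differences in the test suite), Adam and batch
normalization are implemented in compiled code inside the package.

## Evaluation

`crossvalidate` implements fivefold leave-one-recording-out validation: in
fold *i*, recording *i* is held out and the other four train the model; all
data-dependent preprocessing (rescale extrema, feature standardization) is
fitted on the training recordings only. For the CNNs the held-out recording
also serves as the early-stopping monitor, mirroring the stated training
protocol; note this makes the per-fold accuracy a mildly optimistic
estimate (a known property of early stopping on the evaluation fold, and of
the protocol as described). Both the pooled confusion matrix and fold-wise
mean ± SEM are reported, since "overall accuracy" can mean either.

The information transfer rate uses the Wolpaw form

ITR = [log₂N + A·log₂A + (1−A)·log₂((1−A)/(N−1))] · 60/w  bits·min⁻¹,

with the limits 0·log₂0 ≡ 0 at A ∈ {0, 1}. The published rendering of this
formula is typographically garbled; this reading reproduces all seven
"calculated" comparison-table entries to two decimals from their printed
(N, A, w) triples, which the acceptance script recomputes. Values below
zero are returned as-is (no clipping), and the chance case A = 1/N gives
exactly 0.

Alpha SNR: 5 s windows of a 4 Hz-high-passed recording; amplitude spectrum
as the square root of a Welch estimate with the taper spanning the full
window, zero-padded to a 4096-point FFT ("4096-point Hann" is read as the
FFT length, since a 4096-sample taper cannot fit a 2500-sample window; a
shorter `seg_len` implements the other reading). A_signal is the largest
amplitude in 8–13 Hz; the exclusion zone around the detected peak is
± 2 Hz (unstated in the source; exposed as `exclusion_hz`), and A_noise is
the largest remaining amplitude in 4–40 Hz. SNR = 10·log₁₀((A_signal/A_noise)²).

## The online control scheme and the game

`stream_classify` replays the online path: causal decimation and band-pass
with persistent filter state, rescaling with the extrema frozen at training
time, and a 4 s window classified every 0.16 s (ticks quantized to whole
samples). Because the preprocessing is causal and time-invariant, filtering
the whole recording once is sample-for-sample identical to processing tick
by tick.

`confirm_commands` emits a confirmed instruction when two consecutive
classifications agree. For runs longer than two the pairing is
non-overlapping — A,A,A,A confirms twice — so one agreeing pair is never
double-counted, while sustained intent re-confirms every 0.32 s.

`run_game` scores a 240 s session: after a 1 s delay a colored cube spawns
every 4 s (Blue → feet, Green → left hand, Red → right hand, Yellow → eyes
closed, colors uniform), and each cue accepts responses until the next
spawn. The first confirmed command *matching* the cue clears it for one
point; mismatching commands are recorded but do not consume the cue. The
alternative reading — first command of any class resolves the cue — is
untenable with a sliding window: immediately after a cue change every
window is still dominated by the previous class, so the first confirmed
commands necessarily carry it and every cue would resolve wrong. Scoring by
first *match* reproduces the described gameplay, where a well-trained
subject misses only a few cues per session.

## Problem sizes used by the tests

The test suite regenerates all data. Full-protocol sizes (60 s segments)
are used where the check is about the protocol itself (window bookkeeping,
ERD/ERS recovery, window-length trend, the closed-loop game); the
CNN-family comparison runs on a scaled session (30 s segments, 2 s windows,
epoch budget 25) — chosen once as a size at which the directional contrast
is stable across seeds — and the fold-mechanics tests use miniature
recordings. The vignette-level claims match what those tests compute:
directional orderings and recovery rates, never the human-subject accuracy
figures, which depend on recordings this package does not have.

## Known limitations

* The generator's leakage is a uniform mixing coefficient, not a forward
  model; the spatial CNN's measured advantage quantifies the value of
  learned spatial filtering *under this model*, not its magnitude on real
  scalp data.
* The synthetic alpha peak is modest (a few dB over background at POz), so
  SNR values are not comparable to electrode-validation figures measured on
  humans.
* CNN determinism is exact for a fixed seed and platform; across BLAS/
  compiler combinations, accuracy may differ in the last few decimals.
* The EDF writer/reader covers the 16-bit continuous EDF+ subset this
  pipeline produces (equal per-signal rates, one annotations channel); it
  is not a general EDF library.
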