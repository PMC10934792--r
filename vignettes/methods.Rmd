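---
title: "Adaptive time-frequency segment optimization for motor-imagery EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive time-frequency segment optimization for motor-imagery EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitfopt)
```

## The problem

Imagining a movement suppresses the power of sensorimotor EEG rhythms —
event-related desynchronization (ERD) in the alpha (8–12 Hz) and beta
(14–30 Hz) bands — and a two-class motor-imagery brain–computer interface
decodes *which* movement was imagined from *where* and *how strongly* that
suppression occurs. The decisive nuisance parameter is the time window and
frequency band on which features are computed: ERD timing and frequency vary
substantially across subjects, so a fixed choice (the conventional 8–30 Hz
band over a fixed post-cue window) is systematically suboptimal for many
individuals.

`mitfopt` treats the segment — the rectangle
`(fstart, fwidth, tstart, twidth)` in the time–frequency plane — as a
4-dimensional hyperparameter and optimizes it per subject with a sparrow
search algorithm (SSA), scoring each candidate by the cross-validated
accuracy of the full downstream decoder: correlation-based channel selection
(CCS), regularized common spatial patterns (RCSP), and an RBF-kernel SVM.

## The decoding chain

### Time–frequency segmentation

A candidate segment is applied by cropping trials to
`[tstart, tstart + twidth)` and bandpass-filtering to
`[fstart, fstart + fwidth]` (crop first, then filter; with zero-phase
reflect-padded filtering the difference from the reverse order is confined
to the window edges).

### Channel selection (CCS)

Channels engaged by the same task share signal. Each trial is z-scored per
channel, its channel-by-channel Pearson correlation matrix is computed, and
channels are ranked by the mean of their matrix row (diagonal included; a
flag excludes it). The top `Ns` channels of each of `Nt` trials cast votes,
and the `Ns` most-voted channels are kept. Vote ties are resolved by the
higher mean row-correlation across the voting trials, then by channel index,
making selection deterministic. Inside cross-validation, selection uses the
fold's training trials only — never the validation trials.

### Feature extraction (RCSP)

For each class, two per-trial covariance estimators are mixed with weight
$\alpha$ and averaged over the class's $N_{tr}$ trials:

$$P_{class} = \frac{(1-\alpha)\sum_i E_i E_i^\top / \mathrm{tr}(E_i E_i^\top)
  + \alpha \sum_i \mathrm{cov}(E_i^\top)}{N_{tr}},$$

then shrunk toward a scaled identity with weight $\beta$:

$$Q_{class} = (1-\beta) P_{class} + \frac{\beta\,\mathrm{tr}(P_{class})}{N_{ch}} I.$$

The shrinkage preserves the trace and guarantees positive definiteness for
$\beta > 0$, so the generalized eigenproblem
$Q_1 \omega = \lambda Q_2 \omega$ is always well posed. It is solved by
Cholesky whitening of $Q_2$ followed by a symmetric eigendecomposition —
not by the classic composite-covariance shortcut, whose
$\lambda_1 + \lambda_2 = 1$ identity no longer holds once the covariances
are regularized. The filter bank keeps the eigenvectors of the $m$ largest
and $m$ smallest eigenvalues; features are
$f = \ln \mathrm{var}(\omega_{2m}^\top E)$ per trial, with the sample
variance (mean removed, $1/(n-1)$) and no cross-filter normalization.

Conventions fixed here because they matter for reproducibility: the class
with the smaller label maps to $Q_1$; eigenvectors are scaled to
$\omega^\top Q_2 \omega = 1$ with their first nonzero component positive.
Defaults $m = 2$, $\alpha = 0.4$, $\beta = 0.01$.

### Classification

An RBF-kernel SVM with penalty `C` and kernel width `g` grid-searched over
$\{10^{-3}, \dots, 10^{3}\}$ (both axes) by stratified five-fold
cross-validation; ties prefer the smaller `C`, then the smaller `g`.
Features are standardized inside each fit using the training portion only —
the RBF kernel is scale-sensitive and log-variance features are unbounded.
Inside the optimizer's fitness evaluations a 3×3 subgrid
($\{0.01, 1, 100\}$) bounds the cost (`svm$fast_grid`, on by default); the
final model is always tuned on the full 7×7 grid.

## The optimizer

SSA maintains `n = 10` position vectors for `itermax = 20` iterations.
After each evaluation the population is sorted by fitness; the best 70%
are *producers* (broad search around themselves), the rest *scroungers*
(following the best producer), and each iteration an independently drawn
20% of the population additionally act as *scouts* (escaping their
position). Fitness is `1 −` mean cross-validated accuracy, so the lowest
fitness marks the best segment.

Decisions the algorithm's published description leaves open, fixed here:

* **Normalized coordinates.** The search runs in $[0,1]^4$ and positions
  are decoded to physical segments affinely. The producer update is
  multiplicative ($x \leftarrow x\, e^{-i/(\alpha\,\mathrm{itermax})}$); on
  heterogeneous physical units (Hz vs seconds) that contraction would act
  unequally per dimension. Normalization makes it isotropic. Positions are
  clipped to the box after every update, and the decode map is total: every
  raw position yields a valid segment, with widths floored at 2 Hz and
  0.5 s so filters never degenerate.
* **Random-scalar scoping.** The safety threshold `ST ~ U(0.5, 1)` is drawn
  once per run; the alarm `R2 ~ U(0,1)` once per iteration; the producer
  scalars (`alpha`, `Q`) once per sparrow per iteration; the scout scalars
  (`beta`, `K`) once per scout. This matches the granularity of the
  original SSA reference implementation.
* **Scout direction `K`** is drawn from `U(-1, 1)` (it encodes a direction;
  the one-sided `(0,1)` variant is available via `ssa$k_sign_range`).
* **Scrounger branch rank** is the rank within the scrounger block, with
  the worse half (`i > n2/2`) leaving and the better half following; the
  follow step adds the *mean over dimensions* of
  `r_j |x_j - x_{best,j}|`, `r_j ~ U(-1,1)`, as a scalar to all dimensions.
* **Elitism.** The best position ever evaluated is returned even if the
  population drifts away, which makes the best-fitness history
  non-increasing by construction. $\varepsilon = 10^{-10}$ guards the scout
  rule's division.
* **Parsimony tie-break.** Cross-validated accuracy is a step function with
  resolution `1/n_train`, and on strongly separable data many segments tie
  at the optimum. Among all evaluated segments with exactly the best
  fitness, the pipeline returns the one with the smallest
  time × frequency area: a broader segment that classifies no better
  carries no additional evidence, and compact subject-specific segments are
  the point of the search. The fitness value itself is never modified.
* **Failure as worst fitness.** A degenerate candidate (too few samples
  after cropping, or fewer channels than `2m` after selection) scores
  fitness 1 with a warning rather than raising, keeping the optimizer total
  over the box.

## The pipeline protocol

A single seed controls everything: the stratified train/test split
(default 7:3), both fold assignments, and the optimizer stream, so runs are
bit-reproducible. Within each fitness evaluation the training partition is
segment-filtered once and split into five stratified folds; channel
selection and RCSP are fit per fold on the fold-training side only. The
held-out partition lives behind an access guard that counts reads: it is
touched exactly once, by the final evaluation after optimization ends, and
every `pipeline_result` carries that record. Duplicate positions (the
producer contraction often parks several sparrows on a box corner) hit a
fitness cache keyed on coordinates rounded at `1e-6`.

The split ratio is configurable (`split$train_frac`) because the final
evaluation ratio is a property of each dataset's protocol; the synthetic
default keeps 7:3 for both phases.

## The synthetic generator

Real motor-imagery EEG cannot ship with a package; the generator produces
the *phenomenology the method exploits* with a known ground truth, so
recovery is measurable:

* per-channel background: $1/f^\gamma$ noise ($\gamma = 1$), made by
  spectral shaping of white noise and scaled analytically (not
  empirically) to `background_scale` (default 10 µV sd);
* a band-limited "sensorimotor rhythm" on every channel, independent
  across channels (default 6 µV RMS in the planted band, 9–13 Hz);
* ERD: inside the planted window (default 0.5–2.5 s) the rhythm's
  amplitude on the informative channels of the trial's class is scaled by
  $\sqrt{1 - d}$, `erd_depth` $d$ defaulting to 0.8 — a power attenuation,
  not a phase-locked response, with 100 ms raised-cosine ramps so window
  edges do not trivially cue the crop;
* optionally, a shared band-limited component on a channel subset
  (`common_mode_channels`) plants a mutually correlated group for
  channel-selection tests.

Defaults describe one session: 100 trials per class, 16 channels at 125 Hz
(the rate the reference datasets are analyzed at after downsampling), 4-s
trials, two informative channels per class. What the generator deliberately
omits: volume-conduction channel covariance, artifacts (EOG/EMG),
non-stationarity across the session, and ERS rebound. Passing recovery
tests therefore shows the chain is correct and sensitive at realistic
signal-to-noise, not that it handles every property of scalp recordings.

## Numerical choices

* Zero-phase filtering is implemented as reflect-padded (odd reflection,
  one second of padding) frequency-domain multiplication by the *squared*
  magnitude response of the analog prototype — order-4 Butterworth for
  bandpass, a Q = 30 biquad for the notch. This is the asymptotic response
  of forward–backward IIR filtering, has exactly zero phase and no startup
  transient, and vectorizes over all trials and channels at once; the
  optimizer performs hundreds of filterings per run, which makes this the
  difference between seconds and minutes. Passband flatness (1 dB) and
  stopband attenuation (≥ 20 dB at the reference frequencies) are verified
  by test.
* Resampling is polyphase FIR (anti-aliased) at the rational ratio of the
  rates.
* Time windows are half-open `[start, end)`; sample indices are
  `round((t - t0) * sfreq)` with round-half-away-from-zero.
* The fixture format stores little-endian 32-bit floats, row-major
  `[trial, channel, sample]`, with shape and metadata in `meta.json` —
  byte-identical across platforms for the same data and adequate for EEG
  dynamic range.
* Problem sizes in the verification suite are chosen to keep a full check
  of all properties, including twenty full pipeline runs, within tens of
  minutes on a single core: synthetic sessions of 200 trials × 16
  channels × 500 samples, and 100-instance batches for the algebraic
  oracles.

## Known limitations

* Binary classification only; the reference multi-class extensions
  (one-vs-rest CSP, joint diagonalization) are out of scope.
* Channel selection assumes task-relevant channels are *mutually*
  correlated; a single informative but isolated channel would rank low.
* The CV-accuracy fitness is noisy at small sample sizes; with fewer than
  ~10 trials per class, stratified folds degenerate and the optimizer's
  preferences are dominated by fold noise.
* Segment recovery is identifiable only to the resolution accuracy
  provides: when several segments classify perfectly, the parsimony
  tie-break picks the smallest, which may still be wider or narrower than
  the generative truth.
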