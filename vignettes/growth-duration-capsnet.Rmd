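---
title: "Methods: Raman crest imaging and capsule-network classification of rice growth duration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman crest imaging and capsule-network classification of rice growth duration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramancaps)
```

## The problem

Japonica rice varieties bred for the three accumulated-temperature zones of
Heilongjiang differ in growth duration (GD): roughly 144 days for the first
zone, 134–135 for the second, 124–126 for the third. GD tracks the
starch/sugar make-up of the mature grain, and those carbohydrates dominate
a grain's Raman spectrum. `ramancaps` classifies a grain's zone class
(labels 0/1/2 = third/first/second zone) from a single Raman spectrum
acquired over 200–3400 cm⁻¹ at 1.4 cm⁻¹ resolution (2286 grid points;
multiple co-added scans are averaged into one trace and counted in
`n_scans`).

## Preprocessing: zero-phase filtering and the difference signal

Raw grain spectra sit on a large, smooth fluorescence baseline with an
arbitrary overall intensity scale. The pipeline first removes the scale by
per-spectrum min–max normalization to [0, 1] (no normalization formula is
canonical here; min–max is the simplest map that removes the dimensional
influence and keeps the downstream difference well-scaled; it is applied
*before* filtering so both filter passes see a bounded signal). The
normalized trace `x` is then filtered with a zero-phase Butterworth
low-pass:

* **First pass** (order `N = 2`, normalized cutoff `wn = 0.002`): with so
  low a cutoff the output `y1` can follow only baseline-scale structure,
  so `X = x − y1` retains the crests and drops the baseline. The identity
  `x = X + y1` holds to the last bit by construction and is asserted in
  the tests.
* **Second pass** (`N = 2`, `wn = 0.03`) applied to `X` removes the
  small clutter that the difference step exposes, giving the crest signal
  `Xs` from which windows are cut.

`wn` is a fraction of the Nyquist frequency (`wn = 2·f_c / f_s`). The
coefficients come from `signal::butter()` (DC gain verified to 1 within
1e-9). The zero-phase pass itself is implemented in the package: each end
of the signal is extended by odd reflection over `3(N+1)` points, the
recursive filter is run with steady-state initial conditions scaled to the
first sample, and the procedure is repeated on the reversed signal. This
reproduces the widely used scientific-Python `filtfilt` behavior to
~1e-13, keeps constants exactly constant, and leaves no phase lag.

**Edge behavior.** Any forward–backward recursive filter has edge
transients that decay with the filter's time constant (roughly 1/`wn` in
samples — hundreds of points at `wn = 0.002`). Zero-phase symmetry and
reversal-commutation therefore hold to 1e-8 only for features far from the
boundaries; the property tests place their features accordingly, and the
seven reference crests of real spectra all sit hundreds of points from the
axis ends.

`detect_peaks()` (local maxima filtered by topographic prominence,
default threshold 5% of the signal maximum) is provided as a diagnostic to
confirm that the difference signal exposes the expected crests; the
production pipeline never re-discovers crests per sample but uses the
seven fixed reference shifts.

## Crest windows and the 28 × 28 pseudo-image

Seven crests — 480, 865, 941, 1129, 1339, 1461, 2910 cm⁻¹, attributed to
starch (amylum) and sugars — are mapped to their nearest grid points (ties
to the lower index). Around each center, 56 points before and 55 after are
cut from `Xs` (112 points per window, 784 per sample). Two conventions are
not fixed by the construction itself and are therefore fixed here and
documented:

* *Forward/backward*: "forward" is toward lower indices. Any 56/55 split
  yields 112 points; this one is frozen so images are reproducible.
* *Layout*: each window's four 28-point segments become four adjacent
  image **columns** (window `w` occupies columns `4(w−1)+1 … 4w`, segment
  points run down the rows). The quarter-window segmentation aligns the
  crest's rise, peak, and fall in neighboring columns, which is what lets
  a 2-D classifier exploit crest shape and offset.

Folding is a pure rearrangement: `unfold_image()` inverts it exactly, and
the pixel multiset equals the multiset of the 784 extracted values (both
asserted in tests). No per-image rescaling is applied afterwards — pixels
keep the normalized-signal scale.

## The capsule network

With a 28 × 28 input: Conv1 (valid 9 × 9 convolution, stride 1, ReLU,
default 256 channels) gives a 20 × 20 grid; the primary capsule
convolution (valid 9 × 9, stride 2, default 256 channels) gives 6 × 6.
Only valid (unpadded) convolutions reproduce these grid sizes. The primary
channels regroup into 8-D capsule vectors — 32 types × 6 × 6 positions =
1152 capsules — each squashed by

v = (‖s‖² / (1 + ‖s‖²)) · s/‖s‖,

which preserves direction and maps length monotonically into [0, 1). Every
primary capsule `i` predicts every class capsule `j` through a learned
16 × 8 matrix, `û_{j|i} = W_ij u_i` (no bias on these transforms — the
simplest scheme consistent with the linear prediction map; the
convolutions do carry biases). Routing by agreement is *full-link*
(appropriate for a small-sample problem — every output routes to all
possible parents): log-priors `b` start at 0, and each of 3 iterations
computes `c = softmax(b)` over classes, `s_j = Σ_i c_ij û_{j|i}`,
`v_j = squash(s_j)`, `b_ij += v_j·û_{j|i}`; after the last squash `b` is
left alone. Three iterations and 16-D class capsules are the canonical
choices for this architecture; both are exposed in the configuration.

The classification rule is `argmax_j ‖v_j‖` (vector length as class
evidence). The loss is the separation margin loss with `m⁺ = 0.9`,
`m⁻ = 0.1`, `λ = 0.5` — the canonical companion of this architecture, and
the natural choice here because no reconstruction decoder is part of the
model, so none is implemented.

Gradients are computed analytically, including through the unrolled
routing loop (the coupling coefficients are *not* treated as constants),
and the whole backward pass is validated against central finite
differences in the test suite. Degenerate points are handled by
continuity: `squash(0) = 0` with zero Jacobian, and zero-length class
vectors contribute zero length-gradient.

## Training protocol

* Stratified split: exactly 8 randomly drawn (seeded) test samples per
  variety; with the reference per-variety counts (32, 34, 32, 34, 34, 34,
  33) this reproduces the 177-train / 56-test partition of 233 samples.
  Only the counts of the original partition are knowable, so the selection
  is random-stratified.
* Optimizer: Adam, learning rate 1e-3, batch size 16 (standard small-data
  choices, all configuration-exposed), 160 epochs
  by default with "early stopping" realized as the configured epoch
  budget. Per-epoch mean loss and train/test accuracy are recorded at full
  precision (logged rounded to integer percent).
* Outlier screening is available (per-variety robust z on total pixel
  intensity; images beyond `z_threshold` robust SDs from the variety
  median are dropped, with zero spread meaning "any deviating image") but
  **off by default**: the screening rule applied to the original material
  is not documented anywhere, and this robust-z rule is a stand-in that
  does not claim to reproduce that selection.
* Everything is seeded: initialization, shuffling, and the split derive
  child seeds via `derive_seed()`, and reruns are bit-identical on one
  machine.

## The synthetic generator

`generate_spectrum()` emulates the morphology the pipeline assumes: a
smooth baseline (low-order polynomial plus a sinusoid of ~2560 cm⁻¹
wavelength — far above the first filter's cutoff wavelength, so the
baseline lands in `y1`), Gaussian crests of sd 12 cm⁻¹ at the seven
reference shifts (typical Raman bandwidths; the crest fits comfortably in
a 112-point ≈ 156 cm⁻¹ window), lognormal between-sample amplitude jitter
(CV 0.08), white noise (sd 0.02 on the baseline-scale 0.4), and clipping
at zero. Classes differ by ~20% multiplicative gaps on the starch/sugar
crests 480/941/1129 cm⁻¹ (class 0 × 1.0, class 2 × 1.2, class 1 × 1.44),
leaving the 2910 cm⁻¹ CH-stretch the largest band in every class so
min–max normalization does not erase the class signal. The default
dataset is 7 varieties × 35 grains = 245 spectra with the variety-to-zone
label map (140/35/70 per class).

What the generator does **not** emulate: cosmic-ray spikes, detector
etaloning, wavenumber miscalibration, within-variety biological structure
beyond amplitude jitter, or the true variance of real grain spectra. A
passing synthetic benchmark therefore demonstrates that the pipeline can
recover a class signal of this geometry and strength — not that it attains
any particular accuracy on real grains.

## Scale of the validation runs

The test suite and the acceptance script train a reduced-width network
(Conv1 32 channels, primary 64 channels = 8 capsule types, 288 primary
capsules) for 40 epochs on the default 245-sample dataset; these sizes
keep a full run in the minutes range on a single CPU while leaving the
architecture (grids, capsule regrouping, routing) untouched. The full
256/256 geometry is exercised in shape and initialization tests. On the
default synthetic dataset (master seed 7, split seed 1, training seed 1)
the reduced network reaches 94.6% held-out accuracy by epoch 36; the
negative control with identical class profiles stays at the majority-class
rate (~57%), confirming the classifier learns the injected crest signal
rather than an artifact. A smaller three-seed experiment in the test suite
shows held-out accuracy rising with the between-class amplitude gap.

## Known limitations

* Real-data accuracy is out of reach by design: the package ships no
  instrument data, and synthetic results do not transfer.
* The spectrum parser handles delimited-text (PRN-style) files only; no
  vendor binary formats.
* Single-channel 28 × 28 inputs are assumed throughout the network; other
  window geometries imply other image sides and are validated but not
  otherwise tested.
* Training is plain single-threaded CPU; the reduced widths exist because
  the full 256-channel network is an order of magnitude slower, not
  because the architecture changes.
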