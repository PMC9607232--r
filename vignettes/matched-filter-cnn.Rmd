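---
title: "Shallow 1D CNNs as matched filters: model, simulator and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shallow 1D CNNs as matched filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfcnn)
```

## The model

A matched filter (MF) is the optimal linear detector for a known,
time-limited waveform observed in additive white Gaussian noise: correlate
the observation with the template, sample the correlator's maximum, and
decide.  A shallow one-dimensional CNN computes the same pipeline.  With
valid-mode stride-1 correlation, a Conv1D layer with kernel $h_i$ produces
the correlation trace

$$y_i[n] = \sum_{j=1}^{N_K} x[n+j-1]\, h_i[j], \qquad n = 1,\dots,N_S-N_K+1,$$

global max pooling (GMP) samples each trace's peak (conferring shift
invariance), and a softmax fully connected (FC) layer turns the pooled
peaks into class probabilities — a bank of matched filters with a learned
decision stage.  The full univariate stack is

> Conv1D($N_F$ filters, kernel $N_K$, no bias) → BatchNorm → tanh → GMP →
> FC($N_C$, no bias) → softmax,

trained with categorical cross-entropy.  Because tanh is strictly
increasing it commutes with GMP, so the activation never changes the
ranking of correlation peaks; batch normalization applies one affine map
per channel and likewise preserves per-channel peak locations.  For
multichannel (sensor) input the convolution is *depthwise*: each channel
owns $N_F$ kernels and no cross-channel mixing happens before the FC
layer, so each feature map remains a bona fide matched-filter output for
one channel.  An optional kernel-size-1 linear convolution in front
expands $N_\mathrm{sen}$ raw sensor channels into $N_{ch}$ learned channel
mixtures, and a training-time-only additive Gaussian noise layer
(`noiseStd`, default 0.2 in post-normalization units) regularizes and
pushes the depthwise kernels toward strong templates.

Three weight-constraint variants expose the interpretation:

* **frozen_preassigned** — the ground-truth templates are written into the
  convolution kernels and the FC weights are fixed to the identity; only
  the normalization parameters adapt.  The network *is* the classical MF.
* **diagonal_constrained** — the FC matrix is masked to its diagonal; the
  network must solve the task through the one-to-one kernel-to-class
  mapping, learning only per-kernel scales.
* **unconstrained** — everything is learned; interpretation then *checks*
  whether the kernels recovered the templates.

## The synthetic simulator

The simulator produces the ground-truth conditions under which the
interpretation is testable.  Each class is defined by one template of
`LT = 64` samples; an example is the template placed at an integer shift
drawn uniformly (inclusive) from $[0, N_S-L_T]$ inside an `NS = 128`
zero sample window, plus white Gaussian noise over the *whole* window with
variance equal to a fraction `P` of the template power.  An optional
`PTestExtra` adds further noise to the test split only, emulating a
train/deployment covariate shift.  Splits are stratified per class
(64/16/20 by default) by largest-remainder apportionment, so per-split
class proportions deviate from the global proportions by less than one
example.

Two design choices deserve explanation:

* **Equal-energy templates.**  Templates are normalized to unit RMS
  amplitude rather than unit peak.  The classical argmax-of-peaks decision
  rule is only template-optimal under equal-energy signaling; with
  unequal energies a broad kernel's cross-correlation can exceed a narrow
  template's autocorrelation energy and the learning-free oracle would
  misclassify even noiseless input.  Unit power also makes `P` exact: the
  injected noise variance is numerically `P`.
* **A frequency-disjoint family.**  The five built-in generators —
  Gaussian pulse, Hann-windowed sinusoid burst (5 cycles), bipolar
  triangle waveform (2 cycles), linear chirp (8→14 cycles), square burst
  (7 cycles) — occupy essentially disjoint spectral bands.  The tests
  verify that every pair stays well below 0.95 peak |NCC|.  Low mutual
  correlation is what gives the matched-filter receiver (and hence the
  CNN) comfortable decision margins; families with strongly overlapping
  bands (e.g. a unimodal triangular pulse next to a Gaussian pulse, or a
  chirp sweeping through the sinusoid's band) make the final fraction of
  a percent of accuracy disproportionately hard to learn, because by the
  time the kernels approach the templates, the tanh inputs saturate and
  kernel gradients are damped by $1-\tanh^2 \approx 0$.

What the simulator does *not* emulate about real sensor data: amplitude
jitter, non-Gaussian or colored noise, template morphology variation
within a class, unsegmented streams, and class overlap.  Passing the
synthetic suite therefore demonstrates correctness of the mechanism (the
CNN can recover and exploit matched filters), not performance on any real
recording; the HAR adapters exist precisely to connect the model to real
raw formats.

## Training protocol

Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$),
minibatch 512, categorical cross-entropy; the learning rate is multiplied
by 0.9 when the validation loss fails to improve for 5 consecutive epochs
("reduce on plateau" — the stated decay read as plateau scheduling, since
a per-epoch exponential decay would contradict "adaptive"); early stopping
monitors the validation loss with patience 20; the returned model is the
best-validation-accuracy checkpoint.  Per-epoch validation metrics are
computed in inference mode (running normalization statistics, momentum
0.99), as a deployed model would behave.  The forward/backward pass and
the optimizer are implemented in the package itself (the univariate path
additionally in compiled code, verified against the plain R implementation
to $10^{-12}$ and against finite-difference gradients to $10^{-6}$), so
the training dynamics are fully inspectable.

Problem sizes used by the shipped experiments: the reference synthetic
condition is $N = N_C = N_F = 4$, $N_K = L_T = 64$, $N_S = 128$,
$NT_i = 10{,}000$ (40,000 examples), $P = 0.5$; the stress condition is
1,875 examples with per-class counts 1000/500/250/125, $P = 1$ plus an
extra 100% test-only noise.  The printed counts 1000/500/250/125 are used
for the stress condition because they are the only four-class halving
series totalling 1,875, mirroring the 10000/5000/2500/1250 series of the
moderate-size condition.  The shipped acceptance experiments run the full
200-epoch budget, stopping once validation accuracy reaches its ceiling
(`stopAtPerfect`); the stop records the perfect epoch before triggering,
so it saves computation without affecting any measured quantity.

Two checkpoint rules are provided: `"best_val_accuracy"` (default —
the deployment-safe rule) and `"last"` (the early-stopped final model).
The choice interacts with interpretation: once validation accuracy
saturates at 1.0, the best-accuracy checkpoint freezes at the *first*
ceiling epoch, so the returned kernels reflect early training; kernel
waveforms keep evolving afterwards even though accuracy cannot improve.
Under either rule, learned kernels on the reference condition show the
characteristic mixture of strong and weak template matches rather than
uniformly near-perfect recovery — classification pressure alone does not
force exact template recovery once the classes are separated.

A caution on convergence-epoch measurements: reaching *exactly* 100% on
6,400 validation examples is an extreme event time, dominated by when the
last borderline example flips.  With the square configuration
$N_F = N_C = 4$ its seed-to-seed spread is wide; widening the filter bank
($N_F > N$, as the larger configurations of the original experiment grid
do) makes convergence dramatically faster and more stable, at the price
of redundant learned kernels.

## Numerical choices

* Correlation is valid-mode, stride 1, no padding: with $N_S = 128$,
  $N_K = 64$ the 65-lag trace covers exactly the generator's shift range.
* Argmax ties (classifier and oracle) break toward the lowest class id.
* Batch normalization uses $\varepsilon = 10^{-3}$, momentum 0.99, biased
  batch variance; "identity normalization" sets the running variance to
  $1-\varepsilon$ so the inference-time scale is exactly 1, which is what
  makes the frozen variant *numerically* identical to the classical MF.
* tanh saturates to exactly 1.0 in double precision for arguments above
  about 19.  Saturated peaks produce exact argmax ties, so the
  MF-equivalence property is asserted on inputs whose correlation peaks
  stay inside the representable range; this is a floating-point artifact,
  not a property of the model.
* Kernel-template similarity is the peak |NCC| over lags with at least
  half-overlap, each window rescaled to unit energy; `minOverlap = 1`
  restricts the search to full containment.  Matching is sign-agnostic
  because the tanh symmetry lets a model learn amplitude-reversed
  templates; the per-kernel argmax assignment mirrors per-filter visual
  comparison, with a greedy one-to-one option for the square case.
* The strong/weak threshold $\tau = 0.8$ is reported alongside raw NCC
  values so conclusions do not hinge on it; white-noise kernels stay
  below it with probability > 0.99 (Monte-Carlo, checked in the tests).
* The flat model export stores every parameter as IEEE-754 float32 after
  a JSON manifest; no quantization.  The HAR depth multipliers shipped in
  `harConfig()` ($N_F = 30$ for the 9-channel and 6-channel smartphone
  configurations, 40 for the 3-channel one with the linear expander) are
  reconstructed from the published parameter budgets of the corresponding
  architectures (e.g. $36 + 1251 \cdot 30 = 37{,}566$ for the 9-channel
  configuration including normalization statistics and depthwise biases).

## HAR adapters

Raw-format loaders cover: pre-segmented fixed-width inertial text (9
channels × 128 samples, distributed train/test partition), the raw
`user,activity,timestamp,x,y,z;` accelerometer dialect (52-sample windows,
25% overlap, stratified 64/16/20 — the inconsistent published split
percentages summing to 104% are resolved to 64/16/20), and per-trial CSV
motion files (128-sample windows, trial-based 75/25 partition; overlap is
unstated for this dataset and defaults to 0).  Windows are 0-based,
half-open, stride `round(window * (1 - overlap))`; a window spanning a
label change is dropped under the strict rule (majority vote available).
No normalization is applied outside the model: the network ingests raw
sensor units, the first normalization layer is part of the model.  A
fixture writer emits each raw layout from the template library (values
rounded to 6 decimals so text round-trips are exact), which is how the
loaders and the end-to-end multivariate path are tested without
downloads.

## Known limitations

* The trainer is single-threaded CPU code; it is sized for the shipped
  experiments (tens of thousands of 128-sample windows), not for
  large-scale training.
* Matched filtering inherits the MF's weakness for highly correlated
  classes; the model is intentionally shallow and this package does not
  implement deeper stacked variants.
* The flat float32 export is this package's own portable format, not a
  framework interchange format.
* `epochsToPerfect` tests exact equality with 1.0; on validation sets of
  several thousand examples this is a demanding criterion and its epoch
  index has noticeable seed-to-seed variance.
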