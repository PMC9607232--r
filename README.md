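# mfcnn

Matched-filter tools for shallow 1D convolutional classifiers.

## The problem

Time-series classifiers built from one wide-kernel Conv1D layer, global
max pooling (GMP) and a softmax output layer are routinely treated as
black boxes, yet they compute something classical: a **matched-filter
(MF) receiver**.  Valid-mode correlation of the input with each kernel is
the MF correlator, GMP is the peak-sampling stage, and the FC/softmax
layer is the decision stage.  This package makes the reading operational
for anyone studying lightweight interpretable time-series models (e.g.
wearable-sensor human activity recognition, where sub-150 KB models run
on phones):

* a **synthetic simulator** with known ground truth — class-defining
  templates (64 samples), uniform random shifts inside a 128-sample
  window, additive white Gaussian noise at a controlled fraction `P` of
  the template power, configurable class balance, mixed-class labeling
  and stratified splits;
* the **classical MF classifier** as a learning-free oracle,
  `y[n] = Σ_j x[n+j]·h[j]`, peak sampling, argmax decision;
* **MF CNN architectures** — univariate
  (Conv1D→BatchNorm→tanh→GMP→FC/softmax) and multivariate depthwise (per
  sensor channel kernels, optional 1×1 channel expander, training-time
  Gaussian noise) — with three weight-constraint variants
  (template-frozen, diagonal-FC, unconstrained) and a self-contained
  Adam training engine (compiled core for the univariate path);
* **interpretation tools** that match learned kernels to ground-truth
  templates by sign- and shift-agnostic peak normalized
  cross-correlation, flag strong vs weak kernels, and dump FC weight
  heatmaps;
* **HAR adapters** for three raw wearable-sensor formats plus synthetic
  raw-format fixtures so the whole pipeline runs without downloads;
* a **float32 flat model export** for the edge-footprint size check.

## Worked example

```r
library(mfcnn)

## 4 classes x 10,000 examples, 50% noise-to-signal, 64/16/20 split
spec <- SyntheticDatasetSpec(N = 4, NT = 10000, P = 0.5, seed = 11)
ds   <- buildDataset(spec)
ds
#> SyntheticDataset: 40000 examples x 128 samples
#>   N=4 templates, P=0.50, Nc=4 classes, seed=11
#>        label
#> split      1    2    3    4
#>   test  2000 2000 2000 2000
#>   train 6400 6400 6400 6400
#>   val   1600 1600 1600 1600

## learning-free matched-filter oracle
scoreMatrix(ds, filterBank(templates(ds)), "val")$accuracy
#> [1] 1

## train the unconstrained MF CNN (NF = NC = 4, NK = 64)
cfg <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4, seed = 11)
fit <- trainModel(buildUnivariate(cfg), ds,
                  hyperparams(seed = 11, maxEpochs = 60))
max(fit$history$val_acc)          # validation accuracy ceiling
#> [1] 1
epochsToPerfect(fit$history)      # first epoch at 100%
#> [1] 21

## do the learned kernels recover the generating templates?
matchKernelsToTemplates(extractKernels(fit$model), templates(ds))
#>   kernelId bestTemplateId       ncc sign bestShift strength
#> 1       f1              1 0.7800568    1        17     weak
#> 2       f2              2 0.9810940    1        -7   strong
#> 3       f3              4 0.7250305    1         1     weak
#> 4       f4              1 0.7282945    1        -2     weak
```

Each learned kernel aligns with a generating template at substantial
normalized cross-correlation (`ncc`), with a mixture of *strong* and
*weak* learning across filters — a perfectly accurate classifier does not
need perfect templates, only enough of each to separate the classes.
Quantifying that mixture (sign- and shift-agnostic, since the tanh
symmetry makes an amplitude-reversed template an equivalent solution) is
the matched-filter reading of what the CNN learned.

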