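#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' TemplateSignal: a time-limited class-defining waveform
#'
#' A template signal is the known, time-limited waveform that defines one
#' class of the synthetic classification problem.  The same waveform doubles
#' as a matched-filter kernel.  Templates are normalized to unit RMS
#' amplitude (equal energy across the family), the classical equal-energy
#' signaling convention under which peak-correlation argmax detection is
#' optimal and the noise-to-signal fraction `P` is well defined.
#'
#' @slot templateId integer index of the template within its bank (1-based).
#' @slot family name of the generating waveform family.
#' @slot samples numeric vector of length `L_T` (arbitrary amplitude units).
#' @slot power mean squared amplitude of `samples` (1 after normalization).
#'
#' @seealso [makeTemplates()]
#' @export
setClass("TemplateSignal",
  representation(
    templateId = "integer",
    family = "character",
    samples = "numeric",
    power = "numeric"
  )
)

setValidity("TemplateSignal", function(object) {
  msg <- NULL
  if (!all(is.finite(object@samples))) {
    msg <- c(msg, "template samples must all be finite")
  }
  if (length(object@samples) < 1L) {
    msg <- c(msg, "template must contain at least one sample")
  }
  if (length(object@power) != 1L || !is.finite(object@power) ||
      object@power <= 0) {
    msg <- c(msg, "template power must be a single positive number")
  }
  if (is.null(msg)) TRUE else msg
})

#' SyntheticDatasetSpec: full description of a synthetic dataset
#'
#' Captures every knob of the simulator: the number of templates `N`, the
#' template length `L_T`, the example length `NS`, per-template example
#' counts `NT`, the noise-to-signal fraction `P` (noise power as a fraction
#' of template power), the template-to-class label map, the split fractions
#' and the master RNG seed.  `PTestExtra` is an additional noise fraction
#' applied to the test split only (distribution-shift stress testing).
#'
#' @slot N integer, number of templates.
#' @slot LT integer, template length in samples.
#' @slot NS integer, example length in samples (`NS >= LT`).
#' @slot NT integer vector of per-template example counts (length `N`).
#' @slot P numeric, noise-to-signal power fraction (>= 0).
#' @slot labelMap integer vector of length `N` mapping template i to a class
#'   label in `1..Nc`; classes may group several templates (mixed classes).
#' @slot splitFractions numeric length-3 vector (train, val, test) summing
#'   to 1.
#' @slot PTestExtra numeric, extra noise fraction for the test split.
#' @slot seed integer master RNG seed.
#'
#' @seealso [datasetSpec()], [buildDataset()]
#' @export
setClass("SyntheticDatasetSpec",
  representation(
    N = "integer",
    LT = "integer",
    NS = "integer",
    NT = "integer",
    P = "numeric",
    labelMap = "integer",
    splitFractions = "numeric",
    PTestExtra = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticDatasetSpec", function(object) {
  msg <- NULL
  if (object@NS < object@LT) msg <- c(msg, "NS must be >= LT")
  if (length(object@NT) != object@N) {
    msg <- c(msg, "NT must have one count per template")
  }
  if (any(object@NT <= 0L)) msg <- c(msg, "all NT counts must be positive")
  if (length(object@labelMap) != object@N) {
    msg <- c(msg, "labelMap must have one label per template")
  }
  nc <- max(object@labelMap)
  if (nc > object@N) msg <- c(msg, "number of classes cannot exceed N")
  if (!setequal(unique(object@labelMap), seq_len(nc))) {
    msg <- c(msg, "every class label in 1..Nc must have at least one template")
  }
  if (length(object@splitFractions) != 3L ||
      any(object@splitFractions <= 0) ||
      abs(sum(object@splitFractions) - 1) > 1e-9) {
    msg <- c(msg, "splitFractions must be 3 positive numbers summing to 1")
  }
  if (object@P < 0) msg <- c(msg, "P must be non-negative")
  if (object@PTestExtra < 0) msg <- c(msg, "PTestExtra must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticDataset: labeled shifted-noisy examples with stratified splits
#'
#' Extends [SummarizedExperiment::SummarizedExperiment].  The single assay
#' `"signal"` holds one example per column (`NS` rows); `colData` carries the
#' class `label`, generating `templateId`, integer `shift` of the template
#' start within the example, and the `split` assignment
#' (train/validation/test).  The generating spec and template bank travel in
#' `metadata()` and via [datasetSpec()] / [templates()].
#'
#' @seealso [buildDataset()], [exampleMatrix()], [addTestNoise()]
#' @export
setClass("SyntheticDataset", contains = "SummarizedExperiment")

setValidity("SyntheticDataset", function(object) {
  msg <- NULL
  cd <- colData(object)
  need <- c("label", "templateId", "shift", "split")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  }
  if (!"signal" %in% assayNames(object)) {
    msg <- c(msg, "assay 'signal' is required")
  }
  spec <- metadata(object)$spec
  if (!is.null(spec) && is(spec, "SyntheticDatasetSpec")) {
    if (nrow(object) != spec@NS) {
      msg <- c(msg, "assay row count must equal spec NS")
    }
    if (ncol(object) != sum(spec@NT)) {
      msg <- c(msg, "example count must equal sum(NT)")
    }
  }
  if (all(need %in% colnames(cd))) {
    if (!all(cd$split %in% c("train", "val", "test"))) {
      msg <- c(msg, "split must be one of train/val/test")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' FilterBank: matched-filter kernel bank
#'
#' One correlation kernel per class template, stored as the columns of a
#' `NK x n_kernels` matrix, with aligned class ids.
#'
#' @slot kernels numeric matrix, one kernel per column.
#' @slot classIds integer vector of class labels aligned with the columns.
#'
#' @seealso [filterBank()], [mfClassify()]
#' @export
setClass("FilterBank",
  representation(kernels = "matrix", classIds = "integer")
)

setValidity("FilterBank", function(object) {
  msg <- NULL
  if (ncol(object@kernels) < 1L) msg <- c(msg, "bank must hold >= 1 kernel")
  if (length(object@classIds) != ncol(object@kernels)) {
    msg <- c(msg, "classIds must align with kernel columns")
  }
  en <- colSums(object@kernels^2)
  if (any(en == 0)) msg <- c(msg, "every kernel must have nonzero energy")
  if (!all(is.finite(object@kernels))) msg <- c(msg, "kernels must be finite")
  if (is.null(msg)) TRUE else msg
})

#' MFDecision: output of the classical matched-filter classifier
#'
#' @slot predictedClass integer class id (argmax of peak scores, ties broken
#'   toward the lowest class id).
#' @slot peakScores named numeric vector of per-kernel maximum correlation.
#'
#' @seealso [mfClassify()]
#' @export
setClass("MFDecision",
  representation(predictedClass = "integer", peakScores = "numeric")
)

setValidity("MFDecision", function(object) {
  ps <- object@peakScores
  if (length(ps) < 1L) return("peakScores must be nonempty")
  best <- which(ps == max(ps))[1L]
  if (object@predictedClass != best) {
    return("predictedClass must be the argmax of peakScores (lowest-id ties)")
  }
  TRUE
})

#' ModelConfig: matched-filter CNN architecture description
#'
#' @slot NS integer input length (samples per segment).
#' @slot Nsen integer number of input sensor channels (1 for univariate).
#' @slot Nch integer number of model channels after the optional
#'   kernel-size-1 linear channel expansion (equals `Nsen` without it).
#' @slot NF integer filters per channel (depth multiplier).
#' @slot NK integer convolution kernel length.
#' @slot NC integer number of classes.
#' @slot variant `"frozen_preassigned"`, `"diagonal_constrained"` or
#'   `"unconstrained"`.
#' @slot useInputLinear logical, instantiate the kernel-size-1 channel
#'   expander in front of the depthwise stack.
#' @slot noiseStd numeric, training-time additive Gaussian noise standard
#'   deviation in post-normalization units (multivariate stack only).
#' @slot zeroBias logical, fix convolution/FC biases at zero (matched-filter
#'   fidelity; the default everywhere).
#' @slot secondBatchNorm logical, keep the batch-normalization layer after
#'   the depthwise convolution.
#' @slot seed integer initialization seed.
#'
#' @seealso [modelConfig()], [buildUnivariate()], [buildMultivariate()]
#' @export
setClass("ModelConfig",
  representation(
    NS = "integer", Nsen = "integer", Nch = "integer", NF = "integer",
    NK = "integer", NC = "integer", variant = "character",
    useInputLinear = "logical", noiseStd = "numeric", zeroBias = "logical",
    secondBatchNorm = "logical", seed = "integer"
  )
)

setValidity("ModelConfig", function(object) {
  msg <- NULL
  if (object@NK > object@NS) msg <- c(msg, "NK must be <= NS")
  if (object@NF < 1L) msg <- c(msg, "NF must be >= 1")
  if (object@NC < 2L) msg <- c(msg, "NC must be >= 2")
  if (!object@variant %in% c("frozen_preassigned", "diagonal_constrained",
                             "unconstrained")) {
    msg <- c(msg, "unknown variant")
  }
  if (object@useInputLinear && object@Nch < object@Nsen) {
    msg <- c(msg, "channel expansion requires Nch >= Nsen")
  }
  if (!object@useInputLinear && object@Nch != object@Nsen) {
    msg <- c(msg, "without the linear expander, Nch must equal Nsen")
  }
  if (object@noiseStd < 0) msg <- c(msg, "noiseStd must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' MFModel: a (possibly trained) matched-filter CNN
#'
#' Holds the architecture description, all layer parameters (convolution
#' kernels, batch-normalization parameters and running statistics, FC weight
#' matrix), the set of trainable parameter names, and the optional diagonal
#' mask applied to the FC weights by the `diagonal_constrained` variant.
#'
#' @slot config the [ModelConfig-class].
#' @slot arch `"univariate"` or `"multivariate"`.
#' @slot params named list of numeric arrays (layer weights and batch
#'   normalization state).
#' @slot trainable character vector of the parameter names the optimizer may
#'   update.
#' @slot fcMask optional 0/1 matrix multiplied into the FC weights
#'   (diagonal-constrained variant), or `NULL`.
#' @slot trained logical flag.
#'
#' @seealso [buildUnivariate()], [buildMultivariate()], [trainModel()],
#'   [predictProbs()]
#' @export
setClass("MFModel",
  representation(
    config = "ModelConfig",
    arch = "character",
    params = "list",
    trainable = "character",
    fcMask = "ANY",
    trained = "logical"
  )
)

setValidity("MFModel", function(object) {
  msg <- NULL
  if (!object@arch %in% c("univariate", "multivariate")) {
    msg <- c(msg, "arch must be 'univariate' or 'multivariate'")
  }
  if (!all(object@trainable %in% names(object@params))) {
    msg <- c(msg, "trainable names must be a subset of params")
  }
  if (!is.null(object@fcMask)) {
    if (!identical(dim(object@fcMask), dim(object@params$fc_w))) {
      msg <- c(msg, "fcMask must match the FC weight shape")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Hyperparams: training protocol settings
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 0.001, learning rate multiplied by 0.9 on a validation-loss plateau,
#' minibatch size 512, up to 200 epochs with early stopping on the
#' validation loss, and the checkpoint with the best validation accuracy
#' returned.
#'
#' @slot initialLr numeric initial learning rate.
#' @slot lrDecayFactor numeric multiplicative decay on plateau.
#' @slot lrPatience integer epochs without validation-loss improvement
#'   before decaying the learning rate.
#' @slot batchSize integer minibatch size.
#' @slot maxEpochs integer epoch budget.
#' @slot earlyStopPatience integer epochs without validation-loss
#'   improvement before stopping (`Inf`-like large value disables).
#' @slot checkpointRule `"best_val_accuracy"` or `"last"`.
#' @slot stopAtPerfect logical; stop once validation accuracy reaches 1.0
#'   (recorded first, so convergence-epoch measurements are unaffected).
#' @slot seed integer seed for shuffling and noise streams.
#'
#' @seealso [hyperparams()], [trainModel()]
#' @export
setClass("Hyperparams",
  representation(
    initialLr = "numeric", lrDecayFactor = "numeric", lrPatience = "integer",
    batchSize = "integer", maxEpochs = "integer",
    earlyStopPatience = "integer", checkpointRule = "character",
    stopAtPerfect = "logical", seed = "integer"
  )
)

setValidity("Hyperparams", function(object) {
  msg <- NULL
  if (object@initialLr <= 0) msg <- c(msg, "initialLr must be positive")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor > 1) {
    msg <- c(msg, "lrDecayFactor must be in (0, 1]")
  }
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be positive")
  if (!object@checkpointRule %in% c("best_val_accuracy", "last")) {
    msg <- c(msg, "checkpointRule must be 'best_val_accuracy' or 'last'")
  }
  if (is.null(msg)) TRUE else msg
})

#' EvalReport: confusion matrix and derived classification metrics
#'
#' Accuracy is the fraction of correct predictions; per-class F1 uses the
#' one-vs-rest binarization `F1 = 2TP / (2TP + FP + FN)`; `macroF1` is the
#' unweighted mean of per-class F1.
#'
#' @slot confusion integer `NC x NC` matrix, rows = true class, columns =
#'   predicted class.
#' @slot accuracy numeric in `[0, 1]`.
#' @slot perClassF1 numeric vector of per-class F1 scores.
#' @slot macroF1 numeric, unweighted mean of `perClassF1`.
#' @slot counts data.frame of per-class one-vs-rest TP/TN/FP/FN.
#'
#' @seealso [evaluateModel()], [evalReport()]
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    perClassF1 = "numeric",
    macroF1 = "numeric",
    counts = "data.frame"
  )
)

setValidity("EvalReport", function(object) {
  msg <- NULL
  if (nrow(object@confusion) != ncol(object@confusion)) {
    msg <- c(msg, "confusion matrix must be square")
  }
  if (object@accuracy < 0 || object@accuracy > 1) {
    msg <- c(msg, "accuracy must lie in [0, 1]")
  }
  if (any(object@perClassF1 < 0 | object@perClassF1 > 1, na.rm = TRUE)) {
    msg <- c(msg, "F1 scores must lie in [0, 1]")
  }
  if (is.null(msg)) TRUE else msg
})
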