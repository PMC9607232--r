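## Classical matched-filter classifier: valid-mode sliding correlation,
## peak sampling, argmax decision.  The learning-free oracle the CNN is
## interpreted against.

#' Construct a matched-filter bank
#'
#' @param tpls list of [TemplateSignal-class] objects, or a numeric matrix
#'   with one kernel per column.
#' @param classIds class label per kernel; defaults to the template ids.
#' @return a [FilterBank-class].
#' @examples
#' bank <- filterBank(makeTemplates(4, 64))
#' @export
filterBank <- function(tpls, classIds = NULL) {
  if (is.list(tpls)) {
    kernels <- templateMatrix(tpls)
    if (is.null(classIds)) {
      classIds <- vapply(tpls, slot, integer(1), "templateId")
    }
  } else {
    kernels <- as.matrix(tpls)
    if (is.null(classIds)) classIds <- seq_len(ncol(kernels))
  }
  new("FilterBank", kernels = kernels, classIds = as.integer(classIds))
}

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("FilterBank: %d kernels of length %d (classes %s)\n",
              ncol(object@kernels), nrow(object@kernels),
              paste(object@classIds, collapse = ", ")))
})

#' Sliding-window correlation (valid mode, stride 1)
#'
#' Computes `y[n] = sum_j signal[n + j] * kernel[j]` for every full-overlap
#' lag, i.e. the sliding dot product with no padding.  For a signal of
#' length `NS` and a kernel of length `NK` the trace has `NS - NK + 1`
#' values, covering exactly the simulator's shift range.
#'
#' @param signal numeric vector, length `NS`.
#' @param kernel numeric vector, length `NK <= NS`.
#' @return numeric correlation trace of length `NS - NK + 1`.
#' @examples
#' correlate(c(0, 1, 2, 1, 0), c(1, 2, 1))
#' @export
correlate <- function(signal, kernel) {
  NS <- length(signal)
  NK <- length(kernel)
  if (NK > NS) stop("kernel length exceeds signal length")
  if (!all(is.finite(signal)) || !all(is.finite(kernel))) {
    stop("signal and kernel must be finite")
  }
  ## full cross-correlation via convolution with the reversed kernel,
  ## trimmed to the valid lags
  full <- stats::convolve(signal, kernel, conj = TRUE, type = "open")
  full[NK:NS]
}

#' Peak of a correlation trace
#'
#' The sampling stage of the matched-filter receiver: the maximum of the
#' correlator output over all lags.
#'
#' @param trace numeric correlation trace.
#' @return the maximum value.
#' @export
peakScore <- function(trace) {
  if (length(trace) == 0L) stop("empty correlation trace")
  max(trace)
}

## peak scores of many signals (rows of X) against all kernels at once
## returns n x n_kernels matrix of per-kernel peak correlations
.peakScoreMatrix <- function(X, kernels) {
  NS <- ncol(X)
  NK <- nrow(kernels)
  if (NK > NS) stop("kernel length exceeds signal length")
  Tn <- NS - NK + 1L
  best <- matrix(-Inf, nrow(X), ncol(kernels))
  for (t in seq_len(Tn)) {
    sc <- X[, t:(t + NK - 1L), drop = FALSE] %*% kernels
    best <- pmax(best, sc)
  }
  best
}

#' Classify one signal with the matched-filter bank
#'
#' Correlates the signal with every kernel, samples each trace's peak, and
#' decides by argmax of the peak scores; ties break toward the lowest class
#' id (deterministic).  No detection threshold is used: the binary detector
#' of the classical receiver generalizes to multiclass argmax.
#'
#' @param signal numeric vector.
#' @param bank a [FilterBank-class].
#' @return an [MFDecision-class].
#' @examples
#' tpl <- makeTemplates(4, 64)
#' x <- synthesizeExample(tpl[[2]], P = 0, NS = 128, shift = 10)$values
#' mfClassify(x, filterBank(tpl))
#' @export
mfClassify <- function(signal, bank) {
  stopifnot(is(bank, "FilterBank"))
  scores <- drop(.peakScoreMatrix(matrix(signal, nrow = 1L), bank@kernels))
  names(scores) <- bank@classIds
  ## per-class best score (a class may own several kernels)
  byClass <- tapply(scores, bank@classIds, max)
  ids <- as.integer(names(byClass))
  pred <- ids[which.max(byClass)]    # which.max keeps the lowest index on ties
  new("MFDecision", predictedClass = pred, peakScores = scores)
}

setMethod("show", "MFDecision", function(object) {
  cat(sprintf("MFDecision: class %d  (peaks: %s)\n", object@predictedClass,
              paste(sprintf("%.3f", object@peakScores), collapse = ", ")))
})

#' Batch matched-filter evaluation of a dataset
#'
#' Runs the matched-filter classifier over every example of a dataset split
#' and tallies the accuracy — the learning-free reference against which the
#' trained CNN is compared.
#'
#' @param dataset a [SyntheticDataset-class] (or a numeric matrix of
#'   examples in rows, in which case `labels` must be given).
#' @param bank a [FilterBank-class].
#' @param split split to score (`NULL` = all examples).
#' @param labels integer labels when `dataset` is a plain matrix.
#' @return list with `scores` (n x kernels peak-score matrix), `predicted`
#'   (integer vector), `labels`, and `accuracy` (`NA` for empty input).
#' @export
scoreMatrix <- function(dataset, bank, split = NULL, labels = NULL) {
  stopifnot(is(bank, "FilterBank"))
  if (is(dataset, "SyntheticDataset")) {
    X <- exampleMatrix(dataset, split)
    labels <- exampleLabels(dataset, split)
  } else {
    X <- as.matrix(dataset)
  }
  if (nrow(X) == 0L) {
    return(list(scores = matrix(numeric(0), 0, ncol(bank@kernels)),
                predicted = integer(0), labels = integer(0),
                accuracy = NA_real_))
  }
  scores <- .peakScoreMatrix(X, bank@kernels)
  ids <- bank@classIds
  classes <- sort(unique(ids))
  byClass <- vapply(classes, function(cl) {
    apply(scores[, ids == cl, drop = FALSE], 1L, max)
  }, numeric(nrow(scores)))
  byClass <- matrix(byClass, nrow = nrow(scores))
  pred <- classes[max.col(byClass, ties.method = "first")]
  acc <- if (is.null(labels)) NA_real_ else mean(pred == labels)
  list(scores = scores, predicted = pred, labels = labels, accuracy = acc)
}
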