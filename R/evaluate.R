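## Evaluation metrics: confusion matrix, accuracy, one-vs-rest F1.

#' Build an EvalReport from predictions and labels
#'
#' Tallies the `NC x NC` confusion matrix (rows = true class), the overall
#' accuracy, per-class one-vs-rest TP/TN/FP/FN, per-class
#' `F1 = 2TP / (2TP + FP + FN)` and the macro (unweighted) mean F1.  A
#' class absent from both predictions and labels gets `F1 = NA` and is
#' dropped from the macro mean.
#'
#' @param predicted integer predictions in `1..NC`.
#' @param truth integer labels in `1..NC`.
#' @param NC number of classes (default: observed maximum).
#' @return an [EvalReport-class].
#' @examples
#' evalReport(c(1, 2, 2, 1), c(1, 2, 1, 1), NC = 2)
#' @export
evalReport <- function(predicted, truth, NC = max(predicted, truth)) {
  if (length(predicted) == 0L) stop("cannot evaluate an empty prediction set")
  if (length(predicted) != length(truth)) {
    stop("predictions and labels must align")
  }
  lv <- seq_len(NC)
  conf <- table(factor(truth, levels = lv), factor(predicted, levels = lv))
  conf <- matrix(as.integer(conf), NC, NC,
                 dimnames = list(true = lv, predicted = lv))
  n <- length(truth)
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  tn <- n - tp - fp - fn
  f1 <- ifelse(2 * tp + fp + fn == 0, NA_real_,
               2 * tp / (2 * tp + fp + fn))
  new("EvalReport",
      confusion = conf,
      accuracy = sum(tp) / n,
      perClassF1 = as.numeric(f1),
      macroF1 = mean(f1, na.rm = TRUE),
      counts = data.frame(class = lv, TP = as.integer(tp),
                          TN = as.integer(tn), FP = as.integer(fp),
                          FN = as.integer(fn)))
}

#' Evaluate a model on labeled examples
#'
#' Runs inference and summarizes argmax predictions against the labels.
#'
#' @param model an [MFModel-class].
#' @param x examples (matrix or array per the architecture).
#' @param y integer labels in `1..NC`.
#' @return an [EvalReport-class].
#' @export
evaluateModel <- function(model, x, y) {
  if (length(y) == 0L) stop("cannot evaluate an empty example set")
  pred <- predictClasses(model, x)
  evalReport(pred, y, NC = model@config@NC)
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.4f, macro F1 %.4f (%d examples)\n",
              object@accuracy, object@macroF1, sum(object@confusion)))
  print(object@confusion)
})
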