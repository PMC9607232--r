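## Post hoc interpretation: extract learned kernels, match them to the
## generating templates (sign- and shift-agnostic normalized
## cross-correlation), flag strong vs weak learning, dump FC weights.

#' Extract convolution kernels from a model
#'
#' @param model an [MFModel-class].
#' @return numeric matrix with one kernel per column (length `NK`), named
#'   `ch<c>.f<f>` for the multivariate layout, `f<f>` for the univariate
#'   one; ordering is channel-major, matching the depthwise feature-map
#'   concatenation.
#' @rdname extractKernels
#' @export
setMethod("extractKernels", "MFModel", function(model) {
  cfg <- model@config
  if (model@arch == "univariate") {
    K <- model@params$conv_w
    colnames(K) <- paste0("f", seq_len(ncol(K)))
  } else {
    K <- matrix(0, cfg@NK, cfg@Nch * cfg@NF)
    nm <- character(ncol(K))
    for (ch in seq_len(cfg@Nch)) {
      cols <- (ch - 1L) * cfg@NF + seq_len(cfg@NF)
      K[, cols] <- matrix(model@params$dw_w[, ch, ], ncol = cfg@NF)
      nm[cols] <- paste0("ch", ch, ".f", seq_len(cfg@NF))
    }
    colnames(K) <- nm
  }
  K
})

#' Peak normalized cross-correlation of two sequences
#'
#' Slides one sequence over the other and, at each lag whose overlap covers
#' at least `minOverlap` of the shorter sequence, computes the inner
#' product of the two overlapping windows after scaling each to unit
#' energy.  Returns the maximum absolute value, the correlation sign at
#' that peak, and the lag of `b` relative to `a`.  The measure is invariant
#' to positive rescaling of either input; `minOverlap = 1` restricts the
#' search to full-containment alignments.
#'
#' @param a,b numeric sequences with nonzero energy.
#' @param minOverlap minimum overlap as a fraction of the shorter length.
#' @return list with `ncc` (in `[0, 1]`), `sign` (-1 or +1) and `shift`
#'   (integer lag at the peak).
#' @examples
#' t1 <- makeTemplates(2, 64)[[1]]@samples
#' normalizedCrossCorrelation(t1, -t1)   # ncc 1, sign -1
#' @export
normalizedCrossCorrelation <- function(a, b, minOverlap = 0.5) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (sum(a^2) == 0 || sum(b^2) == 0) {
    stop("zero-energy input to normalized cross-correlation")
  }
  la <- length(a)
  lb <- length(b)
  minLen <- max(1L, ceiling(minOverlap * min(la, lb)))
  best <- -1
  bestSign <- 1
  bestShift <- 0L
  for (lag in seq(-(lb - 1L), la - 1L)) {
    ia <- max(1L, 1L + lag):min(la, lb + lag)
    if (length(ia) < minLen) next
    ib <- ia - lag
    aa <- a[ia]
    bb <- b[ib]
    den <- sqrt(sum(aa^2) * sum(bb^2))
    if (den == 0) next
    r <- sum(aa * bb) / den
    if (abs(r) > best) {
      best <- abs(r)
      bestSign <- if (r >= 0) 1L else -1L
      bestShift <- lag
    }
  }
  list(ncc = best, sign = bestSign, shift = bestShift)
}

#' Match learned kernels to ground-truth templates
#'
#' Each kernel is assigned the template with the highest peak absolute
#' normalized cross-correlation (sign-agnostic: the Tanh symmetry lets a
#' model learn an amplitude-reversed template).  A kernel is called
#' *strong* when its peak NCC reaches the threshold `tau`, *weak*
#' otherwise.  With `assignment = "one_to_one"` (square case) a greedy
#' best-first unique assignment is used instead of per-kernel argmax.
#'
#' @param kernels matrix of kernels (one per column) from
#'   [extractKernels()], or a list of numeric vectors.
#' @param tpls list of [TemplateSignal-class] objects.
#' @param tau strong/weak threshold on the peak NCC (default 0.8; reported
#'   alongside the raw values so conclusions do not hinge on it).
#' @param minOverlap forwarded to [normalizedCrossCorrelation()].
#' @param assignment `"argmax"` (default, mirrors per-filter visual
#'   comparison) or `"one_to_one"`.
#' @return data.frame with one row per kernel: `kernelId`,
#'   `bestTemplateId`, `ncc`, `sign`, `bestShift`, `strength`.
#' @export
matchKernelsToTemplates <- function(kernels, tpls, tau = 0.8,
                                    minOverlap = 0.5,
                                    assignment = c("argmax", "one_to_one")) {
  assignment <- match.arg(assignment)
  if (is.list(kernels)) kernels <- do.call(cbind, kernels)
  kernels <- as.matrix(kernels)
  if (ncol(kernels) == 0L || length(tpls) == 0L) {
    stop("need at least one kernel and one template")
  }
  nk <- ncol(kernels)
  nt <- length(tpls)
  ncc <- matrix(0, nk, nt)
  sgn <- matrix(1L, nk, nt)
  shf <- matrix(0L, nk, nt)
  for (i in seq_len(nk)) {
    for (j in seq_len(nt)) {
      r <- normalizedCrossCorrelation(kernels[, i], tpls[[j]]@samples,
                                      minOverlap = minOverlap)
      ncc[i, j] <- r$ncc
      sgn[i, j] <- r$sign
      shf[i, j] <- r$shift
    }
  }
  if (assignment == "argmax") {
    bestT <- max.col(ncc, ties.method = "first")
  } else {
    if (nk != nt) stop("one_to_one assignment requires #kernels == #templates")
    bestT <- integer(nk)
    freeK <- seq_len(nk)
    freeT <- seq_len(nt)
    work <- ncc
    for (step in seq_len(nk)) {
      pos <- which(work == max(work[freeK, freeT]), arr.ind = TRUE)
      pos <- pos[pos[, 1] %in% freeK & pos[, 2] %in% freeT, , drop = FALSE][1L, ]
      bestT[pos[1L]] <- pos[2L]
      freeK <- setdiff(freeK, pos[1L])
      freeT <- setdiff(freeT, pos[2L])
      work[pos[1L], ] <- -Inf
      work[, pos[2L]] <- -Inf
    }
  }
  pick <- cbind(seq_len(nk), bestT)
  data.frame(
    kernelId = if (!is.null(colnames(kernels))) colnames(kernels)
               else as.character(seq_len(nk)),
    bestTemplateId = vapply(bestT, function(j) tpls[[j]]@templateId,
                            integer(1)),
    ncc = ncc[pick],
    sign = sgn[pick],
    bestShift = shf[pick],
    strength = ifelse(ncc[pick] >= tau, "strong", "weak"),
    stringsAsFactors = FALSE
  )
}

#' Dump and render the FC output-layer weights
#'
#' Writes the numeric weight matrix as CSV and a heatmap as PNG; for a
#' square FC matrix the diagonal and its signs are returned, since the
#' diagonal characterizes the one-to-one mapping between each kernel's
#' peak-correlation output and its class probability.
#'
#' @param model a trained [MFModel-class].
#' @param path output prefix; `<path>.csv` and `<path>.png` are written.
#' @return invisibly, a list with the weight `matrix`, and for the square
#'   case `diagonal` and `negativeDiagonal` (indices of negative diagonal
#'   weights, i.e. amplitude-reversed kernels).
#' @export
fcWeightHeatmap <- function(model, path) {
  W <- model@params$fc_w
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  utils::write.csv(W, paste0(path, ".csv"), row.names = FALSE)
  grDevices::png(paste0(path, ".png"), width = 640, height = 560)
  op <- graphics::par(mar = c(4.5, 4.5, 2.5, 1))
  on.exit({
    graphics::par(op)
    grDevices::dev.off()
  })
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(seq_len(ncol(W)), seq_len(nrow(W)),
                  t(W[rev(seq_len(nrow(W))), , drop = FALSE]),
                  col = pal, xlab = "class output", ylab = "GMP input",
                  main = "FC output-layer weights", axes = FALSE)
  graphics::axis(1, at = seq_len(ncol(W)))
  graphics::axis(2, at = seq_len(nrow(W)), labels = rev(seq_len(nrow(W))))
  out <- list(matrix = W)
  if (nrow(W) == ncol(W)) {
    out$diagonal <- diag(W)
    out$negativeDiagonal <- which(diag(W) < 0)
  }
  invisible(out)
}
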