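## Matched-filter CNN architectures.
##
## Univariate stack (one input channel):
##   Conv1D (NF filters, kernel NK, stride 1, valid, zero bias)
##   -> BatchNorm -> Tanh -> GlobalMaxPool (time) -> FC(NC) -> softmax
##
## Multivariate stack (Nsen sensor channels):
##   [optional kernel-size-1 linear channel expander Nsen -> Nch]
##   -> BatchNorm -> train-time additive Gaussian noise
##   -> DepthwiseConv1D (NF kernels per channel, valid)
##   -> BatchNorm -> Tanh -> GlobalMaxPool -> FC(NC) -> softmax
##
## No deep-learning framework is used: forward, backward and the optimizer
## are implemented in the package on plain matrix algebra, which keeps the
## whole computation inspectable — the point of the matched-filter reading.

.BN_EPS <- 1e-3
.BN_MOMENTUM <- 0.99

#' Construct a ModelConfig
#'
#' @param NS input segment length (samples).
#' @param NK convolution kernel length (`<= NS`).
#' @param NF filters per channel (depth multiplier).
#' @param NC number of classes.
#' @param Nsen number of input sensor channels (1 = univariate).
#' @param Nch model channels after the optional linear expander; defaults
#'   to `Nsen`.
#' @param variant weight-constraint variant: `"unconstrained"` (default),
#'   `"diagonal_constrained"`, or `"frozen_preassigned"`.
#' @param useInputLinear instantiate the kernel-size-1 channel expander.
#' @param noiseStd training-time Gaussian noise std (post-normalization
#'   units) in the multivariate stack; 0 disables.
#' @param zeroBias keep convolution/FC biases at zero (matched-filter
#'   fidelity; biases are omitted entirely).
#' @param secondBatchNorm keep the batch-normalization layer after the
#'   depthwise convolution.
#' @param seed initialization seed.
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(NS, NK, NF, NC, Nsen = 1L, Nch = NULL,
                        variant = "unconstrained", useInputLinear = FALSE,
                        noiseStd = 0.2, zeroBias = TRUE,
                        secondBatchNorm = TRUE, seed = 1L) {
  if (is.null(Nch)) Nch <- Nsen
  new("ModelConfig", NS = as.integer(NS), Nsen = as.integer(Nsen),
      Nch = as.integer(Nch), NF = as.integer(NF), NK = as.integer(NK),
      NC = as.integer(NC), variant = variant,
      useInputLinear = isTRUE(useInputLinear),
      noiseStd = as.numeric(noiseStd), zeroBias = isTRUE(zeroBias),
      secondBatchNorm = isTRUE(secondBatchNorm), seed = as.integer(seed))
}

## Glorot (fan-scaled) uniform initializer
.glorot <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

.bnInit <- function(n, prefix) {
  out <- list(rep(1, n), rep(0, n), rep(0, n), rep(1, n))
  names(out) <- paste0(prefix, c("_g", "_b", "_m", "_v"))
  out
}

#' Build the univariate matched-filter CNN
#'
#' @param config a [ModelConfig-class] with `Nsen = 1`.
#' @param tpls template bank, required when
#'   `config@variant == "frozen_preassigned"`.
#' @return an untrained [MFModel-class]; initialization is deterministic
#'   for a fixed `config@seed`.
#' @examples
#' m <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4))
#' countParameters(m)
#' @export
buildUnivariate <- function(config, tpls = NULL) {
  validObject(config)
  if (config@Nsen != 1L) stop("univariate model requires Nsen = 1")
  params <- .withSeed(config@seed, {
    c(list(conv_w = .glorot(c(config@NK, config@NF),
                            fanIn = config@NK, fanOut = config@NK * config@NF)),
      .bnInit(config@NF, "bn"),
      list(fc_w = .glorot(c(config@NF, config@NC),
                          fanIn = config@NF, fanOut = config@NC)))
  })
  model <- new("MFModel", config = config, arch = "univariate",
               params = params,
               trainable = c("conv_w", "bn_g", "bn_b", "fc_w"),
               fcMask = NULL, trained = FALSE)
  applyVariant(model, config@variant, tpls)
}

#' Build the multivariate depthwise matched-filter CNN
#'
#' Each model channel is convolved with its own `NF` depthwise kernels,
#' with no cross-channel mixing before the FC layer; the optional leading
#' kernel-size-1 convolution expands `Nsen` sensor channels into `Nch`
#' model channels by learned weighted sums.
#'
#' @param config a [ModelConfig-class].
#' @param tpls template bank, required when
#'   `config@variant == "frozen_preassigned"`.
#' @return an untrained [MFModel-class].
#' @examples
#' cfg <- modelConfig(NS = 128, NK = 128, NF = 30, NC = 6, Nsen = 9)
#' m <- buildMultivariate(cfg)
#' @export
buildMultivariate <- function(config, tpls = NULL) {
  validObject(config)
  nOut <- config@Nch * config@NF
  params <- .withSeed(config@seed, {
    p <- list()
    if (config@useInputLinear) {
      p$lin_w <- .glorot(c(config@Nsen, config@Nch),
                         fanIn = config@Nsen, fanOut = config@Nch)
    }
    p <- c(p, .bnInit(config@Nch, "bn1"))
    p$dw_w <- .glorot(c(config@NK, config@Nch, config@NF),
                      fanIn = config@NK * config@Nch,
                      fanOut = config@NK * config@NF)
    if (config@secondBatchNorm) p <- c(p, .bnInit(nOut, "bn2"))
    p$fc_w <- .glorot(c(nOut, config@NC), fanIn = nOut, fanOut = config@NC)
    p
  })
  trainable <- c(if (config@useInputLinear) "lin_w",
                 "bn1_g", "bn1_b", "dw_w",
                 if (config@secondBatchNorm) c("bn2_g", "bn2_b"),
                 "fc_w")
  model <- new("MFModel", config = config, arch = "multivariate",
               params = params, trainable = trainable, fcMask = NULL,
               trained = FALSE)
  applyVariant(model, config@variant, tpls)
}

#' Apply a weight-constraint variant
#'
#' Variant `"frozen_preassigned"` assigns the template bank to the
#' convolution kernels and a sparse identity matrix to the FC layer and
#' freezes both (only normalization parameters remain trainable) — the
#' model then *is* the classical matched filter.  Variant
#' `"diagonal_constrained"` masks the FC weights to their diagonal (the
#' diagonal stays learnable).  Variant `"unconstrained"` leaves every layer
#' free.
#'
#' @param model an [MFModel-class].
#' @param variant variant name (see above).
#' @param tpls list of [TemplateSignal-class] (required for
#'   `"frozen_preassigned"`; one template per filter, length `NK`).
#' @return the modified model.
#' @export
applyVariant <- function(model, variant = model@config@variant, tpls = NULL) {
  variant <- match.arg(variant, c("unconstrained", "diagonal_constrained",
                                  "frozen_preassigned"))
  cfg <- model@config
  model@config@variant <- variant
  if (variant == "unconstrained") {
    model@fcMask <- NULL
    return(model)
  }
  nIn <- nrow(model@params$fc_w)
  nOut <- ncol(model@params$fc_w)
  if (variant == "diagonal_constrained") {
    if (nIn != nOut) {
      stop("diagonal constraint requires a square FC matrix (NF*Nch == NC)")
    }
    mask <- diag(1, nIn, nOut)
    model@fcMask <- mask
    model@params$fc_w <- model@params$fc_w * mask
    return(model)
  }
  ## frozen_preassigned
  if (is.null(tpls)) {
    stop("frozen_preassigned requires the template bank")
  }
  K <- templateMatrix(tpls)
  if (model@arch == "univariate") {
    if (!identical(dim(K), dim(model@params$conv_w))) {
      stop(sprintf("template bank (%d x %d) does not match kernels (%d x %d)",
                   nrow(K), ncol(K), nrow(model@params$conv_w),
                   ncol(model@params$conv_w)))
    }
    model@params$conv_w <- K
    convName <- "conv_w"
  } else {
    if (nrow(K) != cfg@NK || ncol(K) != cfg@Nch * cfg@NF) {
      stop("template bank does not match the depthwise kernel layout")
    }
    model@params$dw_w <- array(K, dim = dim(model@params$dw_w))
    convName <- "dw_w"
  }
  if (nIn != nOut) stop("frozen variant requires NF*Nch == NC")
  model@params$fc_w <- diag(1, nIn, nOut)
  model@fcMask <- NULL
  model@trainable <- setdiff(model@trainable, c(convName, "fc_w", "lin_w"))
  model
}

## ---- forward passes ------------------------------------------------------

.softmax <- function(l) {
  e <- exp(l - apply(l, 1L, max))
  e / rowSums(e)
}

## BN on an (m x F) matrix of per-channel columns; returns normalized
## output + cache.  training = use batch statistics and report them.
## column-recycled a*M + b without sweep()'s aperm overhead
.colScale <- function(M, mult, add = NULL) {
  m <- nrow(M)
  out <- M * rep(mult, each = m)
  if (!is.null(add)) out <- out + rep(add, each = m)
  out
}

.bnForward <- function(M, g, b, rm, rv, training) {
  if (training) {
    mu <- colMeans(M)
    vr <- colMeans(M^2) - mu^2        # biased batch variance
  } else {
    mu <- rm
    vr <- rv
  }
  m <- nrow(M)
  invstd <- 1 / sqrt(vr + .BN_EPS)
  Yhat <- (M - rep(mu, each = m)) * rep(invstd, each = m)
  Z <- .colScale(Yhat, g, b)
  list(Z = Z, Yhat = Yhat, invstd = invstd, mu = mu, vr = vr)
}

.bnBackward <- function(dZ, cache, g) {
  m <- nrow(dZ)
  dg <- colSums(dZ * cache$Yhat)
  db <- colSums(dZ)
  dYhat <- .colScale(dZ, g)
  s1 <- colSums(dYhat)
  s2 <- colSums(dYhat * cache$Yhat)
  dM <- dYhat - rep(s1 / m, each = m) -
    .colScale(cache$Yhat, s2 / m)
  dM <- .colScale(dM, cache$invstd)
  list(dM = dM, dg = dg, db = db)
}

## im2col gather: rows = (example, lag) pairs (example fastest), cols =
## kernel taps, so valid-mode correlation is a single matrix product
.im2col <- function(X, NK) {
  B <- nrow(X)
  Tn <- ncol(X) - NK + 1L
  cidx <- rep(seq_len(NK), each = Tn) + rep(seq_len(Tn) - 1L, times = NK)
  Xc <- X[, cidx, drop = FALSE]
  dim(Xc) <- c(B * Tn, NK)
  Xc
}

## valid-mode conv of batch X (B x NS) against kernels K (NK x F);
## returns (B*T) x F matrix, row block t holding lag t for all examples
.convForward <- function(X, K) {
  .im2col(X, nrow(K)) %*% K
}

## gradient of conv w.r.t. kernels given dC ((B*T) x F)
.convKernelGrad <- function(X, dC, NK) {
  crossprod(.im2col(X, NK), dC)
}

## global max pool over the lag axis of a (B*T) x F matrix
.gmpForward <- function(C, B) {
  Tn <- nrow(C) / B
  Fm <- ncol(C)
  g <- matrix(0, B, Fm)
  idx <- matrix(0L, B, Fm)
  for (f in seq_len(Fm)) {
    M <- matrix(C[, f], B, Tn)
    ix <- max.col(M, ties.method = "first")
    idx[, f] <- ix
    g[, f] <- M[cbind(seq_len(B), ix)]
  }
  list(g = g, idx = idx)
}

.gmpBackward <- function(dg, idx, B, Tn) {
  dC <- matrix(0, B * Tn, ncol(dg))
  for (f in seq_len(ncol(dg))) {
    dC[(idx[, f] - 1L) * B + seq_len(B), f] <- dg[, f]
  }
  dC
}

## univariate forward; X: B x NS.  Returns probs and (optionally) caches.
.fwdUnivariate <- function(par, X, cfg, training = FALSE, keepCache = FALSE) {
  B <- nrow(X)
  Tn <- cfg@NS - cfg@NK + 1L
  Xc <- .im2col(X, cfg@NK)
  C <- Xc %*% par$conv_w
  bn <- .bnForward(C, par$bn_g, par$bn_b, par$bn_m, par$bn_v, training)
  A <- tanh(bn$Z)
  gm <- .gmpForward(A, B)
  logits <- gm$g %*% par$fc_w
  probs <- .softmax(logits)
  out <- list(probs = probs, bnStats = if (training) bn[c("mu", "vr")])
  if (keepCache) {
    out$cache <- list(Xc = Xc, bn = bn, A = A, gm = gm, B = B, Tn = Tn)
  }
  out
}

.bwdUnivariate <- function(par, cache, probs, y, cfg) {
  B <- cache$B
  dLogits <- probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  grads <- list()
  grads$fc_w <- crossprod(cache$gm$g, dLogits)
  dg <- dLogits %*% t(par$fc_w)
  dA <- .gmpBackward(dg, cache$gm$idx, B, cache$Tn)
  dZ <- dA * (1 - cache$A^2)
  bb <- .bnBackward(dZ, cache$bn, par$bn_g)
  grads$bn_g <- bb$dg
  grads$bn_b <- bb$db
  grads$conv_w <- crossprod(cache$Xc, bb$dM)
  grads
}

## multivariate forward; X: B x NS x Nsen array.
.fwdMultivariate <- function(par, X, cfg, training = FALSE,
                             keepCache = FALSE) {
  B <- dim(X)[1L]
  NS <- cfg@NS
  Tn <- NS - cfg@NK + 1L
  nOut <- cfg@Nch * cfg@NF
  ## optional linear channel expander
  if (cfg@useInputLinear) {
    Xf <- matrix(X, B * NS, cfg@Nsen)
    Cf <- Xf %*% par$lin_w               # (B*NS) x Nch
  } else {
    Cf <- matrix(X, B * NS, cfg@Nch)
  }
  bn1 <- .bnForward(Cf, par$bn1_g, par$bn1_b, par$bn1_m, par$bn1_v, training)
  Zn <- bn1$Z
  if (training && cfg@noiseStd > 0) {
    Zn <- Zn + stats::rnorm(length(Zn), 0, cfg@noiseStd)
  }
  ZnArr <- array(Zn, dim = c(B, NS, cfg@Nch))
  ## depthwise convolution: channel c -> NF feature maps
  D <- matrix(0, B * Tn, nOut)
  Xcs <- vector("list", cfg@Nch)
  for (ch in seq_len(cfg@Nch)) {
    cols <- (ch - 1L) * cfg@NF + seq_len(cfg@NF)
    Zc <- matrix(ZnArr[, , ch], nrow = B)
    Xcs[[ch]] <- .im2col(Zc, cfg@NK)
    D[, cols] <- Xcs[[ch]] %*% matrix(par$dw_w[, ch, ], ncol = cfg@NF)
  }
  if (cfg@secondBatchNorm) {
    bn2 <- .bnForward(D, par$bn2_g, par$bn2_b, par$bn2_m, par$bn2_v, training)
    Z2 <- bn2$Z
  } else {
    bn2 <- NULL
    Z2 <- D
  }
  A <- tanh(Z2)
  gm <- .gmpForward(A, B)
  probs <- .softmax(gm$g %*% par$fc_w)
  out <- list(probs = probs,
              bnStats = if (training) {
                list(bn1 = bn1[c("mu", "vr")],
                     bn2 = if (cfg@secondBatchNorm) bn2[c("mu", "vr")])
              })
  if (keepCache) {
    out$cache <- list(X = X, bn1 = bn1, Xcs = Xcs, bn2 = bn2, A = A,
                      gm = gm, B = B, Tn = Tn)
  }
  out
}

.bwdMultivariate <- function(par, cache, probs, y, cfg) {
  B <- cache$B
  NS <- cfg@NS
  Tn <- cache$Tn
  nOut <- cfg@Nch * cfg@NF
  dLogits <- probs
  dLogits[cbind(seq_len(B), y)] <- dLogits[cbind(seq_len(B), y)] - 1
  dLogits <- dLogits / B
  grads <- list()
  grads$fc_w <- crossprod(cache$gm$g, dLogits)
  dg <- dLogits %*% t(par$fc_w)
  dA <- .gmpBackward(dg, cache$gm$idx, B, Tn)
  dZ2 <- dA * (1 - cache$A^2)
  if (cfg@secondBatchNorm) {
    bb2 <- .bnBackward(dZ2, cache$bn2, par$bn2_g)
    grads$bn2_g <- bb2$dg
    grads$bn2_b <- bb2$db
    dD <- bb2$dM
  } else {
    dD <- dZ2
  }
  ## depthwise kernel gradients + gradient w.r.t. the normalized-noised
  ## input (needed for the BN1 parameters and, if present, the expander)
  dw <- array(0, dim = dim(par$dw_w))
  dZn <- matrix(0, B * NS, cfg@Nch)
  for (ch in seq_len(cfg@Nch)) {
    cols <- (ch - 1L) * cfg@NF + seq_len(cfg@NF)
    dDc <- dD[, cols, drop = FALSE]
    dw[, ch, ] <- crossprod(cache$Xcs[[ch]], dDc)
    Kc <- matrix(par$dw_w[, ch, ], ncol = cfg@NF)
    dZc <- matrix(0, B, NS)
    for (t in seq_len(Tn)) {
      rows <- ((t - 1L) * B + 1L):(t * B)
      dZc[, t:(t + cfg@NK - 1L)] <- dZc[, t:(t + cfg@NK - 1L)] +
        dDc[rows, , drop = FALSE] %*% t(Kc)
    }
    dZn[, ch] <- as.vector(dZc)
  }
  grads$dw_w <- dw
  bb1 <- .bnBackward(dZn, cache$bn1, par$bn1_g)
  grads$bn1_g <- bb1$dg
  grads$bn1_b <- bb1$db
  if (cfg@useInputLinear) {
    Xf <- matrix(cache$X, B * NS, cfg@Nsen)
    grads$lin_w <- crossprod(Xf, bb1$dM)
  }
  grads
}

.forward <- function(model, X, training = FALSE, keepCache = FALSE) {
  if (model@arch == "univariate") {
    .fwdUnivariate(model@params, X, model@config, training, keepCache)
  } else {
    .fwdMultivariate(model@params, X, model@config, training, keepCache)
  }
}

.backward <- function(model, cache, probs, y) {
  if (model@arch == "univariate") {
    .bwdUnivariate(model@params, cache, probs, y, model@config)
  } else {
    .bwdMultivariate(model@params, cache, probs, y, model@config)
  }
}

## coerce user input to the shape the arch expects
.coerceInput <- function(model, x) {
  cfg <- model@config
  if (model@arch == "univariate") {
    x <- as.matrix(x)
    if (ncol(x) != cfg@NS) stop("input must have NS = ", cfg@NS, " columns")
    x
  } else {
    if (length(dim(x)) != 3L) stop("multivariate input must be B x NS x Nsen")
    if (dim(x)[2L] != cfg@NS || dim(x)[3L] != cfg@Nsen) {
      stop("multivariate input must be B x ", cfg@NS, " x ", cfg@Nsen)
    }
    x
  }
}

#' Class-probability and class predictions
#'
#' Inference-mode forward pass (batch normalization uses its running
#' statistics).  Softmax rows sum to 1.
#'
#' @param model a trained or untrained [MFModel-class].
#' @param x numeric matrix (examples x `NS`) for the univariate model, or a
#'   `B x NS x Nsen` array for the multivariate model.
#' @return `predictProbs`: matrix of class probabilities (examples x `NC`);
#'   `predictClasses`: integer class labels (argmax, lowest-id ties).
#' @rdname predictProbs
#' @export
setMethod("predictProbs", "MFModel", function(model, x) {
  x <- .coerceInput(model, x)
  B <- if (model@arch == "univariate") nrow(x) else dim(x)[1L]
  chunk <- 2048L
  out <- matrix(0, B, model@config@NC)
  p <- model@params
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    if (model@arch == "univariate") {
      out[s:e, ] <- .cppUniProbs(x[s:e, , drop = FALSE], p$conv_w, p$bn_g,
                                 p$bn_b, p$bn_m, p$bn_v, p$fc_w, .BN_EPS)
    } else {
      out[s:e, ] <- .forward(model, x[s:e, , , drop = FALSE],
                             training = FALSE)$probs
    }
  }
  out
})

#' @rdname predictProbs
#' @export
setMethod("predictClasses", "MFModel", function(model, x) {
  max.col(predictProbs(model, x), ties.method = "first")
})

## ---- parameter accounting ------------------------------------------------

.layerTable <- function(model) {
  cfg <- model@config
  rows <- list()
  addRow <- function(layer, name, n) {
    trainable <- name %in% model@trainable
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = layer, param = name, count = n, trainable = trainable)
  }
  for (nm in names(model@params)) {
    n <- length(model@params[[nm]])
    layer <- switch(sub("_[a-z]$", "", nm),
                    conv = "Conv1D", dw = "DepthwiseConv1D",
                    lin = "LinearConv1x1", fc = "Dense",
                    bn = "BatchNorm", bn1 = "BatchNorm1", bn2 = "BatchNorm2",
                    nm)
    ## running statistics are bookkeeping, never trainable
    if (grepl("_(m|v)$", nm)) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = layer, param = nm, count = n, trainable = FALSE)
    } else {
      addRow(layer, nm, n)
    }
  }
  do.call(rbind, rows)
}

#' Count model parameters
#'
#' Reports trainable and total parameter counts with a per-layer breakdown
#' (attribute `"breakdown"`).  Batch-normalization running statistics count
#' as non-trainable parameters, matching the usual framework bookkeeping.
#'
#' @param x an [MFModel-class] or a [ModelConfig-class] (a model is built
#'   to derive the layout).
#' @return named numeric vector `c(trainable, nonTrainable, total)`.
#' @rdname countParameters
#' @export
setMethod("countParameters", "MFModel", function(x) {
  tab <- .layerTable(x)
  out <- c(trainable = sum(tab$count[tab$trainable]),
           nonTrainable = sum(tab$count[!tab$trainable]),
           total = sum(tab$count))
  attr(out, "breakdown") <- tab
  out
})

#' @rdname countParameters
#' @export
setMethod("countParameters", "ModelConfig", function(x) {
  ## build the layout with free weights, then impose the variant's
  ## trainability (template values are irrelevant to the counts)
  cfg <- x
  frozen <- cfg@variant == "frozen_preassigned"
  if (frozen) cfg@variant <- "unconstrained"
  model <- if (cfg@Nsen == 1L && cfg@Nch == 1L && !cfg@useInputLinear) {
    buildUnivariate(cfg)
  } else {
    buildMultivariate(cfg)
  }
  if (frozen) {
    model@trainable <- setdiff(model@trainable,
                               c("conv_w", "dw_w", "fc_w", "lin_w"))
  }
  countParameters(model)
})

#' Force every normalization layer to the exact identity
#'
#' Sets gamma to 1, beta to 0, the running mean to 0 and the running
#' variance to `1 - eps`, so that the inference-time scaling is exactly 1.
#' With the frozen template-preassigned variant this reduces the network,
#' input-to-argmax, to the classical matched-filter classifier.
#'
#' @param model an [MFModel-class].
#' @return the model with identity normalization.
#' @export
identityNormalization <- function(model) {
  for (prefix in c("bn", "bn1", "bn2")) {
    if (!is.null(model@params[[paste0(prefix, "_g")]])) {
      n <- length(model@params[[paste0(prefix, "_g")]])
      model@params[[paste0(prefix, "_g")]] <- rep(1, n)
      model@params[[paste0(prefix, "_b")]] <- rep(0, n)
      model@params[[paste0(prefix, "_m")]] <- rep(0, n)
      model@params[[paste0(prefix, "_v")]] <- rep(1 - .BN_EPS, n)
    }
  }
  model
}

setMethod("show", "MFModel", function(object) {
  cfg <- object@config
  n <- countParameters(object)
  cat(sprintf("MFModel (%s, %s)\n", object@arch, cfg@variant))
  cat(sprintf("  NS=%d NK=%d NF=%d NC=%d Nsen=%d Nch=%d\n",
              cfg@NS, cfg@NK, cfg@NF, cfg@NC, cfg@Nsen, cfg@Nch))
  cat(sprintf("  parameters: %d trainable, %d total%s\n", n[["trainable"]],
              n[["total"]], if (object@trained) " [trained]" else ""))
})
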