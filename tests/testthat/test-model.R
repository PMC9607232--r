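test_that("the univariate stack has the documented shapes and determinism", {
  cfg <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4, seed = 3)
  m <- buildUnivariate(cfg)
  expect_identical(dim(m@params$conv_w), c(64L, 4L))
  expect_identical(dim(m@params$fc_w), c(4L, 4L))   # square GMP -> class map
  ## conv feature-map length NS - NK + 1
  C <- mfcnn:::.convForward(matrix(rnorm(128), 1), m@params$conv_w)
  expect_identical(nrow(C), 65L)
  m2 <- buildUnivariate(cfg)
  expect_identical(m@params, m2@params)
  expect_error(buildUnivariate(modelConfig(NS = 64, NK = 128, NF = 4,
                                           NC = 4)), "NK")
})

test_that("softmax outputs are normalized probabilities", {
  m <- buildUnivariate(modelConfig(NS = 64, NK = 16, NF = 3, NC = 5,
                                   seed = 8))
  p <- predictProbs(m, matrix(rnorm(40 * 64), 40))
  expect_identical(dim(p), c(40L, 5L))
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("weight-constraint variants assign, mask and freeze as specified", {
  tpl <- makeTemplates(4, 64)
  cfg1 <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                      variant = "frozen_preassigned", seed = 2)
  m1 <- buildUnivariate(cfg1, tpls = tpl)
  expect_identical(m1@params$conv_w, templateMatrix(tpl))
  expect_identical(m1@params$fc_w, diag(1, 4, 4))
  expect_setequal(m1@trainable, c("bn_g", "bn_b"))

  cfg2 <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                      variant = "diagonal_constrained", seed = 2)
  m2 <- buildUnivariate(cfg2)
  expect_true(all(m2@params$fc_w[upper.tri(m2@params$fc_w)] == 0))
  expect_true(all(m2@params$fc_w[lower.tri(m2@params$fc_w)] == 0))
  expect_true("fc_w" %in% m2@trainable)

  m3 <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                                    seed = 2))
  expect_setequal(m3@trainable, c("conv_w", "bn_g", "bn_b", "fc_w"))
  expect_error(buildUnivariate(cfg1), "template")
  expect_error(buildUnivariate(cfg1, tpls = makeTemplates(4, 32)),
               "does not match")
})

test_that("frozen layers survive training bitwise; diagonal mask is enforced", {
  ds <- smallDataset(N = 4, NT = 60, P = 0.5, seed = 6)
  tpl <- templates(ds)
  m1 <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                                    variant = "frozen_preassigned", seed = 2),
                        tpls = tpl)
  fit1 <- trainModel(m1, ds, hyperparams(batchSize = 64, maxEpochs = 5,
                                         seed = 4))
  expect_identical(fit1$model@params$conv_w, templateMatrix(tpl))
  expect_identical(fit1$model@params$fc_w, diag(1, 4, 4))

  m2 <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                                    variant = "diagonal_constrained",
                                    seed = 2))
  fit2 <- trainModel(m2, ds, hyperparams(batchSize = 64, maxEpochs = 5,
                                         seed = 4))
  W <- fit2$model@params$fc_w
  expect_true(all(W[row(W) != col(W)] == 0))
  expect_false(identical(fit2$model@params$conv_w, m2@params$conv_w))
})

test_that("parameter accounting matches closed-form layer arithmetic", {
  cfg <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4, seed = 1)
  n <- countParameters(cfg)
  tab <- attr(n, "breakdown")
  expect_equal(tab$count[tab$param == "fc_w"], 16)       # 4 x 4, no bias
  expect_equal(n[["total"]], 64 * 4 + 4 * 4 + 16)

  frozen <- modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                        variant = "frozen_preassigned", seed = 1)
  nf <- countParameters(frozen)
  expect_equal(nf[["trainable"]], 2 * 4)    # normalization only

  mv1 <- countParameters(modelConfig(NS = 128, NK = 128, NF = 15, NC = 6,
                                     Nsen = 9, seed = 1))
  mv2 <- countParameters(modelConfig(NS = 128, NK = 128, NF = 30, NC = 6,
                                     Nsen = 9, seed = 1))
  b1 <- attr(mv1, "breakdown")
  b2 <- attr(mv2, "breakdown")
  getc <- function(b, nm) b$count[b$param == nm]
  expect_equal(getc(b2, "dw_w"), 2 * getc(b1, "dw_w"))
  expect_equal(getc(b2, "fc_w"), 2 * getc(b1, "fc_w"))
})

test_that("the multivariate stack wires the expander and depthwise layout", {
  wis <- modelConfig(NS = 52, NK = 52, NF = 4, NC = 6, Nsen = 3, Nch = 9,
                     useInputLinear = TRUE, seed = 5)
  mw <- buildMultivariate(wis)
  expect_identical(dim(mw@params$lin_w), c(3L, 9L))
  expect_identical(dim(mw@params$dw_w), c(52L, 9L, 4L))
  expect_identical(dim(mw@params$fc_w), c(36L, 6L))

  uci <- modelConfig(NS = 128, NK = 128, NF = 2, NC = 6, Nsen = 9, seed = 5)
  mu <- buildMultivariate(uci)
  expect_null(mu@params$lin_w)
  expect_identical(nrow(mu@params$fc_w), 9L * 2L)   # GMP dim Nch * NF
})

test_that("depthwise feature maps are independent across input channels", {
  cfg <- modelConfig(NS = 32, NK = 32, NF = 2, NC = 3, Nsen = 4,
                     noiseStd = 0, seed = 7)
  m <- buildMultivariate(cfg)
  x0 <- array(0, dim = c(1, 32, 4))
  x1 <- x0
  x1[1, , 2] <- rnorm(32)     # perturb channel 2 only
  g0 <- mfcnn:::.forward(m, x0, keepCache = TRUE)$cache$gm$g
  g1 <- mfcnn:::.forward(m, x1, keepCache = TRUE)$cache$gm$g
  changed <- which(abs(g1 - g0) > 1e-12)
  expect_true(all(changed %in% (2L - 1L) * 2L + 1:2))
})

test_that("tanh commutes with global max pooling", {
  set.seed(19)
  for (i in 1:100) {
    v <- rnorm(65, sd = runif(1, 0.1, 10))
    expect_identical(max(tanh(v)), tanh(max(v)))
  }
})

test_that("analytic gradients match finite differences on both stacks", {
  set.seed(42)
  cfg <- modelConfig(NS = 12, NK = 5, NF = 3, NC = 3, seed = 9)
  m <- buildUnivariate(cfg)
  X <- matrix(rnorm(4 * 12), 4)
  y <- sample(3, 4, replace = TRUE)
  fw <- mfcnn:::.forward(m, X, training = TRUE, keepCache = TRUE)
  gr <- mfcnn:::.backward(m, fw$cache, fw$probs, y)
  lossAt <- function(params) {
    mm <- m
    mm@params <- params
    mfcnn:::.ceLoss(mfcnn:::.forward(mm, X, training = TRUE)$probs, y)
  }
  eps <- 1e-6
  for (nm in c("conv_w", "bn_g", "bn_b", "fc_w")) {
    num <- m@params[[nm]] * 0
    for (i in seq_along(num)) {
      pp <- m@params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m@params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
    }
    expect_equal(max(abs(num - gr[[nm]])), 0, tolerance = 1e-6)
  }

  cfg2 <- modelConfig(NS = 10, NK = 6, NF = 2, NC = 3, Nsen = 2, Nch = 4,
                      useInputLinear = TRUE, noiseStd = 0, seed = 3)
  m2 <- buildMultivariate(cfg2)
  X2 <- array(rnorm(4 * 10 * 2), c(4, 10, 2))
  fw2 <- mfcnn:::.forward(m2, X2, training = TRUE, keepCache = TRUE)
  gr2 <- mfcnn:::.backward(m2, fw2$cache, fw2$probs, y)
  lossAt2 <- function(params) {
    mm <- m2
    mm@params <- params
    mfcnn:::.ceLoss(mfcnn:::.forward(mm, X2, training = TRUE)$probs, y)
  }
  for (nm in c("lin_w", "bn1_g", "dw_w", "bn2_g", "fc_w")) {
    num <- m2@params[[nm]] * 0
    for (i in seq_along(num)) {
      pp <- m2@params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m2@params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num[i] <- (lossAt2(pp) - lossAt2(pm)) / (2 * eps)
    }
    expect_equal(max(abs(num - gr2[[nm]])), 0, tolerance = 1e-6)
  }
})

test_that("the compiled training core reproduces the reference R pass", {
  set.seed(77)
  cfg <- modelConfig(NS = 40, NK = 16, NF = 3, NC = 3, seed = 4)
  m <- buildUnivariate(cfg)
  X <- matrix(rnorm(50 * 40), 50)
  y <- sample(3, 50, replace = TRUE)
  fw <- mfcnn:::.forward(m, X, training = TRUE, keepCache = TRUE)
  gr <- mfcnn:::.backward(m, fw$cache, fw$probs, y)
  st <- mfcnn:::.cppUniStep(X, as.integer(y), m@params$conv_w,
                            m@params$bn_g, m@params$bn_b, m@params$fc_w,
                            mfcnn:::.BN_EPS)
  expect_equal(st$loss, mfcnn:::.ceLoss(fw$probs, y), tolerance = 1e-12)
  for (nm in c("conv_w", "bn_g", "bn_b", "fc_w")) {
    expect_equal(drop(st[[nm]]), drop(gr[[nm]]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  pr <- mfcnn:::.forward(m, X, training = FALSE)$probs
  expect_equal(predictProbs(m, X), pr, tolerance = 1e-12)
})

test_that("flat float32 export round-trips the model", {
  m <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                                   seed = 12))
  f <- tempfile(fileext = ".mfm")
  bytes <- exportFlatModel(m, f)
  expect_true(file.exists(f))
  expect_equal(bytes, file.size(f))
  back <- readFlatModel(f)
  expect_equal(back@params$conv_w, m@params$conv_w, tolerance = 1e-6)
  X <- matrix(rnorm(10 * 128), 10)
  expect_equal(predictProbs(back, X), predictProbs(m, X), tolerance = 1e-5)
  expect_identical(back@config@NK, 64L)
})
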