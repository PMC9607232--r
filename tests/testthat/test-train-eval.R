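test_that("accuracy and F1 follow the one-vs-rest formulas", {
  ## binarized single-class example: TP=90, TN=5, FP=3, FN=2 -> Acc 0.95
  truth <- c(rep(1L, 92), rep(2L, 8))
  pred <- c(rep(1L, 90), rep(2L, 2), rep(1L, 3), rep(2L, 5))
  rep1 <- evalReport(pred, truth, NC = 2)
  expect_equal(rep1@accuracy, 0.95)
  expect_equal(rep1@counts$TP[1], 90L)
  expect_equal(rep1@counts$TN[1], 5L)
  expect_equal(rep1@counts$FP[1], 3L)
  expect_equal(rep1@counts$FN[1], 2L)

  ## TP=8, FP=2, FN=2 -> F1 = 16/20 = 0.8
  truth2 <- c(rep(1L, 10), rep(2L, 4))
  pred2 <- c(rep(1L, 8), rep(2L, 2), rep(1L, 2), rep(2L, 2))
  rep2 <- evalReport(pred2, truth2, NC = 2)
  expect_equal(rep2@perClassF1[1], 0.8)
  expect_error(evalReport(integer(0), integer(0)), "empty")
})

test_that("metrics agree with an independent brute-force tally", {
  set.seed(55)
  for (r in 1:50) {
    n <- 30
    NC <- 3
    truth <- sample(NC, n, replace = TRUE)
    pred <- sample(NC, n, replace = TRUE)
    rp <- evalReport(pred, truth, NC = NC)
    M <- naiveConfusion(pred, truth, NC)
    expect_identical(unname(rp@confusion), M)
    expect_equal(rp@accuracy, sum(diag(M)) / n)
    f1 <- vapply(seq_len(NC), function(cl) {
      tp <- M[cl, cl]
      fp <- sum(M[-cl, cl])
      fn <- sum(M[cl, -cl])
      if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    expect_equal(rp@perClassF1, f1)
    expect_equal(rp@macroF1, mean(f1, na.rm = TRUE))
    ## confusion conservation: row sums equal per-class true counts
    expect_equal(rowSums(rp@confusion),
                 as.vector(table(factor(truth, levels = 1:NC))),
                 ignore_attr = TRUE)
  }
})

test_that("epochsToPerfect finds the first perfect epoch", {
  h <- data.frame(val_acc = c(0.5, 0.9, 1.0, 1.0))
  expect_identical(epochsToPerfect(h), 3L)
  expect_true(is.na(epochsToPerfect(data.frame(val_acc = c(0.5, 0.99)))))
  expect_error(epochsToPerfect(data.frame(val_acc = numeric(0))), "empty")
})

test_that("training fits a small synthetic problem and checkpoints the best epoch", {
  ds <- smallDataset(N = 2, NT = 400, P = 0.25, seed = 42)
  cfg <- modelConfig(NS = 128, NK = 64, NF = 2, NC = 2, seed = 42)
  hp <- hyperparams(batchSize = 64, maxEpochs = 40, seed = 42)
  fit <- trainModel(buildUnivariate(cfg), ds, hp)
  expect_gte(max(fit$history$val_acc), 0.99)
  expect_true(all(c("loss", "acc", "val_loss", "val_acc", "lr") %in%
                  colnames(fit$history)))
  ## checkpointed model reproduces the best recorded validation accuracy
  valAcc <- evaluateModel(fit$model, exampleMatrix(ds, "val"),
                          exampleLabels(ds, "val"))@accuracy
  expect_equal(valAcc, max(fit$history$val_acc))
  expect_error(trainModel(buildUnivariate(cfg), ds,
                          hyperparams(batchSize = 0)), "batchSize")
})

test_that("the learning-rate column obeys the plateau decay contract", {
  ds <- smallDataset(N = 2, NT = 150, P = 1.0, seed = 13)
  cfg <- modelConfig(NS = 128, NK = 64, NF = 2, NC = 2, seed = 13)
  hp <- hyperparams(batchSize = 64, maxEpochs = 30, lrPatience = 3L,
                    earlyStopPatience = 100L, seed = 13)
  fit <- trainModel(buildUnivariate(cfg), ds, hp)
  h <- fit$history
  ## replay the scheduler from the recorded validation losses
  lr <- hp@initialLr
  best <- Inf
  wait <- 0L
  for (e in seq_len(nrow(h))) {
    expect_equal(h$lr[e], lr, tolerance = 1e-12)
    if (h$val_loss[e] < best - 1e-9) {
      best <- h$val_loss[e]
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= hp@lrPatience) {
        lr <- lr * hp@lrDecayFactor
        wait <- 0L
      }
    }
  }
  ## every decay event multiplies the rate by exactly the decay factor
  changes <- which(diff(h$lr) != 0)
  if (length(changes) > 0) {
    expect_equal(h$lr[changes + 1] / h$lr[changes],
                 rep(hp@lrDecayFactor, length(changes)), tolerance = 1e-12)
  }
})

test_that("the frozen matched-filter variant is accurate from the first epochs", {
  ds <- smallDataset(N = 4, NT = 150, P = 0.5, seed = 31)
  m <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4,
                                   variant = "frozen_preassigned",
                                   seed = 31),
                       tpls = templates(ds))
  fit <- trainModel(m, ds, hyperparams(batchSize = 64, maxEpochs = 5,
                                       seed = 31))
  expect_gte(max(fit$history$val_acc), 0.99)
  expect_identical(fit$model@params$conv_w, templateMatrix(templates(ds)))
})

test_that("experiment grids run per cell, tolerate failures and reproduce", {
  expect_identical(nrow(runExperimentGrid(list())), 0L)
  cells <- list(
    list(name = "ok",
         spec = SyntheticDatasetSpec(N = 2, NT = 120, P = 0.5, seed = 3),
         config = modelConfig(NS = 128, NK = 64, NF = 2, NC = 2, seed = 3)),
    list(name = "bad",      # frozen bank cannot satisfy NF == NC here
         spec = SyntheticDatasetSpec(N = 2, NT = 120, P = 0.5, seed = 3),
         config = modelConfig(NS = 128, NK = 64, NF = 2, NC = 3,
                              variant = "frozen_preassigned", seed = 3))
  )
  hp <- hyperparams(batchSize = 64, maxEpochs = 3, seed = 1)
  res <- runExperimentGrid(cells, hp)
  expect_equal(nrow(res), 2L)
  expect_true(is.na(res$accuracy[2]))
  expect_false(is.na(res$error[2]))
  res2 <- runExperimentGrid(cells[1], hp)
  expect_equal(res$accuracy[1], res2$accuracy[1])
  expect_equal(res$meanKernelNcc[1], res2$meanKernelNcc[1])
})
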