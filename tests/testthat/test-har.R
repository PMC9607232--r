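test_that("windowing specs reproduce the dataset stride conventions", {
  expect_equal(windowingSpec(52, 0.25)$stride, 39L)    # 20 Hz, 2.6 s
  expect_equal(windowingSpec(128, 0.5)$stride, 64L)    # 50 Hz, 2.56 s
  expect_equal(windowingSpec(128, 0)$stride, 128L)
  expect_error(windowingSpec(1, 0), "at least 2")
  expect_error(windowingSpec(52, 1), "overlap")
})

test_that("window counts match the closed form and a brute-force enumerator", {
  spec <- windowingSpec(52, 0.25)
  seg <- segmentWindows(matrix(rnorm(1000 * 2), 1000), rep(1L, 1000), spec)
  expect_equal(dim(seg$x)[1], floor((1000 - 52) / 39) + 1)   # 25 windows

  set.seed(8)
  for (r in 1:100) {
    L <- sample(60:400, 1)
    W <- sample(10:50, 1)
    ov <- runif(1, 0, 0.8)
    sp <- windowingSpec(W, ov)
    n <- dim(segmentWindows(matrix(rnorm(L)), rep(1L, L), sp)$x)[1]
    ## brute force: count window starts that fit
    starts <- 0L
    cnt <- 0L
    while (starts + W <= L) {
      cnt <- cnt + 1L
      starts <- starts + sp$stride
    }
    expect_identical(n, as.integer(cnt))
    expect_identical(n, as.integer(floor((L - W) / sp$stride) + 1))
  }
})

test_that("label rules drop or vote on boundary-spanning windows", {
  labels <- c(rep("walk", 60), rep("sit", 60))
  vals <- matrix(rnorm(120))
  sp <- windowingSpec(40, 0.5)
  strict <- segmentWindows(vals, labels, sp, labelRule = "strict")
  ## the window spanning the walk->sit change (samples 41-80) is dropped
  expect_equal(strict$y, c("walk", "walk", "sit", "sit"))
  maj <- segmentWindows(vals, labels, sp, labelRule = "majority")
  expect_equal(length(maj$y), 5L)
  expect_warning(segmentWindows(matrix(rnorm(10)), rep(1L, 10), sp),
                 "shorter")
})

test_that("the UCI-HAR loader round-trips its fixture exactly", {
  dir <- tempfile()
  ref <- makeHarFixture("ucihar", dir, nSubjects = 1L, windowsPerClass = 2L,
                        seed = 4)
  got <- loadUciHar(dir)
  expect_identical(dim(got$train$x), dim(ref$train$x))
  expect_equal(got$train$x, ref$train$x, tolerance = 1e-12)
  expect_identical(got$test$y, ref$test$y)
  expect_identical(got$channels[1:3], c("body_acc_x", "body_acc_y",
                                        "body_acc_z"))
  expect_identical(dim(got$train$x)[2:3], c(128L, 9L))
  expect_error(loadUciHar(tempfile()), "expected layout")
})

test_that("fixture generation is deterministic", {
  d1 <- tempfile()
  d2 <- tempfile()
  makeHarFixture("ucihar", d1, nSubjects = 1L, windowsPerClass = 1L,
                 seed = 11)
  makeHarFixture("ucihar", d2, nSubjects = 1L, windowsPerClass = 1L,
                 seed = 11)
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})

test_that("the WISDM loader parses the raw dialect and stratifies", {
  dir <- tempfile()
  makeHarFixture("wisdm", dir, nSubjects = 2L, windowsPerClass = 4L,
                 seed = 5)
  path <- file.path(dir, "wisdm_raw.txt")
  got <- loadWisdm(path, seed = 5)
  expect_identical(got$skipped, 0L)
  ## 2 subjects x 6 activities x 4 windows per contiguous run
  nAll <- length(got$train$y) + length(got$val$y) + length(got$test$y)
  expect_equal(nAll, 2L * 6L * 4L)
  expect_identical(dim(got$train$x)[2:3], c(52L, 3L))
  ## class proportions preserved within one window per class
  for (cl in 1:6) {
    tot <- sum(c(got$train$y, got$val$y, got$test$y) == cl)
    expect_lte(abs(sum(got$train$y == cl) - 0.64 * tot), 1)
  }

  ## the trailing-semicolon dialect parses identically to bare lines
  lines <- readLines(path)
  bare <- sub(";\\s*$", "", lines)
  path2 <- tempfile()
  writeLines(bare, path2)
  got2 <- loadWisdm(path2, seed = 5)
  expect_equal(got$train$x, got2$train$x, tolerance = 1e-12)

  ## malformed lines are skipped, excess aborts
  path3 <- tempfile()
  writeLines(c(lines, "garbage,line"), path3)
  got3 <- loadWisdm(path3, seed = 5)
  expect_identical(got3$skipped, 1L)
  path4 <- tempfile()
  writeLines(c(lines[1:5], rep("bad", 5)), path4)
  expect_error(loadWisdm(path4), "malformed")
})

test_that("the MotionSense loader honors trial partitions and channels", {
  dir <- tempfile()
  makeHarFixture("motionsense", dir, nSubjects = 1L, windowsPerClass = 2L,
                 seed = 6)
  got <- loadMotionSense(dir)
  expect_identical(dim(got$train$x)[2:3], c(128L, 6L))
  ## 4 trials per activity, top quarter (trial 4) reserved for test
  expect_equal(length(got$test$y) / (length(got$test$y) +
                                     length(got$train$y)), 0.25)
  got2 <- loadMotionSense(dir, testTrials = c(3L, 4L))
  expect_gt(length(got2$test$y), length(got$test$y))
  expect_error(loadMotionSense(tempfile()), "folders")
})

test_that("a multivariate model learns the HAR fixture end to end", {
  dir <- tempfile()
  makeHarFixture("ucihar", dir, nSubjects = 2L, windowsPerClass = 6L,
                 seed = 8)
  got <- loadUciHar(dir)
  accs <- vapply(c(1L, 2L), function(seed) {
    cfg <- modelConfig(NS = 128, NK = 128, NF = 2, NC = 6, Nsen = 9,
                       noiseStd = 0.2, seed = seed)
    ## fixture is small: hold out the distributed test part for evaluation
    fit <- trainModel(buildMultivariate(cfg),
                      list(xTrain = got$train$x, yTrain = got$train$y,
                           xVal = got$test$x, yVal = got$test$y),
                      hyperparams(batchSize = 24, maxEpochs = 30,
                                  seed = seed))
    evaluateModel(fit$model, got$test$x, got$test$y)@accuracy
  }, numeric(1))
  expect_true(all(accs >= 3 / 6))    # >= 3x the 6-class chance level
})
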