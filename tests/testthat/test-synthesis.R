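test_that("zero-noise examples are exact shifted copies with zero padding", {
  tpl <- makeTemplates(4, 64)[[1]]
  ex0 <- synthesizeExample(tpl, P = 0, NS = 128, shift = 0)
  expect_identical(ex0$values[1:64], tpl@samples)
  expect_identical(ex0$values[65:128], rep(0, 64))
  ex64 <- synthesizeExample(tpl, P = 0, NS = 128, shift = 64)
  expect_identical(ex64$values[65:128], tpl@samples)
  expect_identical(ex64$values[1:64], rep(0, 64))
  expect_error(synthesizeExample(tpl, P = -0.1), "non-negative")
  expect_error(synthesizeExample(tpl, P = 0, NS = 128, shift = 65), "shift")
  expect_error(synthesizeExample(tpl, P = 0, NS = 32), "NS")
})

test_that("injected noise power matches the requested fraction of template power", {
  tpl <- makeTemplates(4, 64)[[2]]
  for (P in c(0.5, 1.0)) {
    set.seed(100 + P * 10)
    resid <- replicate(200, {
      ex <- synthesizeExample(tpl, P = P, NS = 128)
      clean <- numeric(128)
      clean[ex$shift + 1:64] <- tpl@samples
      ex$values - clean
    })
    ## 200 x 128 = 25,600 noise draws
    expect_equal(stats::var(as.vector(resid)), P * tpl@power,
                 tolerance = 0.03)
  }
})

test_that("shifts are drawn uniformly over the inclusive range", {
  tpl <- makeTemplates(2, 64)[[1]]
  set.seed(7)
  shifts <- replicate(10000, synthesizeExample(tpl, P = 0, NS = 128)$shift)
  expect_setequal(unique(shifts), 0:64)
  p <- stats::chisq.test(table(factor(shifts, levels = 0:64)))$p.value
  expect_gt(p, 0.01)
})

test_that("dataset build honors counts, labels and stratified splits", {
  spec <- SyntheticDatasetSpec(N = 4, NT = c(1000, 500, 250, 125), P = 0.5,
                               seed = 5)
  ds <- buildDataset(spec)
  expect_equal(ncol(ds), 1875L)
  cd <- colData(ds)
  expect_equal(as.vector(table(cd$templateId)), c(1000L, 500L, 250L, 125L))
  expect_identical(cd$label, spec@labelMap[cd$templateId])
  expect_true(all(cd$shift >= 0 & cd$shift <= 64))
  ## split conservation and per-class stratification within one example
  expect_equal(sum(table(cd$split)), 1875L)
  for (cl in 1:4) {
    nc <- sum(cd$label == cl)
    for (s in c("train", "val", "test")) {
      f <- spec@splitFractions[match(s, c("train", "val", "test"))]
      expect_lte(abs(sum(cd$label == cl & cd$split == s) - f * nc), 1)
    }
  }
})

test_that("the balanced reference configuration splits 64/16/20 exactly", {
  spec <- SyntheticDatasetSpec(N = 4, NT = 500, P = 0, seed = 1)
  ds <- buildDataset(spec)
  expect_equal(as.vector(table(colData(ds)$split)[c("train", "val", "test")]),
               c(1280L, 320L, 400L))
})

test_that("dataset build is bitwise reproducible and supports mixed classes", {
  spec <- SyntheticDatasetSpec(N = 4, NT = 100, P = 0.5, seed = 9)
  d1 <- buildDataset(spec)
  d2 <- buildDataset(spec)
  expect_identical(assay(d1, "signal"), assay(d2, "signal"))
  expect_identical(as.data.frame(colData(d1)), as.data.frame(colData(d2)))

  mixed <- SyntheticDatasetSpec(N = 4, NT = 100, P = 0.5,
                                labelMap = c(1L, 1L, 2L, 2L), seed = 9)
  dm <- buildDataset(mixed)
  expect_equal(sort(unique(exampleLabels(dm))), 1:2)
  expect_equal(as.vector(table(exampleLabels(dm))), c(200L, 200L))
  expect_error(SyntheticDatasetSpec(N = 4, NT = 100,
                                    labelMap = c(1L, 1L, 3L, 3L)),
               "class label")
})

test_that("extra test noise touches only the test split at the right power", {
  spec <- SyntheticDatasetSpec(N = 2, NT = 600, P = 0.5, seed = 21)
  ds <- buildDataset(spec)
  expect_identical(addTestNoise(ds, 0), ds)
  noisy <- addTestNoise(ds, 1.0)
  tr <- colData(ds)$split != "test"
  expect_identical(assay(noisy)[, tr], assay(ds)[, tr])
  delta <- assay(noisy)[, !tr] - assay(ds)[, !tr]
  expect_false(all(delta == 0))
  ## 240 test examples x 128 samples of added AWGN at fraction 1.0
  expect_equal(stats::var(as.vector(delta)), 1.0, tolerance = 0.03)
})

test_that("spec-level PTestExtra is applied during the build", {
  base <- SyntheticDatasetSpec(N = 2, NT = 200, P = 0.5, seed = 3)
  shifted <- SyntheticDatasetSpec(N = 2, NT = 200, P = 0.5, PTestExtra = 1,
                                  seed = 3)
  d0 <- buildDataset(base)
  d1 <- buildDataset(shifted)
  tr <- colData(d0)$split != "test"
  expect_identical(assay(d0)[, tr], assay(d1)[, tr])
  expect_false(identical(assay(d0)[, !tr], assay(d1)[, !tr]))
})

test_that("datasets round-trip through the CSV serialization", {
  ds <- smallDataset(N = 2, NT = 30, P = 0.5, seed = 12)
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  writeDatasetCsv(ds, csv)
  writeSpecYaml(datasetSpec(ds), yml)
  back <- readDatasetCsv(csv, specPath = yml)
  expect_equal(exampleMatrix(back), exampleMatrix(ds), tolerance = 1e-12)
  expect_identical(exampleLabels(back), exampleLabels(ds))
  expect_identical(colData(back)$split, colData(ds)$split)
  spec2 <- datasetSpec(back)
  expect_equal(spec2@NT, datasetSpec(ds)@NT)
})
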