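## Synthetic dataset simulator: shifted templates + AWGN at a controlled
## noise-to-signal power fraction.

## evaluate expr with a temporarily seeded RNG, restoring global RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Construct a SyntheticDatasetSpec
#'
#' @param N number of templates.
#' @param NT integer vector of per-template example counts (recycled to
#'   length `N` if scalar).
#' @param P noise-to-signal power fraction used at generation time.
#' @param LT template length (samples).
#' @param NS example length (samples); default twice `LT`.
#' @param labelMap integer vector mapping template i to class label; default
#'   unique labeling `1..N`.  Mixed classes use repeated labels, e.g.
#'   `c(1, 1, 2, 2)`.
#' @param splitFractions train/validation/test fractions (sum to 1).
#' @param PTestExtra additional noise fraction applied to the test split
#'   only.
#' @param seed master RNG seed.
#' @return a [SyntheticDatasetSpec-class].
#' @examples
#' spec <- SyntheticDatasetSpec(N = 4, NT = 1000, P = 0.5, seed = 7)
#' @export
SyntheticDatasetSpec <- function(N, NT, P = 0.5, LT = 64L, NS = 2L * LT,
                        labelMap = seq_len(N),
                        splitFractions = c(0.64, 0.16, 0.20),
                        PTestExtra = 0, seed = 1L) {
  if (length(NT) == 1L) NT <- rep(NT, N)
  new("SyntheticDatasetSpec", N = as.integer(N), LT = as.integer(LT),
      NS = as.integer(NS), NT = as.integer(NT), P = as.numeric(P),
      labelMap = as.integer(labelMap),
      splitFractions = as.numeric(splitFractions),
      PTestExtra = as.numeric(PTestExtra), seed = as.integer(seed))
}

#' Synthesize one labeled example
#'
#' Places the template at a uniformly drawn integer shift inside an
#' otherwise zero `NS`-sample window and adds white Gaussian noise over the
#' whole window with variance `P` times the template power.  Uses the
#' current RNG stream (seed at the caller for reproducibility).
#'
#' @param template a [TemplateSignal-class].
#' @param P noise-to-signal power fraction (>= 0).
#' @param NS example length (`>= length(template)`).
#' @param shift optional forced integer shift in `0..NS - L_T`; default
#'   drawn uniformly (inclusive).
#' @return list with `values` (length `NS`), `shift`, `templateId`.
#' @export
synthesizeExample <- function(template, P, NS = 128L, shift = NULL) {
  stopifnot(is(template, "TemplateSignal"))
  if (P < 0) stop("P must be non-negative")
  LT <- length(template@samples)
  if (NS < LT) stop("NS must be >= the template length")
  maxShift <- NS - LT
  if (is.null(shift)) {
    shift <- sample.int(maxShift + 1L, 1L) - 1L
  } else if (shift < 0L || shift > maxShift) {
    stop("shift must lie in [0, NS - L_T]")
  }
  values <- numeric(NS)
  values[shift + seq_len(LT)] <- template@samples
  if (P > 0) {
    values <- values + stats::rnorm(NS, 0, sqrt(P * template@power))
  }
  list(values = values, shift = as.integer(shift),
       templateId = template@templateId)
}

## largest-remainder apportionment of n into fractions f (sums to n)
.apportion <- function(n, f) {
  raw <- n * f
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Build a synthetic dataset
#'
#' Generates `NT[i]` examples per template (uniform random shifts, AWGN at
#' fraction `P` of the template power), labels them through the spec's
#' template-to-class map, and assigns a stratified train/validation/test
#' split preserving per-class proportions to within one example.  If
#' `PTestExtra > 0` in the spec, the extra test-split noise is applied via
#' [addTestNoise()].  Fully reproducible from the spec seed.
#'
#' @param spec a [SyntheticDatasetSpec-class].
#' @param tpls optional template list; default `makeTemplates(N, LT)`.
#' @return a [SyntheticDataset-class].
#' @examples
#' ds <- buildDataset(SyntheticDatasetSpec(N = 2, NT = 50, P = 0.5, seed = 3))
#' table(exampleLabels(ds), colData(ds)$split)
#' @export
buildDataset <- function(spec, tpls = NULL) {
  validObject(spec)
  if (is.null(tpls)) tpls <- makeTemplates(spec@N, spec@LT, spec@seed)
  if (length(tpls) != spec@N) stop("template list must have length N")
  if (length(spec@labelMap) != spec@N) {
    stop("labelMap must provide a class for every template id")
  }
  NDS <- sum(spec@NT)
  NS <- spec@NS
  LT <- spec@LT

  out <- .withSeed(spec@seed, {
    values <- matrix(0, nrow = NS, ncol = NDS)
    shifts <- integer(NDS)
    tplIds <- integer(NDS)
    col0 <- 0L
    for (i in seq_len(spec@N)) {
      ni <- spec@NT[i]
      cols <- col0 + seq_len(ni)
      sh <- sample.int(NS - LT + 1L, ni, replace = TRUE) - 1L
      rows <- outer(seq_len(LT), sh, "+")      # LT x ni sample positions
      idx <- cbind(as.vector(rows), rep(cols, each = LT))
      values[idx] <- tpls[[i]]@samples
      if (spec@P > 0) {
        values[, cols] <- values[, cols] +
          stats::rnorm(NS * ni, 0, sqrt(spec@P * tpls[[i]]@power))
      }
      shifts[cols] <- sh
      tplIds[cols] <- i
      col0 <- col0 + ni
    }
    list(values = values, shifts = shifts, tplIds = tplIds)
  })

  labels <- spec@labelMap[out$tplIds]
  split <- .withSeed(spec@seed + 1L, {
    s <- character(NDS)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      sizes <- .apportion(length(idx), spec@splitFractions)
      s[idx] <- rep(c("train", "val", "test"), times = sizes)
    }
    s
  })

  se <- SummarizedExperiment(
    assays = list(signal = out$values),
    colData = DataFrame(label = labels, templateId = out$tplIds,
                        shift = out$shifts, split = split)
  )
  metadata(se)$spec <- spec
  metadata(se)$templates <- tpls
  ds <- new("SyntheticDataset", se)
  if (spec@PTestExtra > 0) {
    ds <- addTestNoise(ds, spec@PTestExtra)
  }
  ds
}

#' Add extra noise to the test split only
#'
#' Emulates a covariate shift between training and deployment conditions:
#' AWGN with variance `PExtra` times the source-template power is added to
#' every test-split example; train and validation examples are untouched.
#'
#' @param dataset a [SyntheticDataset-class].
#' @param PExtra additional noise-to-signal power fraction (>= 0).
#' @param seed RNG seed; default derived from the spec seed.
#' @return the dataset with noisier test examples.
#' @export
addTestNoise <- function(dataset, PExtra, seed = NULL) {
  stopifnot(is(dataset, "SyntheticDataset"))
  if (PExtra < 0) stop("PExtra must be non-negative")
  if (PExtra == 0) return(dataset)
  spec <- metadata(dataset)$spec
  tpls <- metadata(dataset)$templates
  if (is.null(seed)) seed <- spec@seed + 2L
  testIdx <- which(colData(dataset)$split == "test")
  if (length(testIdx) == 0L) return(dataset)
  pw <- vapply(tpls, slot, numeric(1), "power")
  sds <- sqrt(PExtra * pw[colData(dataset)$templateId[testIdx]])
  vals <- assay(dataset, "signal")
  vals[, testIdx] <- .withSeed(seed, {
    vals[, testIdx] +
      matrix(stats::rnorm(nrow(vals) * length(testIdx)),
             nrow = nrow(vals)) * rep(sds, each = nrow(vals))
  })
  assay(dataset, "signal") <- vals
  metadata(dataset)$PTestExtraApplied <-
    c(metadata(dataset)$PTestExtraApplied, PExtra)
  dataset
}

## ---- accessors -----------------------------------------------------------

.splitIdx <- function(x, split) {
  if (is.null(split)) return(seq_len(ncol(x)))
  split <- match.arg(split, c("train", "val", "test"))
  which(colData(x)$split == split)
}

#' @rdname datasetSpec
#' @param x a [SyntheticDataset-class].
#' @export
setMethod("datasetSpec", "SyntheticDataset", function(x) metadata(x)$spec)

#' Template bank of a dataset
#'
#' @param x a [SyntheticDataset-class].
#' @return list of [TemplateSignal-class] objects.
#' @rdname templates
#' @export
setMethod("templates", "SyntheticDataset", function(x) metadata(x)$templates)

#' Extract example values, labels and shifts
#'
#' `exampleMatrix` returns the signal values with one example per row
#' (model-input orientation); `exampleLabels` and `exampleShifts` return the
#' aligned per-example metadata.
#'
#' @param x a [SyntheticDataset-class].
#' @param split `NULL` (all examples) or one of `"train"`, `"val"`,
#'   `"test"`.
#' @return a numeric matrix (examples x NS), or an integer vector.
#' @rdname exampleMatrix
#' @export
setMethod("exampleMatrix", "SyntheticDataset", function(x, split = NULL) {
  t(assay(x, "signal")[, .splitIdx(x, split), drop = FALSE])
})

#' @rdname exampleMatrix
#' @export
setMethod("exampleLabels", "SyntheticDataset", function(x, split = NULL) {
  colData(x)$label[.splitIdx(x, split)]
})

#' @rdname exampleMatrix
#' @export
setMethod("exampleShifts", "SyntheticDataset", function(x, split = NULL) {
  colData(x)$shift[.splitIdx(x, split)]
})

setMethod("show", "SyntheticDataset", function(object) {
  spec <- metadata(object)$spec
  cat(sprintf("SyntheticDataset: %d examples x %d samples\n",
              ncol(object), nrow(object)))
  if (!is.null(spec)) {
    cat(sprintf("  N=%d templates, P=%.2f, Nc=%d classes, seed=%d\n",
                spec@N, spec@P, max(spec@labelMap), spec@seed))
  }
  print(table(split = colData(object)$split, label = colData(object)$label))
})

setMethod("show", "SyntheticDatasetSpec", function(object) {
  cat(sprintf(
    "SyntheticDatasetSpec: N=%d, LT=%d, NS=%d, P=%.2f, Nc=%d, NDS=%d\n",
    object@N, object@LT, object@NS, object@P, max(object@labelMap),
    sum(object@NT)))
  cat("  NT:", paste(object@NT, collapse = ", "),
      " splits:", paste(object@splitFractions, collapse = "/"),
      " PTestExtra:", object@PTestExtra, " seed:", object@seed, "\n")
})

## ---- serialization -------------------------------------------------------

#' Read and write datasets as plain text
#'
#' `writeDatasetCsv` stores one example per row (`split`, `label`,
#' `templateId`, `shift`, then the `NS` sample values); `readDatasetCsv`
#' reconstructs a [SyntheticDataset-class] (without the generating spec
#' unless a YAML sidecar written by [writeSpecYaml()] is supplied).
#'
#' @param dataset a [SyntheticDataset-class].
#' @param path output/input CSV file.
#' @param specPath optional YAML spec sidecar.
#' @return `readDatasetCsv` returns a [SyntheticDataset-class].
#' @export
writeDatasetCsv <- function(dataset, path) {
  cd <- colData(dataset)
  df <- data.frame(split = cd$split, label = cd$label,
                   templateId = cd$templateId, shift = cd$shift,
                   t(assay(dataset, "signal")))
  colnames(df)[-(1:4)] <- paste0("v", seq_len(nrow(dataset)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDatasetCsv
#' @export
readDatasetCsv <- function(path, specPath = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vals <- t(as.matrix(df[, -(1:4), drop = FALSE]))
  dimnames(vals) <- NULL
  se <- SummarizedExperiment(
    assays = list(signal = vals),
    colData = DataFrame(label = as.integer(df$label),
                        templateId = as.integer(df$templateId),
                        shift = as.integer(df$shift), split = df$split))
  if (!is.null(specPath)) metadata(se)$spec <- readSpecYaml(specPath)
  new("SyntheticDataset", se)
}

#' Spec serialization to YAML
#'
#' @param spec a [SyntheticDatasetSpec-class].
#' @param path YAML file path.
#' @export
writeSpecYaml <- function(spec, path) {
  yaml::write_yaml(list(
    N = spec@N, LT = spec@LT, NS = spec@NS, NT = spec@NT, P = spec@P,
    labelMap = spec@labelMap, splitFractions = spec@splitFractions,
    PTestExtra = spec@PTestExtra, seed = spec@seed), path)
  invisible(path)
}

#' @rdname writeSpecYaml
#' @export
readSpecYaml <- function(path) {
  y <- yaml::read_yaml(path)
  SyntheticDatasetSpec(N = y$N, NT = y$NT, P = y$P, LT = y$LT, NS = y$NS,
              labelMap = y$labelMap, splitFractions = y$splitFractions,
              PTestExtra = y$PTestExtra, seed = y$seed)
}
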