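## Adapters from raw wearable-sensor recordings to model-ready segment
## tensors, plus a synthetic raw-format fixture writer so the whole
## pipeline is testable without downloading the public datasets.

#' Windowing specification
#'
#' @param windowSamples window length in samples (>= 2).
#' @param overlapFraction fractional overlap between consecutive windows in
#'   `[0, 1)`; the stride is `round(windowSamples * (1 - overlapFraction))`.
#' @return list with `window`, `overlap`, `stride`.
#' @examples
#' windowingSpec(52, 0.25)$stride   # 39
#' windowingSpec(128, 0.5)$stride   # 64
#' @export
windowingSpec <- function(windowSamples, overlapFraction = 0) {
  windowSamples <- as.integer(windowSamples)
  if (windowSamples < 2L) stop("window must span at least 2 samples")
  if (overlapFraction < 0 || overlapFraction >= 1) {
    stop("overlap fraction must lie in [0, 1)")
  }
  stride <- as.integer(round(windowSamples * (1 - overlapFraction)))
  if (stride < 1L) stop("resulting stride must be >= 1")
  list(window = windowSamples, overlap = overlapFraction, stride = stride)
}

#' Built-in HAR dataset conventions
#'
#' Windowing, channel and class conventions of the three supported public
#' datasets, plus the depth multiplier at which the multivariate model
#' matches its published parameter budget.
#'
#' @param name `"ucihar"`, `"wisdm"` or `"motionsense"`.
#' @return list with `name`, `Nsen`, `NS`, `NC`, `samplingRate`,
#'   `windowing`, `NF`, `useInputLinear`, `Nch`, `activities`, `channels`.
#' @export
harConfig <- function(name = c("ucihar", "wisdm", "motionsense")) {
  name <- match.arg(name)
  switch(name,
    ucihar = list(
      name = "ucihar", Nsen = 9L, NS = 128L, NC = 6L, samplingRate = 50,
      windowing = windowingSpec(128, 0.5), NF = 30L,
      useInputLinear = FALSE, Nch = 9L,
      activities = c("WALKING", "WALKING_UPSTAIRS", "WALKING_DOWNSTAIRS",
                     "SITTING", "STANDING", "LAYING"),
      channels = paste(rep(c("body_acc", "body_gyro", "total_acc"),
                           each = 3), c("x", "y", "z"), sep = "_")),
    wisdm = list(
      name = "wisdm", Nsen = 3L, NS = 52L, NC = 6L, samplingRate = 20,
      windowing = windowingSpec(52, 0.25), NF = 40L,
      useInputLinear = TRUE, Nch = 9L,
      activities = c("Walking", "Jogging", "Upstairs", "Downstairs",
                     "Sitting", "Standing"),
      channels = c("x", "y", "z")),
    motionsense = list(
      name = "motionsense", Nsen = 6L, NS = 128L, NC = 6L, samplingRate = 50,
      windowing = windowingSpec(128, 0), NF = 30L,
      useInputLinear = FALSE, Nch = 6L,
      activities = c("dws", "ups", "wlk", "jog", "sit", "std"),
      channels = c("userAcceleration.x", "userAcceleration.y",
                   "userAcceleration.z", "rotationRate.x", "rotationRate.y",
                   "rotationRate.z"))
  )
}

#' Segment a continuous recording into labeled windows
#'
#' Windows start at multiples of the stride (0-based, half-open
#' `[start, start + window)`).  Under the strict label rule (default) a
#' window spanning a label change is dropped; under majority vote it keeps
#' the most frequent label (ties to the earliest label value).
#'
#' @param values numeric matrix (samples x channels) or vector.
#' @param labels per-sample labels (length `nrow(values)`).
#' @param spec a [windowingSpec()].
#' @param labelRule `"strict"` or `"majority"`.
#' @return list with `x` (array `n x window x channels`) and `y` (labels);
#'   zero windows (with a warning) when the recording is shorter than one
#'   window.
#' @export
segmentWindows <- function(values, labels, spec,
                           labelRule = c("strict", "majority")) {
  labelRule <- match.arg(labelRule)
  if (is.factor(labels)) labels <- as.character(labels)
  values <- as.matrix(values)
  L <- nrow(values)
  C <- ncol(values)
  W <- spec$window
  if (length(labels) != L) stop("labels must align with samples")
  if (L < W) {
    warning("recording shorter than one window; no segments produced")
    return(list(x = array(0, dim = c(0L, W, C)), y = labels[0]))
  }
  starts <- seq(1L, L - W + 1L, by = spec$stride)
  keep <- logical(length(starts))
  y <- vector(class(labels), length(starts))
  for (i in seq_along(starts)) {
    lab <- labels[starts[i]:(starts[i] + W - 1L)]
    u <- unique(lab)
    if (length(u) == 1L) {
      keep[i] <- TRUE
      y[i] <- u
    } else if (labelRule == "majority") {
      keep[i] <- TRUE
      cnt <- tabulate(match(lab, u))
      y[i] <- u[which.max(cnt)]    # ties to the first-occurring label
    }
  }
  starts <- starts[keep]
  x <- array(0, dim = c(length(starts), W, C))
  for (i in seq_along(starts)) {
    x[i, , ] <- values[starts[i]:(starts[i] + W - 1L), ]
  }
  list(x = x, y = y[keep])
}

## read one fixed-width whitespace signal file (n windows x 128 values)
.readInertialFile <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE)
  matrix(v, ncol = 128L, byrow = TRUE)
}

#' Load the UCI-HAR pre-segmented dataset
#'
#' Reads the distributed "Inertial Signals" fixed-width text layout and
#' honors the dataset's own train/test partition.  Channel order is fixed
#' and documented: body_acc x/y/z, body_gyro x/y/z, total_acc x/y/z.
#'
#' @param root dataset root containing `train/` and `test/`.
#' @return list with `train` and `test`, each holding `x`
#'   (`n x 128 x 9` array) and `y` (integer labels 1..6), plus
#'   `activities` and `channels`.
#' @export
loadUciHar <- function(root) {
  cfg <- harConfig("ucihar")
  out <- list()
  for (part in c("train", "test")) {
    sigDir <- file.path(root, part, "Inertial Signals")
    yFile <- file.path(root, part, paste0("y_", part, ".txt"))
    if (!dir.exists(sigDir) || !file.exists(yFile)) {
      stop("expected layout <root>/", part, "/Inertial Signals/*_", part,
           ".txt and <root>/", part, "/y_", part, ".txt under ", root)
    }
    y <- as.integer(scan(yFile, what = numeric(), quiet = TRUE))
    x <- array(0, dim = c(length(y), 128L, 9L))
    for (ci in seq_along(cfg$channels)) {
      f <- file.path(sigDir, paste0(cfg$channels[ci], "_", part, ".txt"))
      if (!file.exists(f)) stop("missing signal file: ", f)
      m <- .readInertialFile(f)
      if (nrow(m) != length(y)) stop("window count mismatch in ", f)
      x[, , ci] <- m
    }
    out[[part]] <- list(x = x, y = y)
  }
  out$activities <- cfg$activities
  out$channels <- cfg$channels
  out
}

#' Load the WISDM-AR raw accelerometer file
#'
#' Parses the raw `user,activity,timestamp,x,y,z;` dialect (trailing
#' semicolons tolerated), segments contiguous per-user per-activity runs
#' with the 52-sample / 25%-overlap convention, and draws a stratified
#' train/validation/test split.  Malformed lines are skipped and counted; a
#' malformed fraction above 5% aborts.
#'
#' @param path raw text file.
#' @param windowing a [windowingSpec()]; default 52 samples, 0.25 overlap.
#' @param splitFractions stratified split fractions (default 64/16/20).
#' @param seed split RNG seed.
#' @return list with `train`/`val`/`test` (each `x`: `n x 52 x 3`, `y`:
#'   integer labels), `activities`, `skipped` (malformed line count).
#' @export
loadWisdm <- function(path, windowing = windowingSpec(52, 0.25),
                      splitFractions = c(0.64, 0.16, 0.20), seed = 1L) {
  cfg <- harConfig("wisdm")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(gsub(";\\s*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, ",")
  ok <- lengths(parts) == 6L
  xyz <- matrix(NA_real_, length(lines), 3L)
  xyz[ok, ] <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(parts[ok], `[`, 4:6))),
           ncol = 3L, byrow = TRUE))
  act <- rep(NA_character_, length(lines))
  act[ok] <- vapply(parts[ok], `[`, character(1), 2L)
  usr <- rep(NA_character_, length(lines))
  usr[ok] <- vapply(parts[ok], `[`, character(1), 1L)
  good <- ok & stats::complete.cases(xyz) & act %in% cfg$activities
  skipped <- sum(!good)
  if (length(lines) > 0L && skipped / length(lines) > 0.05) {
    stop(sprintf("%d of %d lines malformed (> 5%%)", skipped, length(lines)))
  }
  df <- data.frame(user = usr[good], activity = act[good],
                   x = xyz[good, 1L], y = xyz[good, 2L], z = xyz[good, 3L],
                   stringsAsFactors = FALSE)
  ## contiguous same-user same-activity runs in file order
  runId <- cumsum(c(TRUE, df$user[-1L] != df$user[-nrow(df)] |
                          df$activity[-1L] != df$activity[-nrow(df)]))
  segsX <- list()
  segsY <- integer()
  for (r in unique(runId)) {
    rows <- which(runId == r)
    if (length(rows) < windowing$window) next
    seg <- segmentWindows(as.matrix(df[rows, c("x", "y", "z")]),
                          rep(df$activity[rows[1L]], length(rows)),
                          windowing)
    segsX[[length(segsX) + 1L]] <- seg$x
    segsY <- c(segsY,
               rep(match(df$activity[rows[1L]], cfg$activities),
                   dim(seg$x)[1L]))
  }
  if (length(segsX) == 0L) stop("no complete windows in ", path)
  n <- length(segsY)
  x <- array(0, dim = c(n, windowing$window, 3L))
  at <- 0L
  for (s in segsX) {
    k <- dim(s)[1L]
    x[at + seq_len(k), , ] <- s
    at <- at + k
  }
  ## stratified split
  split <- .withSeed(seed, {
    sp <- character(n)
    for (cl in sort(unique(segsY))) {
      idx <- which(segsY == cl)
      idx <- idx[sample.int(length(idx))]
      sizes <- .apportion(length(idx), splitFractions)
      sp[idx] <- rep(c("train", "val", "test"), times = sizes)
    }
    sp
  })
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    i <- which(split == s)
    list(x = x[i, , , drop = FALSE], y = segsY[i])
  })
  out$activities <- cfg$activities
  out$skipped <- skipped
  out
}

#' Load the MotionSense per-trial CSV layout
#'
#' Expects trial directories `<activity>_<trial>` under `root`, each
#' holding per-subject files `sub_<id>.csv` with at least the six motion
#' channels (user acceleration and rotation rate, x/y/z).  The trial-based
#' train/test prepartition is honored: by default the top quarter of trial
#' ids per activity form the test set (override with `testTrials`).
#'
#' @param root directory of trial folders.
#' @param windowing a [windowingSpec()]; default 128 samples,
#'   non-overlapping.
#' @param testTrials optional integer vector of trial ids reserved for the
#'   test split.
#' @return list with `train`/`test` (`x`: `n x 128 x 6`, `y`), and
#'   `activities`.
#' @export
loadMotionSense <- function(root, windowing = windowingSpec(128, 0),
                            testTrials = NULL) {
  cfg <- harConfig("motionsense")
  dirs <- list.dirs(root, recursive = FALSE)
  base <- basename(dirs)
  m <- regmatches(base, regexec("^([a-z]+)_([0-9]+)$", base))
  keep <- lengths(m) == 3L & vapply(m, function(g) {
    length(g) == 3L && g[2L] %in% cfg$activities
  }, logical(1))
  if (!any(keep)) stop("no <activity>_<trial> folders found under ", root)
  dirs <- dirs[keep]
  acts <- vapply(m[keep], `[`, character(1), 2L)
  trials <- as.integer(vapply(m[keep], `[`, character(1), 3L))
  if (is.null(testTrials)) {
    ut <- sort(unique(trials))
    testTrials <- utils::tail(ut, max(1L, ceiling(length(ut) / 4)))
  }
  acc <- list(train = list(x = list(), y = integer()),
              test = list(x = list(), y = integer()))
  for (i in seq_along(dirs)) {
    part <- if (trials[i] %in% testTrials) "test" else "train"
    lab <- match(acts[i], cfg$activities)
    for (f in list.files(dirs[i], pattern = "^sub_.*\\.csv$",
                         full.names = TRUE)) {
      df <- utils::read.csv(f)
      if (!all(cfg$channels %in% colnames(df))) {
        stop("missing motion channels in ", f)
      }
      seg <- segmentWindows(as.matrix(df[, cfg$channels]),
                            rep(lab, nrow(df)), windowing)
      if (dim(seg$x)[1L] == 0L) next
      acc[[part]]$x[[length(acc[[part]]$x) + 1L]] <- seg$x
      acc[[part]]$y <- c(acc[[part]]$y, rep(lab, dim(seg$x)[1L]))
    }
  }
  out <- lapply(acc, function(p) {
    n <- length(p$y)
    x <- array(0, dim = c(n, windowing$window, 6L))
    at <- 0L
    for (s in p$x) {
      k <- dim(s)[1L]
      x[at + seq_len(k), , ] <- s
      at <- at + k
    }
    list(x = x, y = p$y)
  })
  out$activities <- cfg$activities
  out
}

## per-activity, per-channel synthetic motion stream built from the
## template library: tiled template scaled per channel + mild noise
.fixtureStream <- function(activity, nChannels, nSamples, tpls) {
  tp <- tpls[[(activity - 1L) %% length(tpls) + 1L]]@samples
  LT <- length(tp)
  reps <- ceiling(nSamples / LT)
  base <- rep(tp, reps)[seq_len(nSamples)]
  sapply(seq_len(nChannels), function(ch) {
    scale <- 0.5 + ((activity * ch) %% 7) / 7 * 1.5
    round(base * scale + stats::rnorm(nSamples, 0, 0.05), 6)
  })
}

#' Write a synthetic raw-format HAR fixture
#'
#' Emits files mimicking the chosen dataset's raw on-disk layout, with
#' per-activity signals built from the template library (one template per
#' activity, per-channel amplitude scaling), so loaders and the full
#' train/evaluate path run end to end without downloads.  All values are
#' rounded to 6 decimals before writing, so the returned reference data
#' round-trip exactly through the text loaders.
#'
#' @param dataset `"ucihar"`, `"wisdm"` or `"motionsense"`.
#' @param dir output directory (created if needed).
#' @param nSubjects subjects to simulate.
#' @param windowsPerClass windows (ucihar) or window-equivalents
#'   (wisdm/motionsense run lengths) per subject and activity.
#' @param seed RNG seed; fixed seed gives identical files.
#' @return invisibly, the reference data the written files encode (layout
#'   mirrors the matching loader's output).
#' @export
makeHarFixture <- function(dataset = c("ucihar", "wisdm", "motionsense"),
                           dir, nSubjects = 2L, windowsPerClass = 4L,
                           seed = 1L) {
  dataset <- match.arg(dataset)
  cfg <- harConfig(dataset)
  tpls <- makeTemplates(5L, 64L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .withSeed(seed, {
    switch(dataset,
      ucihar = .writeUciharFixture(cfg, dir, nSubjects, windowsPerClass,
                                   tpls),
      wisdm = .writeWisdmFixture(cfg, dir, nSubjects, windowsPerClass, tpls),
      motionsense = .writeMotionSenseFixture(cfg, dir, nSubjects,
                                             windowsPerClass, tpls))
  })
}

.writeUciharFixture <- function(cfg, dir, nSubjects, windowsPerClass, tpls) {
  ref <- list()
  for (part in c("train", "test")) {
    nWin <- nSubjects * cfg$NC * windowsPerClass
    y <- rep(seq_len(cfg$NC), each = nSubjects * windowsPerClass)
    x <- array(0, dim = c(nWin, 128L, 9L))
    for (w in seq_len(nWin)) {
      x[w, , ] <- .fixtureStream(y[w], 9L, 128L, tpls)
    }
    sigDir <- file.path(dir, part, "Inertial Signals")
    dir.create(sigDir, recursive = TRUE, showWarnings = FALSE)
    for (ci in seq_along(cfg$channels)) {
      f <- file.path(sigDir, paste0(cfg$channels[ci], "_", part, ".txt"))
      writeLines(apply(x[, , ci, drop = FALSE], 1L, function(r) {
        paste(sprintf("%.6f", r), collapse = " ")
      }), f)
    }
    writeLines(as.character(y), file.path(dir, part, paste0("y_", part,
                                                            ".txt")))
    ref[[part]] <- list(x = x, y = y)
  }
  ref$activities <- cfg$activities
  ref$channels <- cfg$channels
  invisible(ref)
}

.writeWisdmFixture <- function(cfg, dir, nSubjects, windowsPerClass, tpls) {
  W <- cfg$windowing$window
  stride <- cfg$windowing$stride
  runLen <- W + (windowsPerClass - 1L) * stride
  lines <- character()
  for (s in seq_len(nSubjects)) {
    for (a in seq_len(cfg$NC)) {
      vals <- .fixtureStream(a, 3L, runLen, tpls)
      ts <- seq_len(runLen) * 50000000
      lines <- c(lines, sprintf("%d,%s,%.0f,%.6f,%.6f,%.6f;",
                                s, cfg$activities[a], ts,
                                vals[, 1L], vals[, 2L], vals[, 3L]))
    }
  }
  writeLines(lines, file.path(dir, "wisdm_raw.txt"))
  invisible(list(path = file.path(dir, "wisdm_raw.txt"),
                 activities = cfg$activities))
}

.writeMotionSenseFixture <- function(cfg, dir, nSubjects, windowsPerClass,
                                     tpls) {
  W <- cfg$windowing$window
  nTrials <- 4L
  for (a in seq_len(cfg$NC)) {
    for (tr in seq_len(nTrials)) {
      d <- file.path(dir, paste0(cfg$activities[a], "_", tr))
      dir.create(d, showWarnings = FALSE)
      for (s in seq_len(nSubjects)) {
        vals <- .fixtureStream(a, 6L, W * windowsPerClass, tpls)
        df <- data.frame(attitude.roll = 0, attitude.pitch = 0,
                         attitude.yaw = 0, vals)
        colnames(df)[4:9] <- cfg$channels
        utils::write.csv(df, file.path(d, paste0("sub_", s, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  invisible(list(root = dir, activities = cfg$activities))
}
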