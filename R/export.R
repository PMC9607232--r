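## Portable flat model export: a single little-endian binary file holding a
## JSON manifest (architecture + parameter shapes) followed by the raw
## 32-bit float weights — the deployment artifact whose on-disk size is the
## edge-footprint figure of merit.

.configToList <- function(cfg) {
  list(NS = cfg@NS, Nsen = cfg@Nsen, Nch = cfg@Nch, NF = cfg@NF,
       NK = cfg@NK, NC = cfg@NC, variant = cfg@variant,
       useInputLinear = cfg@useInputLinear, noiseStd = cfg@noiseStd,
       zeroBias = cfg@zeroBias, secondBatchNorm = cfg@secondBatchNorm,
       seed = cfg@seed)
}

.configFromList <- function(l) {
  modelConfig(NS = l$NS, NK = l$NK, NF = l$NF, NC = l$NC, Nsen = l$Nsen,
              Nch = l$Nch, variant = l$variant,
              useInputLinear = l$useInputLinear, noiseStd = l$noiseStd,
              zeroBias = l$zeroBias, secondBatchNorm = l$secondBatchNorm,
              seed = l$seed)
}

#' Export a model as a flat 32-bit-float binary
#'
#' Serializes every parameter (convolution kernels, FC weights, batch
#' normalization parameters and running statistics) as IEEE-754 single
#' precision, preceded by a compact JSON manifest describing the
#' architecture and the parameter layout.  No quantization is applied.
#'
#' @param model an [MFModel-class].
#' @param path output file.
#' @return invisibly, the file size in bytes.
#' @examples
#' m <- buildUnivariate(modelConfig(NS = 128, NK = 64, NF = 4, NC = 4))
#' f <- tempfile(fileext = ".mfm")
#' exportFlatModel(m, f)
#' file.size(f) / 1024   # KB
#' @export
exportFlatModel <- function(model, path) {
  stopifnot(is(model, "MFModel"))
  manifest <- jsonlite::toJSON(list(
    format = "mfcnn-flat",
    version = 1L,
    arch = model@arch,
    config = .configToList(model@config),
    trainable = model@trainable,
    params = lapply(model@params, function(p) {
      if (is.null(dim(p))) length(p) else dim(p)
    })
  ), auto_unbox = TRUE)
  raw <- charToRaw(as.character(manifest))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MFCN"), con)
  writeBin(length(raw), con, size = 4L, endian = "little")
  writeBin(raw, con)
  for (p in model@params) {
    writeBin(as.numeric(p), con, size = 4L, endian = "little")
  }
  flush(con)
  invisible(file.size(path))
}

#' @rdname exportFlatModel
#' @return `readFlatModel` returns the reconstructed [MFModel-class] (with
#'   float32-rounded weights).
#' @export
readFlatModel <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "MFCN") stop("not a flat model file: ", path)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n)))
  cfg <- .configFromList(manifest$config)
  params <- list()
  for (nm in names(manifest$params)) {
    dims <- manifest$params[[nm]]
    vals <- readBin(con, "numeric", prod(dims), size = 4L, endian = "little")
    params[[nm]] <- if (length(dims) > 1L) array(vals, dim = dims) else vals
  }
  new("MFModel", config = cfg, arch = manifest$arch, params = params,
      trainable = manifest$trainable, fcMask = NULL, trained = TRUE)
}
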