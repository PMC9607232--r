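#' @rdname datasetSpec
#' @export
setGeneric("datasetSpec", function(x) standardGeneric("datasetSpec"))

#' @rdname templates
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname exampleMatrix
#' @export
setGeneric("exampleMatrix",
           function(x, split = NULL) standardGeneric("exampleMatrix"))

#' @rdname exampleMatrix
#' @export
setGeneric("exampleLabels",
           function(x, split = NULL) standardGeneric("exampleLabels"))

#' @rdname exampleMatrix
#' @export
setGeneric("exampleShifts",
           function(x, split = NULL) standardGeneric("exampleShifts"))

#' @rdname predictProbs
#' @export
setGeneric("predictProbs", function(model, x) standardGeneric("predictProbs"))

#' @rdname predictProbs
#' @export
setGeneric("predictClasses",
           function(model, x) standardGeneric("predictClasses"))

#' @rdname countParameters
#' @export
setGeneric("countParameters", function(x) standardGeneric("countParameters"))

#' @rdname extractKernels
#' @export
setGeneric("extractKernels", function(model) standardGeneric("extractKernels"))
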