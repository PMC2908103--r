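#' Accessors for scancal objects
#'
#' `sensitivity`, `curvature` and `autofluorescence` return the B, a and g
#' parameters of a [ScannerModel-class] (or of the model inside a
#' [FitResult-class]); `channelName` and `pmtGain` return its metadata;
#' `modelParams` returns the named triple c(B, a, g). `fittedModel`,
#' `meritValue`, `bootstrapCI` and `converged` extract the corresponding
#' pieces of a [FitResult-class]; `layoutTable` returns the per-column
#' data.frame of a [SlideLayout-class] and `reportTable` the per-column
#' audit table of a [ConsistencyReport-class] or the parameter table of a
#' [DiagnosticsReport-class].
#'
#' @param object a scancal S4 object.
#' @return The extracted slot value; see Description.
#' @examples
#' m <- ScannerModel(106, 0.95, 11.90, channel = "Cy3", pmtGain = 100)
#' sensitivity(m); curvature(m); autofluorescence(m)
#' modelParams(m)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("curvature", function(object) standardGeneric("curvature"))
#' @rdname accessors
#' @export
setGeneric("autofluorescence",
           function(object) standardGeneric("autofluorescence"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("pmtGain", function(object) standardGeneric("pmtGain"))
#' @rdname accessors
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))
#' @rdname accessors
#' @export
setGeneric("fittedModel", function(object) standardGeneric("fittedModel"))
#' @rdname accessors
#' @export
setGeneric("meritValue", function(object) standardGeneric("meritValue"))
#' @rdname accessors
#' @export
setGeneric("bootstrapCI", function(object) standardGeneric("bootstrapCI"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("layoutTable", function(object) standardGeneric("layoutTable"))
#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname accessors
setMethod("sensitivity", "ScannerModel", function(object) object@B)
#' @rdname accessors
setMethod("curvature", "ScannerModel", function(object) object@a)
#' @rdname accessors
setMethod("autofluorescence", "ScannerModel", function(object) object@g)
#' @rdname accessors
setMethod("channelName", "ScannerModel", function(object) object@channel)
#' @rdname accessors
setMethod("pmtGain", "ScannerModel", function(object) object@pmtGain)
#' @rdname accessors
setMethod("modelParams", "ScannerModel", function(object)
  c(B = object@B, a = object@a, g = object@g))

#' @rdname accessors
setMethod("sensitivity", "FitResult", function(object) object@model@B)
#' @rdname accessors
setMethod("curvature", "FitResult", function(object) object@model@a)
#' @rdname accessors
setMethod("autofluorescence", "FitResult", function(object) object@model@g)
#' @rdname accessors
setMethod("channelName", "FitResult", function(object) object@model@channel)
#' @rdname accessors
setMethod("pmtGain", "FitResult", function(object) object@model@pmtGain)
#' @rdname accessors
setMethod("modelParams", "FitResult", function(object)
  modelParams(object@model))
#' @rdname accessors
setMethod("fittedModel", "FitResult", function(object) object@model)
#' @rdname accessors
setMethod("meritValue", "FitResult", function(object) object@merit)
#' @rdname accessors
setMethod("bootstrapCI", "FitResult", function(object) object@bootstrapCI)
#' @rdname accessors
setMethod("converged", "FitResult", function(object) object@converged)

#' @rdname accessors
setMethod("layoutTable", "SlideLayout", function(object) object@columns)
#' @rdname accessors
setMethod("reportTable", "ConsistencyReport", function(object) object@table)
#' @rdname accessors
setMethod("reportTable", "DiagnosticsReport",
          function(object) object@parameterTable)
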