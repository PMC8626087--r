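#' @rdname RunTimeSeries-class
#' @param object,x an object.
#' @export
setGeneric("seriesData", function(x) standardGeneric("seriesData"))

#' @rdname RunTimeSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname RunTimeSeries-class
#' @export
setGeneric("censorMask", function(x) standardGeneric("censorMask"))

#' @rdname RunTimeSeries-class
#' @export
setGeneric("stepsApplied", function(x) standardGeneric("stepsApplied"))

#' @rdname RoiSet-class
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname RoiSet-class
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @rdname RoiSet-class
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("rMatrix", function(x) standardGeneric("rMatrix"))

#' @rdname ConnectivityMatrix-class
#' @export
setGeneric("edgeVector", function(x) standardGeneric("edgeVector"))

#' @rdname networkMean
#' @export
setGeneric("networkMean", function(x) standardGeneric("networkMean"))
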