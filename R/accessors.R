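#' @rdname RunTimeSeries-class
#' @export
setMethod("seriesData", "RunTimeSeries", function(x) x@data)

#' @rdname RunTimeSeries-class
#' @export
setMethod("repetitionTime", "RunTimeSeries", function(x) x@tr)

#' @rdname RunTimeSeries-class
#' @export
setMethod("censorMask", "RunTimeSeries", function(x) x@censorMask)

#' @rdname RunTimeSeries-class
#' @export
setMethod("stepsApplied", "RunTimeSeries", function(x) x@stepsApplied)

#' @rdname RunTimeSeries-class
#' @export
setMethod("dim", "RunTimeSeries", function(x) dim(x@data))

#' @rdname RoiSet-class
#' @export
setMethod("roiTable", "RoiSet", function(x) x@roi)

#' @rdname RoiSet-class
#' @export
setMethod("roiNames", "RoiSet", function(x) x@roi$name)

#' @rdname RoiSet-class
#' @export
setMethod("roiLabel", "RoiSet", function(x) x@label)

#' @rdname RoiSet-class
#' @export
setMethod("length", "RoiSet", function(x) nrow(x@roi))

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("zMatrix", "ConnectivityMatrix", function(x) x@z)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("rMatrix", "ConnectivityMatrix", function(x) x@r)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("edgeVector", "ConnectivityMatrix", function(x) {
  ut <- upper.tri(x@z)
  v <- x@z[ut]
  nm <- outer(rownames(x@z), colnames(x@z),
              function(a, b) paste(a, b, sep = "--"))
  names(v) <- nm[ut]
  v
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet '", object@label, "' with ", nrow(object@roi), " spherical seeds\n",
      sep = "")
  print(utils::head(object@roi, 10))
  invisible(NULL)
})

setMethod("show", "RunTimeSeries", function(object) {
  cat("RunTimeSeries: ", nrow(object@data), " frames x ", ncol(object@data),
      " ROIs, TR = ", object@tr, " s\n", sep = "")
  cat("  retained frames: ", sum(object@censorMask), "/",
      length(object@censorMask), "\n", sep = "")
  cat("  steps applied: ",
      if (length(object@stepsApplied)) paste(object@stepsApplied, collapse = " -> ")
      else "(none)", "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "ConnectivityMatrix", function(object) {
  n <- nrow(object@z)
  cat("ConnectivityMatrix [", object@roiSetLabel, "] subject ", object@subject,
      ", session ", object@session, "\n", sep = "")
  cat("  ", n, " ROIs, ", n * (n - 1L) / 2L, " unique edges, mean z = ",
      signif(mean(object@z[upper.tri(object@z)]), 4), "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "StaircaseState", function(object) {
  cat("StaircaseState: level ", signif(object@currentLevel, 4), ", ",
      nrow(object@trialLog), " trials, ", length(object@reversalLevels),
      " reversals", if (object@terminated) " (terminated)", "\n", sep = "")
  invisible(NULL)
})
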