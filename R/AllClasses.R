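#' @import methods
NULL

#' RoiSet: a named set of spherical seed regions
#'
#' Container for a set of spherical regions of interest defined by a centroid in
#' stereotaxic (Talairach) millimetre coordinates and a radius. The two sets the
#' package ships are the 10-node dorsal-ventral attention network (DVAN:
#' bilateral IPS, hMT+, FEF, TPJ, VFC; see [dvanRois()]) and a 10-node
#' default-mode control network ([dmnRois()]).
#'
#' @slot label single string naming the set (e.g. \code{"DVAN"}).
#' @slot roi \code{data.frame} with columns \code{name}, \code{hemisphere},
#'   \code{x}, \code{y}, \code{z} (mm) and \code{radius_mm}.
#'
#' @seealso [dvanRois()], [dmnRois()], [readRoiSet()], [writeRoiSet()]
#' @export
setClass("RoiSet",
  representation(label = "character", roi = "data.frame"))

setValidity("RoiSet", function(object) {
  need <- c("name", "hemisphere", "x", "y", "z", "radius_mm")
  if (length(object@label) != 1L || is.na(object@label))
    return("'label' must be a single string")
  if (!all(need %in% colnames(object@roi)))
    return(paste0("roi table must have columns: ", paste(need, collapse = ", ")))
  if (anyDuplicated(object@roi$name))
    return("ROI names must be unique")
  if (any(object@roi$radius_mm <= 0))
    return("all radii must be positive")
  if (!all(vapply(object@roi[, c("x", "y", "z", "radius_mm")], is.numeric, TRUE)))
    return("x, y, z, radius_mm must be numeric")
  TRUE
})

#' RunTimeSeries: one run of ROI-averaged BOLD data
#'
#' Frames-by-ROIs matrix with its repetition time, a per-frame censor mask and an
#' append-only provenance trail of the cleaning steps applied so far. All
#' preprocessing operations consume and return this class and refuse to run out
#' of pipeline order (see [preprocessRun()]).
#'
#' @slot data numeric matrix, frames in rows, ROIs in columns (named).
#' @slot tr repetition time in seconds.
#' @slot censorMask logical vector, \code{TRUE} for retained frames.
#' @slot stepsApplied character vector of processing-step tags, append-only.
#'
#' @export
setClass("RunTimeSeries",
  representation(data = "matrix", tr = "numeric",
                 censorMask = "logical", stepsApplied = "character"))

setValidity("RunTimeSeries", function(object) {
  if (!is.numeric(object@data)) return("'data' must be a numeric matrix")
  if (length(object@tr) != 1L || object@tr <= 0)
    return("'tr' must be a single positive number")
  if (length(object@censorMask) != nrow(object@data))
    return("censor mask length must equal the frame count")
  TRUE
})

#' ConnectivityMatrix: Fisher-z edge matrix for one subject and session
#'
#' Symmetric matrix of pairwise Pearson correlations between ROI time courses,
#' stored both as raw r and as Fisher z = atanh(r). For an n-ROI set the upper
#' triangle holds the n(n-1)/2 unique edges (45 for the 10-ROI attention
#' network); the diagonal is excluded from every summary.
#'
#' @slot subject subject identifier.
#' @slot session session identifier.
#' @slot roiSetLabel label of the [RoiSet] the matrix was computed on; operations
#'   mixing matrices from different sets raise an error.
#' @slot r symmetric correlation matrix.
#' @slot z symmetric Fisher-z matrix, \code{z = atanh(r)} off the diagonal.
#'
#' @seealso [connectivityMatrix()], [edgeVector()], [networkMean()], [deltaFC()]
#' @export
setClass("ConnectivityMatrix",
  representation(subject = "character", session = "character",
                 roiSetLabel = "character", r = "matrix", z = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  if (nrow(object@r) != ncol(object@r)) return("'r' must be square")
  if (!isTRUE(all.equal(object@r, t(object@r), tolerance = 1e-8)))
    return("'r' must be symmetric")
  if (!identical(dim(object@r), dim(object@z)))
    return("'r' and 'z' must have identical dimensions")
  off <- upper.tri(object@r)
  if (any(abs(object@r[off]) >= 1))
    return("off-diagonal |r| must be < 1 (infinite Fisher z)")
  if (!isTRUE(all.equal(object@z[off], atanh(object@r[off]), tolerance = 1e-8)))
    return("z must equal atanh(r) on the off-diagonal")
  TRUE
})

#' StaircaseState: running state of an adaptive n-down-1-up staircase
#'
#' Mutable record threaded through [stepStaircase()]: the current stimulus
#' level, the consecutive-correct counter, the direction of the last level
#' movement, logged reversal levels and the full trial log.
#'
#' @slot currentLevel current stimulus offset (orientation degrees or
#'   asynchrony ms).
#' @slot consecutiveCorrect correct responses since the last level change.
#' @slot direction \code{"harder"}, \code{"easier"} or \code{"none"}.
#' @slot reversalLevels levels at which movement direction flipped.
#' @slot trialLog data.frame with columns \code{level}, \code{response},
#'   \code{correct}.
#' @slot terminated has the reversal criterion been met?
#'
#' @seealso [staircaseConfig()], [runStaircase()]
#' @export
setClass("StaircaseState",
  representation(currentLevel = "numeric", consecutiveCorrect = "integer",
                 direction = "character", reversalLevels = "numeric",
                 trialLog = "data.frame", terminated = "logical"))

setValidity("StaircaseState", function(object) {
  if (!object@direction %in% c("harder", "easier", "none"))
    return("direction must be 'harder', 'easier' or 'none'")
  TRUE
})
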