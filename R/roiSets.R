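#' Construct a RoiSet from a coordinate table
#'
#' @param roi data.frame with columns \code{name}, \code{hemisphere}, \code{x},
#'   \code{y}, \code{z} (Talairach mm) and \code{radius_mm}.
#' @param label single string naming the set.
#' @return a [RoiSet-class] object.
#' @examples
#' rs <- RoiSet(data.frame(name = c("A", "B"), hemisphere = c("L", "R"),
#'                         x = c(-20, 20), y = 0, z = 0, radius_mm = 6),
#'              label = "toy")
#' length(rs)
#' @export
RoiSet <- function(roi, label = "ROI set") {
  roi <- as.data.frame(roi)
  new("RoiSet", label = label, roi = roi)
}

#' Built-in seed sets: attention network and default-mode control network
#'
#' `dvanRois()` returns the 10 spherical seeds of the dorsal-ventral attention
#' network (bilateral IPS, hMT+, FEF, TPJ and VFC) at their published group-mean
#' Talairach centroids with 6-mm radii. `dmnRois()` returns a 10-node
#' default-mode control set (medial prefrontal, posterior cingulate, lateral
#' temporal, bilateral IPL, parahippocampal and hippocampal seeds); its centers
#' are synthetic placeholders at literature-typical locations, chosen well away
#' from the attention-network spheres, and should be overridden with study
#' coordinates when available.
#'
#' @return a [RoiSet-class] with 10 ROIs.
#' @examples
#' dvanRois()
#' @export
dvanRois <- function() {
  readRoiSet(system.file("extdata", "dvan_rois.tsv", package = "attnfc"),
             label = "DVAN")
}

#' @rdname dvanRois
#' @export
dmnRois <- function() {
  readRoiSet(system.file("extdata", "dmn_rois_synthetic.tsv", package = "attnfc"),
             label = "DMN")
}

#' Read or write a RoiSet as a tab-separated table
#'
#' The TSV mirrors the coordinate-table layout: columns \code{name},
#' \code{hemisphere}, \code{x}, \code{y}, \code{z}, \code{radius_mm}.
#'
#' @param path file path.
#' @param label set label attached on read.
#' @param x a [RoiSet-class].
#' @return `readRoiSet` returns a [RoiSet-class]; `writeRoiSet` returns `path`
#'   invisibly.
#' @export
readRoiSet <- function(path, label = "ROI set") {
  roi <- utils::read.delim(path, stringsAsFactors = FALSE)
  RoiSet(roi, label = label)
}

#' @rdname readRoiSet
#' @export
writeRoiSet <- function(x, path) {
  utils::write.table(roiTable(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
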