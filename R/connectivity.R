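## Seed-based functional connectivity: spherical ROI extraction from 4D
## volumes, Pearson/Fisher-z edge matrices, network means, session differences
## (delta FC) and within-subject-first group averaging.

#' Extract the mean time course of a spherical ROI from a 4D volume
#'
#' Averages, frame by frame, all voxels whose centers (world coordinates via
#' the affine; voxel indices 0-based) lie within `radius_mm` of the ROI center.
#'
#' @param volume 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix.
#' @param roi single-row ROI data.frame (columns `name`, `x`, `y`, `z`,
#'   `radius_mm`) or a [RoiSet-class] (all ROIs extracted).
#' @return numeric vector of length t (or a frames x ROIs matrix for a
#'   [RoiSet-class]).
#' @export
extractRoiTimeseries <- function(volume, affine, roi) {
  if (is(roi, "RoiSet")) {
    tab <- roiTable(roi)
    out <- vapply(seq_len(nrow(tab)), function(i)
      extractRoiTimeseries(volume, affine, tab[i, , drop = FALSE]),
      numeric(dim(volume)[4]))
    colnames(out) <- tab$name
    return(out)
  }
  dims <- dim(volume)[1:3]
  ctr <- as.numeric(roi[1, c("x", "y", "z")])
  rad <- roi$radius_mm[1]
  ax <- lapply(1:3, function(k) {
    idx <- seq_len(dims[k]) - 1  # 0-based
    affine[k, k] * idx + affine[k, 4]
  })
  # requires an axis-aligned affine (diagonal rotation part)
  rot <- affine[1:3, 1:3]
  if (any(abs(rot[row(rot) != col(rot)]) > 1e-8))
    stop("only axis-aligned affines are supported")
  d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
              (ax[[3]] - ctr[3])^2, `+`)
  inside <- which(d2 <= rad^2)
  if (length(inside) == 0)
    stop(sprintf("ROI '%s': sphere contains no voxel centers", roi$name[1]))
  nvox <- prod(dims)
  nT <- dim(volume)[4]
  flat <- matrix(volume, nrow = nvox, ncol = nT)
  colMeans(flat[inside, , drop = FALSE])
}

#' Pearson / Fisher-z connectivity matrix of a run
#'
#' Pairwise Pearson correlations over the retained frames of every ROI pair,
#' Fisher-z transformed (`z = atanh(r)`). For an n-ROI set the matrix carries
#' n(n-1)/2 unique edges — 45 for a 10-ROI network.
#'
#' @param run a [RunTimeSeries-class] (frames already censored, or with a mask
#'   whose censored frames are excluded from the correlation).
#' @param subject,session identifiers stored on the result.
#' @param roiSetLabel label of the ROI set the run was extracted from.
#' @param clip if `TRUE`, correlations with `|r| = 1` are clipped to
#'   `1 - 1e-7` instead of raising an error.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(run, subject = "s1", session = "1",
                               roiSetLabel = "ROI set", clip = FALSE) {
  X <- seriesData(run)[censorMask(run), , drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 retained frames")
  v <- apply(X, 2, stats::var)
  if (any(v <= 0))
    stop(sprintf("zero-variance ROI(s): %s",
                 paste(colnames(X)[v <= 0], collapse = ", ")))
  r <- stats::cor(X)
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1 - 1e-12)) {
    if (!clip) stop("|r| = 1 on an edge gives infinite Fisher z; set clip = TRUE to clip")
    r[off] <- pmin(pmax(r[off], -(1 - 1e-7)), 1 - 1e-7)
  }
  z <- r
  z[off] <- atanh(r[off])
  diag(z) <- 0
  new("ConnectivityMatrix", subject = as.character(subject),
      session = as.character(session), roiSetLabel = roiSetLabel,
      r = r, z = z)
}

#' Network-mean connectivity
#'
#' Arithmetic mean of the unique (upper-triangle) Fisher-z edges — no diagonal,
#' no double counting.
#'
#' @param x a [ConnectivityMatrix-class].
#' @return list with `subject`, `session`, `roiSetLabel`, `meanZ` and the
#'   `edgeVector` of unique edges.
#' @export
setMethod("networkMean", "ConnectivityMatrix", function(x) {
  ev <- edgeVector(x)
  list(subject = x@subject, session = x@session, roiSetLabel = x@roiSetLabel,
       meanZ = mean(ev), edgeVector = ev)
})

#' Session-to-session connectivity change
#'
#' Elementwise Fisher-z difference, second session minus first
#' (`delta = z(S2) - z(S1)`), for one subject on one ROI set.
#'
#' @param pre,post [ConnectivityMatrix-class] objects for the same subject and
#'   ROI set.
#' @return list of class `deltaFC` with `subject`, `roiSetLabel`, `delta`
#'   (matrix), `meanDelta`, `edgeDelta` (unique-edge vector).
#' @export
deltaFC <- function(pre, post) {
  if (!identical(pre@roiSetLabel, post@roiSetLabel) ||
      !identical(dimnames(pre@z), dimnames(post@z)))
    stop("pre and post matrices are on different ROI sets")
  if (!identical(pre@subject, post@subject))
    stop("pre and post matrices belong to different subjects")
  d <- post@z - pre@z
  ut <- upper.tri(d)
  structure(list(subject = pre@subject, roiSetLabel = pre@roiSetLabel,
                 delta = d, meanDelta = mean(d[ut]), edgeDelta = d[ut]),
            class = "deltaFC")
}

#' Group-by-session summaries, averaging within subject first
#'
#' Values are first computed per subject (one network mean, or 45 edge values),
#' then averaged across the subjects of each group — never pooled across
#' subjects before the subject-level computation.
#'
#' @param perSubject data.frame with columns `subject`, `session`, `value`
#'   (one row per subject/session for the network-mean analysis) or `subject`,
#'   `session`, `edge`, `value` (edge-level analysis).
#' @param design cohort table mapping `subject` to `group`.
#' @return list with `table` (the input joined with group) and `groupMeans`
#'   (group x session mean of the per-subject values).
#' @export
groupAverage <- function(perSubject, design) {
  if (!all(perSubject$subject %in% design$subject))
    stop("unknown subject(s) in the per-subject table")
  tab <- merge(perSubject, design[, c("subject", "group")], by = "subject",
               sort = TRUE)
  groupMeans <- stats::aggregate(value ~ group + session, data = tab, FUN = mean)
  list(table = tab, groupMeans = groupMeans[order(groupMeans$group,
                                                  groupMeans$session), ])
}

#' Write a connectivity matrix as a ROI-labeled square TSV
#' @param x a [ConnectivityMatrix-class].
#' @param path file path.
#' @param what `"z"` or `"r"`.
#' @return `path`, invisibly.
#' @export
writeConnectivityMatrix <- function(x, path, what = c("z", "r")) {
  what <- match.arg(what)
  m <- if (what == "z") zMatrix(x) else rMatrix(x)
  utils::write.table(data.frame(roi = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
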