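## Censoring-aware cleaning of ROI time series: initial-volume drop, nuisance
## regression (12 motion regressors + ventricle signal), detrending, framewise
## displacement scrubbing, least-squares spectral interpolation of censored
## frames, zero-phase band-pass filtering, censor removal and run-retention
## rules.

stepOrder <- c("drop_initial", "nuisance_regression", "detrend",
               "lssd_interpolate", "bandpass", "censor_removed")

# A step may not run after any step later in the canonical order has already
# been recorded.
checkStepOrder <- function(run, step) {
  pos <- match(step, stepOrder)
  later <- stepOrder[stepOrder %in% stepsApplied(run)]
  if (length(later) && max(match(later, stepOrder)) >= pos)
    stop(sprintf("pipeline step '%s' cannot run after '%s' (canonical order: %s)",
                 step, later[which.max(match(later, stepOrder))],
                 paste(stepOrder, collapse = " -> ")))
  invisible(TRUE)
}

recordStep <- function(run, step) {
  run@stepsApplied <- c(run@stepsApplied, step)
  run
}

#' Construct a RunTimeSeries
#'
#' @param data frames x ROIs numeric matrix.
#' @param tr repetition time in seconds.
#' @param censorMask logical retained-frame mask (default all retained).
#' @return a [RunTimeSeries-class].
#' @export
RunTimeSeries <- function(data, tr = 2.0, censorMask = rep(TRUE, nrow(data))) {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("ROI%02d", seq_len(ncol(data)))
  new("RunTimeSeries", data = data, tr = tr, censorMask = censorMask,
      stepsApplied = character(0))
}

#' Censoring configuration
#'
#' @param fdThreshold framewise-displacement scrub threshold in mm (frames with
#'   FD above it are censored).
#' @param runDiscardMm per-dimension instantaneous motion (mm) above which the
#'   whole run is discarded (default 3).
#' @param initialVolumesDropped leading frames removed for non-steady-state
#'   magnetization (default 4).
#' @param minRetainedSeconds minimum retained data for a run to be kept
#'   (default 180 s, i.e. 3 minutes, boundary inclusive).
#' @return list of class `censorConfig`.
#' @export
censorConfig <- function(fdThreshold = 0.5, runDiscardMm = 3.0,
                         initialVolumesDropped = 4, minRetainedSeconds = 180) {
  stopifnot(fdThreshold > 0, runDiscardMm > 0, initialVolumesDropped >= 0,
            minRetainedSeconds > 0)
  structure(list(fdThreshold = fdThreshold, runDiscardMm = runDiscardMm,
                 initialVolumesDropped = as.integer(initialVolumesDropped),
                 minRetainedSeconds = minRetainedSeconds),
            class = "censorConfig")
}

#' Band-pass filter specification
#'
#' @param lowHz high-pass edge in Hz (default 0.009).
#' @param highHz low-pass edge in Hz (default 0.08).
#' @param oversampling frequency-grid oversampling factor of the spectral
#'   interpolation basis (default 8).
#' @param order Butterworth section order of the zero-phase filter (default 2;
#'   the forward-backward pass doubles the effective order).
#' @return list of class `filterSpec`.
#' @export
filterSpec <- function(lowHz = 0.009, highHz = 0.08, oversampling = 8,
                       order = 2) {
  stopifnot(lowHz > 0, highHz > lowHz, oversampling >= 1, order >= 1)
  structure(list(lowHz = lowHz, highHz = highHz,
                 oversampling = oversampling, order = as.integer(order)),
            class = "filterSpec")
}

#' Drop initial non-steady-state volumes
#'
#' Removes the first `k` frames from the data and censor mask (and, when given,
#' from an aligned motion table) so downstream tables stay consistent.
#'
#' @param run a [RunTimeSeries-class].
#' @param config a [censorConfig()] (its `initialVolumesDropped` is used), or an
#'   integer count.
#' @param motion optional aligned frames x 6 motion matrix to trim identically.
#' @return the trimmed run, or a list `(run, motion)` when `motion` is given.
#' @export
dropInitialVolumes <- function(run, config = censorConfig(), motion = NULL) {
  k <- if (is.numeric(config)) as.integer(config) else config$initialVolumesDropped
  checkStepOrder(run, "drop_initial")
  if (nrow(run@data) <= k)
    stop(sprintf("run has %d frames; cannot drop %d initial volumes",
                 nrow(run@data), k))
  if (k > 0) {
    run@data <- run@data[-seq_len(k), , drop = FALSE]
    run@censorMask <- run@censorMask[-seq_len(k)]
  }
  run <- recordStep(run, "drop_initial")
  if (is.null(motion)) return(run)
  if (k > 0) motion <- motion[-seq_len(k), , drop = FALSE]
  list(run = run, motion = motion)
}

#' Assemble the nuisance regressor set
#'
#' Twelve motion-derived regressors (the six rigid-body parameters and their
#' backward-difference first derivatives, first frame set to zero) plus one
#' ventricle global-signal regressor. In synthetic mode (no ventricle signal
#' supplied) a smooth random ventricle trace is generated.
#'
#' @param motion frames x 6 motion matrix.
#' @param ventricleSignal optional frames-long numeric vector.
#' @param seed RNG seed for the synthetic ventricle signal.
#' @return list of class `nuisanceSet` with `motion`, `motionDerivatives`,
#'   `ventricle` and the assembled `design` (frames x 13 matrix).
#' @export
buildNuisanceSet <- function(motion, ventricleSignal = NULL, seed = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have exactly 6 columns")
  if (is.null(colnames(motion)))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
  n <- nrow(motion)
  deriv <- rbind(0, diff(motion))
  colnames(deriv) <- paste0(colnames(motion), "_d1")
  if (is.null(ventricleSignal)) {
    ventricleSignal <- withSeed(seed, {
      x <- stats::rnorm(n)
      as.numeric(stats::filter(x, rep(1 / 5, 5), sides = 2))
    })
    ventricleSignal[is.na(ventricleSignal)] <- 0
  }
  if (length(ventricleSignal) != n)
    stop("ventricle signal length must equal the frame count")
  design <- cbind(motion, deriv, ventricle = ventricleSignal)
  structure(list(motion = motion, motionDerivatives = deriv,
                 ventricle = ventricleSignal, design = design),
            class = "nuisanceSet")
}

#' Regress nuisance signals out of a run
#'
#' Least-squares projection of every ROI time course onto
#' `[intercept | nuisance columns]`; residuals are returned and are orthogonal
#' to every regressor. Collinear columns are dropped with a warning.
#'
#' @param run a [RunTimeSeries-class].
#' @param nuisance a `nuisanceSet` from [buildNuisanceSet()], or a plain
#'   frames x p regressor matrix.
#' @return the run with residual data.
#' @export
regressNuisance <- function(run, nuisance) {
  checkStepOrder(run, "nuisance_regression")
  X <- if (inherits(nuisance, "nuisanceSet")) nuisance$design else
    as.matrix(nuisance)
  if (nrow(X) != nrow(run@data))
    stop("nuisance regressors and run must have equal frame counts")
  D <- cbind(intercept = 1, X)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    keep <- qrD$pivot[seq_len(qrD$rank)]
    warning(sprintf("dropping %d collinear nuisance column(s)",
                    ncol(D) - qrD$rank))
    D <- D[, sort(keep), drop = FALSE]
    qrD <- qr(D)
  }
  run@data <- qr.resid(qrD, run@data)
  recordStep(run, "nuisance_regression")
}

#' Remove the best-fit line from every ROI time course
#'
#' @param run a [RunTimeSeries-class] with at least 3 frames.
#' @return the detrended run.
#' @export
detrendSeries <- function(run) {
  checkStepOrder(run, "detrend")
  n <- nrow(run@data)
  if (n < 3) stop("detrending needs at least 3 frames")
  D <- cbind(1, seq_len(n))
  run@data <- qr.resid(qr(D), run@data)
  recordStep(run, "detrend")
}

#' Framewise displacement and censoring decisions from a motion table
#'
#' Framewise displacement is `FD(t) = sum(|d translations|) +
#' r * sum(|d rotations|)` with `r = 50` mm converting radians to arc length.
#' Frames with FD above `fdThreshold` are censored. The run-discard flag is set
#' when any single-frame change in any of the six dimensions (rotations
#' converted to mm) exceeds `runDiscardMm`.
#'
#' @param motion frames x 6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param config a [censorConfig()].
#' @param headRadius rotation-to-mm conversion radius in mm.
#' @return list with `fd` (per-frame FD, first frame 0), `censorMask` (logical,
#'   `TRUE` = retained), `discardRun` (logical) and `nCensored`.
#' @export
computeCensoring <- function(motion, config = censorConfig(), headRadius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion table must have exactly 6 columns")
  d <- rbind(0, diff(motion))
  fd <- rowSums(abs(d[, 1:3, drop = FALSE])) +
    headRadius * rowSums(abs(d[, 4:6, drop = FALSE]))
  censorMask <- fd <= config$fdThreshold
  dmm <- cbind(d[, 1:3, drop = FALSE], headRadius * d[, 4:6, drop = FALSE])
  discardRun <- any(abs(dmm) > config$runDiscardMm)
  list(fd = fd, censorMask = censorMask, discardRun = discardRun,
       nCensored = sum(!censorMask))
}

#' Attach a censor mask to a run
#'
#' @param run a [RunTimeSeries-class].
#' @param censorMask logical mask, `TRUE` = retained; length must match.
#' @return the run with the mask stored (frames are not removed yet).
#' @export
applyCensorMask <- function(run, censorMask) {
  if (length(censorMask) != nrow(run@data))
    stop("censor mask length must equal the frame count")
  run@censorMask <- censorMask
  run
}

# Sine/cosine basis on the oversampled frequency grid. The grid is capped a
# little above the band-pass upper edge: only in-band content survives the
# subsequent filter, and a full-bandwidth basis on a near-complete grid
# degenerates into a delta comb that cannot interpolate.
lssdBasis <- function(times, totalSpan, tr, oversampling, maxFreq) {
  df <- 1 / (oversampling * totalSpan)
  nyquist <- 1 / (2 * tr)
  freqs <- seq(df, min(maxFreq, nyquist), by = df)
  B <- matrix(1, length(times), 1 + 2 * length(freqs))
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k] * times
    B[, 2 * k] <- cos(w)
    B[, 2 * k + 1] <- sin(w)
  }
  B
}

# Minimum-norm least squares via SVD (the basis is deliberately overcomplete).
# The truncation tolerance trades fit fidelity against coefficient blow-up on
# the overcomplete grid; 1e-6 keeps interior predictions bounded while fitting
# in-band signal to ~1e-7 relative error.
pinvSolve <- function(A, b, tol = 1e-6) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
}

#' Replace censored frames by a least-squares spectral fit
#'
#' Fits a sine/cosine basis (frequency grid oversampled by
#' `spec$oversampling`, extending a margin above the band-pass upper edge) to
#' the retained frames only, by minimum-norm least squares, and replaces
#' censored frames with the fit's prediction so that a uniform-sampling
#' band-pass filter can be applied afterwards. Retained frames are left
#' untouched. With an empty censor mask the run is returned unchanged (so
#' interpolate-then-filter equals direct filtering exactly).
#'
#' @param run a [RunTimeSeries-class] with its censor mask set.
#' @param spec a [filterSpec()].
#' @param minRetainedFraction error out below this retained fraction.
#' @return the run with censored frames replaced.
#' @export
lssdInterpolate <- function(run, spec = filterSpec(),
                            minRetainedFraction = 0.5) {
  checkStepOrder(run, "lssd_interpolate")
  mask <- run@censorMask
  if (all(mask)) return(recordStep(run, "lssd_interpolate"))
  if (sum(mask) < 2)
    stop("fewer than 2 retained frames; cannot interpolate")
  if (mean(mask) < minRetainedFraction)
    stop(sprintf("only %.0f%% of frames retained (< %.0f%%); run fails the retention rule",
                 100 * mean(mask), 100 * minRetainedFraction))
  n <- nrow(run@data)
  times <- (seq_len(n) - 1) * run@tr
  B <- lssdBasis(times, totalSpan = n * run@tr, tr = run@tr,
                 oversampling = spec$oversampling,
                 maxFreq = 1.25 * spec$highHz)
  # spectral prediction is an interpolant only inside the retained span;
  # trigonometric extrapolation beyond it is unbounded, so leading/trailing
  # censored frames take the nearest retained value instead
  ret <- which(mask)
  interior <- !mask & seq_len(n) > min(ret) & seq_len(n) < max(ret)
  coefs <- pinvSolve(B[mask, , drop = FALSE], run@data[mask, , drop = FALSE])
  if (any(interior)) {
    pred <- B[interior, , drop = FALSE] %*% coefs
    # the least-squares fit degrades into ill-conditioned extrapolation when a
    # censored frame sits close to the retained-span boundary; an interpolant
    # never needs to leave the observed range, so clamp column-wise
    lo <- apply(run@data[mask, , drop = FALSE], 2, min)
    hi <- apply(run@data[mask, , drop = FALSE], 2, max)
    pred <- pmin(pmax(pred, rep(lo, each = nrow(pred))),
                 rep(hi, each = nrow(pred)))
    run@data[interior, ] <- pred
  }
  edges <- which(!mask & !interior)
  for (f in edges) {
    nearest <- ret[which.min(abs(ret - f))]
    run@data[f, ] <- run@data[nearest, ]
  }
  recordStep(run, "lssd_interpolate")
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' (\code{signal::filtfilt}), giving approximately unit gain inside
#' `(lowHz, highHz)` — 0.009 to 0.08 Hz by default — strong attenuation well
#' outside it, and zero phase shift.
#'
#' @param run a [RunTimeSeries-class] on a regular sampling grid (i.e. after
#'   interpolation when frames were censored).
#' @param spec a [filterSpec()].
#' @return the filtered run.
#' @export
bandpassSeries <- function(run, spec = filterSpec()) {
  checkStepOrder(run, "bandpass")
  nyquist <- 1 / (2 * run@tr)
  if (spec$highHz >= nyquist)
    stop(sprintf("band edge %.3f Hz is at or above Nyquist (%.3f Hz)",
                 spec$highHz, nyquist))
  bf <- signal::butter(spec$order, c(spec$lowHz, spec$highHz) / nyquist,
                       type = "pass")
  n <- nrow(run@data)
  # demean and reflect-pad to suppress forward-backward edge transients at the
  # very low high-pass edge
  nPad <- min(n - 1, 100L)
  run@data <- apply(run@data, 2, function(x) {
    mu <- mean(x)
    xc <- x - mu
    ext <- c(2 * xc[1] - rev(xc[2:(nPad + 1)]), xc,
             2 * xc[n] - rev(xc[(n - nPad):(n - 1)]))
    as.numeric(signal::filtfilt(bf, ext))[(nPad + 1):(nPad + n)]
  })
  recordStep(run, "bandpass")
}

#' Remove censored frames and apply the run-retention rule
#'
#' Deletes censored (and previously interpolated) frames from the run, then
#' keeps the run only if the retained data span at least
#' `config$minRetainedSeconds` (3 minutes by default, boundary inclusive).
#'
#' @param run a [RunTimeSeries-class] with its censor mask set.
#' @param config a [censorConfig()].
#' @return list of class `retentionResult`: `run` (censored frames removed, or
#'   `NULL` when excluded), `excluded`, `retainedFrames`, `retainedSeconds`,
#'   `nCensored`.
#' @export
applyCensorAndRetention <- function(run, config = censorConfig()) {
  checkStepOrder(run, "censor_removed")
  mask <- run@censorMask
  retained <- sum(mask)
  secs <- retained * run@tr
  excluded <- secs < config$minRetainedSeconds
  out <- NULL
  if (!excluded) {
    run@data <- run@data[mask, , drop = FALSE]
    run@censorMask <- rep(TRUE, retained)
    out <- recordStep(run, "censor_removed")
  }
  structure(list(run = out, excluded = excluded, retainedFrames = retained,
                 retainedSeconds = secs, nCensored = sum(!mask)),
            class = "retentionResult")
}

#' Full preprocessing pipeline for one resting-state run
#'
#' Canonical order: drop initial volumes, nuisance regression, detrend,
#' scrubbing-mask computation, spectral interpolation, band-pass, censor
#' removal and retention check. The censor report (framewise displacement,
#' retained-frame counts, discard flag) is always returned so censoring never
#' biases downstream statistics silently.
#'
#' @param run a [RunTimeSeries-class] (raw, full-length).
#' @param motion aligned frames x 6 motion matrix.
#' @param config a [censorConfig()].
#' @param fspec a [filterSpec()].
#' @param ventricleSignal optional ventricle regressor (full-length); generated
#'   when absent.
#' @param seed RNG seed for the synthetic ventricle signal.
#' @return list of class `preprocResult`: `run` (cleaned, censored frames
#'   removed; `NULL` when the run is discarded or excluded), `excluded`,
#'   `discardRun`, `censorReport` (list with `fd`, `nCensored`,
#'   `retainedFrames`, `retainedSeconds`), `steps`.
#' @export
preprocessRun <- function(run, motion, config = censorConfig(),
                          fspec = filterSpec(), ventricleSignal = NULL,
                          seed = NULL) {
  cens0 <- computeCensoring(motion, config)
  if (cens0$discardRun)
    return(structure(list(run = NULL, excluded = TRUE, discardRun = TRUE,
                          censorReport = list(fd = cens0$fd,
                                              nCensored = cens0$nCensored,
                                              retainedFrames = 0L,
                                              retainedSeconds = 0),
                          steps = character(0)),
                     class = "preprocResult"))
  dropped <- dropInitialVolumes(run, config, motion = motion)
  run <- dropped$run; motion <- dropped$motion
  if (!is.null(ventricleSignal) && config$initialVolumesDropped > 0)
    ventricleSignal <- ventricleSignal[-seq_len(config$initialVolumesDropped)]
  nuis <- buildNuisanceSet(motion, ventricleSignal, seed = seed)
  run <- regressNuisance(run, nuis)
  run <- detrendSeries(run)
  cens <- computeCensoring(motion, config)
  run <- applyCensorMask(run, cens$censorMask)
  run <- lssdInterpolate(run, fspec)
  run <- bandpassSeries(run, fspec)
  ret <- applyCensorAndRetention(run, config)
  structure(list(run = ret$run, excluded = ret$excluded, discardRun = FALSE,
                 censorReport = list(fd = cens$fd, nCensored = ret$nCensored,
                                     retainedFrames = ret$retainedFrames,
                                     retainedSeconds = ret$retainedSeconds),
                 steps = if (!is.null(ret$run)) stepsApplied(ret$run)
                         else character(0)),
            class = "preprocResult")
}
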