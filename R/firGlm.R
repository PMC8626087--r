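## Finite-impulse-response ("deconvolution") GLM for task runs: one predictor
## per post-onset volume per condition over a 20-s window, peak-window
## contrasts around the hemodynamic peak, and FDR thresholding of the
## resulting statistical map.

#' FIR design specification
#'
#' One predictor per volume (sampled every `tr` seconds) per condition,
#' extending `windowSeconds` after trial onset: 10 lags per condition at the
#' 2-s / 20-s defaults. The contrast window holds the `peakWindowVolumes` lags
#' bracketing the hemodynamic peak (about 4 s post-onset); the default window
#' covers lags 1-4, i.e. 2-8 s.
#'
#' @param tr repetition time in seconds.
#' @param windowSeconds FIR window length (must be a multiple of `tr`).
#' @param conditions condition labels.
#' @param peakLagSeconds nominal hemodynamic peak (s post-onset).
#' @param peakWindowVolumes number of lags in the peak contrast.
#' @return list of class `firDesignSpec` with an added `nLags` element.
#' @export
firDesignSpec <- function(tr = 2.0, windowSeconds = 20,
                          conditions = c("OD", "TOJ"),
                          peakLagSeconds = 4, peakWindowVolumes = 4) {
  nLags <- windowSeconds / tr
  if (abs(nLags - round(nLags)) > 1e-9)
    stop("'windowSeconds' must be an integer multiple of 'tr'")
  structure(list(tr = tr, windowSeconds = windowSeconds,
                 conditions = conditions, peakLagSeconds = peakLagSeconds,
                 peakWindowVolumes = as.integer(peakWindowVolumes),
                 nLags = as.integer(round(nLags))),
            class = "firDesignSpec")
}

#' Lags forming the peak-window contrast
#'
#' The `peakWindowVolumes` lags whose times are nearest the nominal peak
#' (`peakLagSeconds`), i.e. the volumes surrounding the peak of the
#' hemodynamic response.
#'
#' @param spec a [firDesignSpec()].
#' @return integer vector of 0-based lags.
#' @export
peakWindowLags <- function(spec) {
  lags <- seq_len(spec$nLags) - 1L
  lagTimes <- lags * spec$tr
  ord <- order(abs(lagTimes - spec$peakLagSeconds), -lagTimes)
  out <- sort(lags[ord[seq_len(spec$peakWindowVolumes)]])
  if (length(out) < spec$peakWindowVolumes)
    stop("peak window does not fit inside the lag range")
  out
}

#' Build an FIR design matrix from an event table
#'
#' One column per (condition, lag): entry 1 at frame `onset + lag`. Baseline
#' columns (intercept and linear drift) are appended. Events whose window runs
#' past the end of the run are truncated with a warning.
#'
#' @param events data.frame with columns `onset` (1-based frame index) and
#'   `condition`.
#' @param spec a [firDesignSpec()].
#' @param nFrames frames in the run.
#' @param drift include a linear-drift baseline column?
#' @return design matrix (nFrames x (conditions*nLags + baseline)) with an
#'   attribute `firColumns` (named list mapping condition to column indices).
#' @export
buildFirDesign <- function(events, spec = firDesignSpec(), nFrames,
                           drift = TRUE) {
  stopifnot(all(c("onset", "condition") %in% colnames(events)))
  if (any(events$onset < 1 | events$onset > nFrames))
    stop("event onsets must lie within the run")
  if (is.unsorted(events$onset)) stop("events must be sorted by onset")
  conds <- spec$conditions
  if (!all(events$condition %in% conds))
    stop("unknown condition label(s) in the event table")
  nL <- spec$nLags
  X <- matrix(0, nFrames, length(conds) * nL)
  colnames(X) <- as.vector(vapply(conds, function(cn)
    sprintf("%s_lag%02d", cn, seq_len(nL) - 1L), character(nL)))
  truncated <- FALSE
  for (i in seq_len(nrow(events))) {
    ci <- match(events$condition[i], conds)
    for (l in seq_len(nL) - 1L) {
      fr <- events$onset[i] + l
      if (fr > nFrames) { truncated <- TRUE; break }
      X[fr, (ci - 1L) * nL + l + 1L] <- 1
    }
  }
  if (truncated)
    warning("some event windows extend past the run end and were truncated")
  base <- if (drift)
    cbind(intercept = 1, drift = scale(seq_len(nFrames), scale = FALSE)[, 1])
  else cbind(intercept = rep(1, nFrames))
  out <- cbind(X, base)
  attr(out, "firColumns") <- stats::setNames(
    lapply(seq_along(conds), function(ci) (ci - 1L) * nL + seq_len(nL)),
    conds)
  attr(out, "spec") <- spec
  out
}

#' Fit the FIR GLM by least squares
#'
#' @param data frames x units matrix (voxels or ROIs).
#' @param design design matrix from [buildFirDesign()].
#' @return list of class `firFit`: `beta` (columns x units), `residVar`
#'   (per-unit residual variance), `df` (residual df), `xtxInv`, `design`
#'   attributes carried over.
#' @export
fitFirGlm <- function(data, design) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(design))
    stop("data and design must have equal frame counts")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, data)
  res <- data - design %*% beta
  df <- nrow(design) - ncol(design)
  residVar <- colSums(res^2) / df
  structure(list(beta = beta, residVar = residVar, df = df,
                 xtxInv = chol2inv(chol(crossprod(design))),
                 firColumns = attr(design, "firColumns"),
                 spec = attr(design, "spec")),
            class = "firFit")
}

#' Peak-window contrast per condition and unit
#'
#' Mean of the lag betas inside the peak window (the volumes surrounding the
#' hemodynamic peak), tested against zero with the usual linear-contrast t
#' statistic `c'beta / sqrt(sigma^2 c'(X'X)^-1 c)`.
#'
#' @param fit a `firFit` from [fitFirGlm()].
#' @param spec a [firDesignSpec()] (defaults to the one stored in the fit).
#' @return data.frame, one row per (condition, unit): `condition`, `unit`,
#'   `contrast`, `t`, `p` (two-sided).
#' @export
contrastPeak <- function(fit, spec = fit$spec) {
  lags <- peakWindowLags(spec)
  units <- colnames(fit$beta)
  if (is.null(units)) units <- sprintf("unit%03d", seq_len(ncol(fit$beta)))
  rows <- lapply(spec$conditions, function(cn) {
    cols <- fit$firColumns[[cn]][lags + 1L]
    cvec <- rep(0, nrow(fit$beta))
    cvec[cols] <- 1 / length(cols)
    est <- as.numeric(crossprod(cvec, fit$beta))
    se <- sqrt(fit$residVar * as.numeric(t(cvec) %*% fit$xtxInv %*% cvec))
    tv <- est / se
    data.frame(condition = cn, unit = units, contrast = est, t = tv,
               p = 2 * stats::pt(abs(tv), fit$df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' FDR-threshold a statistical map
#'
#' Benjamini-Hochberg step-up over the map's p-values at level `q` (default
#' 0.05), via [fdrBH()].
#'
#' @param stats data.frame with a `p` column (e.g. from [contrastPeak()]), or a
#'   numeric p-value vector.
#' @param q FDR level.
#' @return the input with `q` (adjusted p) and `significant` columns added (or,
#'   for a vector input, the [fdrBH()] list).
#' @export
thresholdMap <- function(stats, q = 0.05) {
  if (is.numeric(stats)) return(fdrBH(stats, q))
  res <- fdrBH(stats$p, q)
  stats$pAdj <- res$adjusted
  stats$significant <- res$discoveries
  stats
}

#' Simulate a task run with a known FIR response
#'
#' Event-related data generated as `design %*% beta + noise` for a known 10-lag
#' response profile per condition, used to validate FIR recovery.
#'
#' @param events event table (see [buildFirDesign()]).
#' @param spec a [firDesignSpec()].
#' @param nFrames frames in the run.
#' @param profiles named list: condition -> numeric response profile of length
#'   `spec$nLags`.
#' @param nUnits number of units (voxels/ROIs).
#' @param noiseSd noise standard deviation.
#' @param seed RNG seed.
#' @return list with `data` (frames x units), `design`, `truth` (the profiles).
#' @export
simulateTaskRun <- function(events, spec = firDesignSpec(), nFrames,
                            profiles, nUnits = 1, noiseSd = 1, seed = NULL) {
  X <- buildFirDesign(events, spec, nFrames)
  beta <- matrix(0, ncol(X), nUnits)
  rownames(beta) <- colnames(X)
  for (cn in names(profiles))
    beta[attr(X, "firColumns")[[cn]], ] <- profiles[[cn]]
  data <- withSeed(seed,
    X %*% beta + matrix(stats::rnorm(nFrames * nUnits, sd = noiseSd),
                        nFrames, nUnits))
  list(data = data, design = X, truth = profiles)
}
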