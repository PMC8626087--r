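## Synthetic cohorts, BOLD time series, motion traces and psychophysical
## observers with known ground truth, at the shapes of the study design:
## 3 stimulation groups (Parietal, hMT, Sham) x 10 subjects x 2 fMRI sessions,
## resting runs of 120 volumes at TR = 2 s, 10 attention-network ROIs + 10
## default-mode ROIs.

# Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Generate a randomized cohort table
#'
#' Randomly assigns `nPerGroup` subjects to each stimulation group, mirroring a
#' three-arm design (active stimulation over parietal cortex, active control
#' over hMT+, and Sham) with 10 subjects per arm and two scanning sessions.
#'
#' @param groups character vector of unique group labels.
#' @param nPerGroup subjects per group (>= 2).
#' @param sessions number of scanning sessions (>= 1).
#' @param seed integer RNG seed; identical seeds give identical assignments.
#' @return data.frame with columns `subject`, `group` and `sessions` (count),
#'   one row per subject.
#' @examples
#' head(generateCohort(seed = 1))
#' @export
generateCohort <- function(groups = c("Parietal", "hMT", "Sham"),
                           nPerGroup = 10, sessions = 2, seed = 1) {
  if (anyDuplicated(groups)) stop("group labels must be unique")
  if (nPerGroup < 2) stop("'nPerGroup' must be >= 2")
  if (sessions < 1) stop("'sessions' must be >= 1")
  n <- length(groups) * nPerGroup
  assignment <- withSeed(seed, sample(rep(groups, each = nPerGroup)))
  data.frame(subject = sprintf("S%03d", seq_len(n)),
             group = assignment,
             sessions = sessions,
             stringsAsFactors = FALSE)
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping at zero followed by diagonal renormalization. Used to
#' repair correlation targets after Fisher-z increments push them outside the
#' positive-semi-definite cone.
#'
#' @param mat symmetric matrix.
#' @param minEigen eigenvalues below this are clipped up to it.
#' @return a symmetric positive-semi-definite matrix with unit diagonal.
#' @export
nearestPSD <- function(mat, minEigen = 1e-8) {
  e <- eigen((mat + t(mat)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, minEigen)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

checkCorrelationTarget <- function(C) {
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("correlation target must be symmetric")
  if (!isTRUE(all.equal(unname(diag(C)), rep(1, nrow(C)))))
    stop("correlation target must have unit diagonal")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop(sprintf("correlation target is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev)))
  invisible(ev)
}

#' Simulate ROI BOLD time series with a target correlation structure
#'
#' Generates a frames-by-ROIs matrix whose expected inter-ROI correlation equals
#' `baseCorrelation`. Construction: i.i.d. Gaussian innovations are coloured by
#' the same AR(1) recursion in every ROI (so temporal autocorrelation is added
#' without touching the cross-ROI structure), then mixed through the Cholesky
#' factor of the target matrix; because an identical linear filter applied to
#' every channel commutes with the instantaneous mixing, the cross-correlation
#' of the output equals the target exactly in expectation.
#'
#' @param roiSet a [RoiSet-class], or an integer number of ROIs.
#' @param nFrames frames per run (default 120, i.e. 240 s at TR 2 s).
#' @param tr repetition time in seconds (default 2.0).
#' @param baseCorrelation target correlation matrix (default identity).
#' @param noiseSd marginal signal standard deviation.
#' @param arCoeff lag-1 autocorrelation in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return a [RunTimeSeries-class] with an all-retained censor mask.
#' @examples
#' rts <- simulateRoiTimeSeries(3, nFrames = 120, seed = 1)
#' dim(rts)
#' @export
simulateRoiTimeSeries <- function(roiSet, nFrames = 120, tr = 2.0,
                                  baseCorrelation = NULL, noiseSd = 1,
                                  arCoeff = 0.3, seed = NULL) {
  nms <- if (is(roiSet, "RoiSet")) roiNames(roiSet) else
    sprintf("ROI%02d", seq_len(as.integer(roiSet)))
  p <- length(nms)
  if (is.null(baseCorrelation)) baseCorrelation <- diag(p)
  if (!identical(dim(baseCorrelation), c(p, p)))
    stop("baseCorrelation dimension does not match the ROI count")
  if (arCoeff < 0 || arCoeff >= 1) stop("'arCoeff' must be in [0, 1)")
  checkCorrelationTarget(baseCorrelation)
  L <- chol(baseCorrelation + diag(1e-10, p))
  X <- withSeed(seed, {
    E <- matrix(stats::rnorm(nFrames * p), nFrames, p)
    if (arCoeff > 0) {
      # identical stationary AR(1) colouring per channel
      E[1, ] <- E[1, ] / sqrt(1 - arCoeff^2)
      for (t in 2:nFrames) E[t, ] <- arCoeff * E[t - 1, ] + E[t, ]
      E <- E * sqrt(1 - arCoeff^2)
    }
    E %*% L * noiseSd
  })
  colnames(X) <- nms
  new("RunTimeSeries", data = X, tr = tr,
      censorMask = rep(TRUE, nFrames), stepsApplied = "simulated")
}

#' Describe a localized connectivity effect
#'
#' A Fisher-z increment applied to every within-network edge of one group in one
#' session, emulating a stimulation-induced connectivity increase confined to
#' the attention network of the actively stimulated group.
#'
#' @param targetGroup group label carrying the effect.
#' @param targetNetwork ROI-set label (e.g. `"DVAN"`).
#' @param sessionIndex session carrying the effect (e.g. 2 for post-training).
#' @param deltaZ Fisher-z increment added to all within-network edges.
#' @return a list of class `effectSpec`.
#' @export
effectSpec <- function(targetGroup = "Parietal", targetNetwork = "DVAN",
                       sessionIndex = 2, deltaZ = 0.3) {
  stopifnot(is.finite(deltaZ), sessionIndex >= 1)
  structure(list(targetGroup = targetGroup, targetNetwork = targetNetwork,
                 sessionIndex = as.integer(sessionIndex), deltaZ = deltaZ),
            class = "effectSpec")
}

#' Apply a Fisher-z increment to all unique edges of a correlation matrix
#'
#' Off-diagonal correlations are moved by `deltaZ` in z-space
#' (`r' = tanh(atanh(r) + deltaZ)`). If the result leaves the positive
#' semi-definite cone it is repaired by [nearestPSD()] (or rejected when
#' `repair = FALSE`); the achieved post-repair z increments are returned so the
#' injected ground truth stays honest.
#'
#' @param corr correlation matrix.
#' @param deltaZ z-space increment.
#' @param repair project back to the PSD cone if needed?
#' @return list with elements `corr` (the new target) and `achievedDeltaZ`
#'   (matrix of realized z increments).
#' @export
applyZIncrement <- function(corr, deltaZ, repair = TRUE) {
  z <- atanh(corr * (1 - 1e-12))
  diag(z) <- 0
  z2 <- z + deltaZ
  diag(z2) <- 0
  corr2 <- tanh(z2)
  diag(corr2) <- 1
  ev <- eigen(corr2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    if (!repair)
      stop(sprintf("z increment makes the target non-PSD (smallest eigenvalue %.3g) and repair is disabled",
                   min(ev)))
    corr2 <- nearestPSD(corr2)
  }
  achieved <- atanh(corr2 * (1 - 1e-12)) - z
  diag(achieved) <- 0
  list(corr = corr2, achievedDeltaZ = achieved)
}

#' Build per-group, per-session correlation targets with a localized effect
#'
#' Starting from per-network base correlation targets shared by every group and
#' session, applies the [effectSpec()] increment only to the target group,
#' target session and target network; all other cells are returned untouched.
#'
#' @param baseCorrelation named list of correlation matrices, one per network
#'   label (e.g. `list(DVAN = ..., DMN = ...)`).
#' @param effect an [effectSpec()] (or `NULL` for no effect).
#' @param groups group labels.
#' @param sessions number of sessions.
#' @param repair passed to [applyZIncrement()].
#' @return nested list `specs[[group]][[session]][[network]]`, each element a
#'   list with `corr` and `achievedDeltaZ` (zero matrix where no effect
#'   applies).
#' @export
injectConnectivityEffect <- function(baseCorrelation, effect,
                                     groups = c("Parietal", "hMT", "Sham"),
                                     sessions = 2, repair = TRUE) {
  stopifnot(is.list(baseCorrelation), !is.null(names(baseCorrelation)))
  if (!is.null(effect) && !effect$targetNetwork %in% names(baseCorrelation))
    stop("effect target network not among base correlation networks")
  out <- lapply(groups, function(g) {
    lapply(seq_len(sessions), function(s) {
      lapply(names(baseCorrelation), function(net) {
        C <- baseCorrelation[[net]]
        hit <- !is.null(effect) && effect$deltaZ != 0 &&
          identical(g, effect$targetGroup) && s == effect$sessionIndex &&
          identical(net, effect$targetNetwork)
        if (hit) applyZIncrement(C, effect$deltaZ, repair = repair)
        else list(corr = C, achievedDeltaZ = matrix(0, nrow(C), ncol(C)))
      }) |> stats::setNames(names(baseCorrelation))
    })
  })
  stats::setNames(out, groups)
}

#' Simulate a six-parameter head-motion trace
#'
#' Smooth bounded sinusoidal drift in all six rigid-body parameters (three
#' translations in mm, three rotations in radians) plus single-frame
#' displacement spikes at Bernoulli-sampled frames. The ground-truth spike
#' frames are returned so scrubbing can be validated against them.
#'
#' @param nFrames number of frames.
#' @param spikeRate per-frame spike probability in `[0, 1)`.
#' @param spikeAmplitude spike size in mm (applied to one translation axis).
#' @param driftAmplitude bound on the smooth drift (mm or rad).
#' @param seed integer RNG seed.
#' @return list with `motion` (nFrames x 6 matrix, columns `trans_x`,
#'   `trans_y`, `trans_z`, `rot_x`, `rot_y`, `rot_z`) and `spikeFrames`
#'   (integer vector).
#' @export
simulateMotion <- function(nFrames, spikeRate = 0.05, spikeAmplitude = 0.8,
                           driftAmplitude = 0.2, seed = NULL) {
  stopifnot(nFrames >= 1, spikeRate >= 0, spikeRate < 1)
  withSeed(seed, {
    t <- seq_len(nFrames)
    motion <- vapply(seq_len(6), function(j) {
      # rotation drift scaled so that its 50-mm arc length matches the
      # translation drift bound
      amp <- stats::runif(1, 0, driftAmplitude) * if (j > 3) 1 / 50 else 1
      cycles <- stats::runif(1, 0.5, 2)
      phase <- stats::runif(1, 0, 2 * pi)
      amp * sin(2 * pi * cycles * t / nFrames + phase)
    }, numeric(nFrames))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    spikeFrames <- which(stats::runif(nFrames) < spikeRate)
    spikeFrames <- spikeFrames[spikeFrames > 1]
    for (f in spikeFrames) {
      axis <- sample(1:3, 1)
      motion[f, axis] <- motion[f, axis] + spikeAmplitude * sample(c(-1, 1), 1)
    }
    list(motion = motion, spikeFrames = spikeFrames)
  })
}

#' Write or read a motion table as 6-column TSV
#' @param motion nFrames x 6 matrix.
#' @param path file path.
#' @return `readMotion` returns the matrix; `writeMotion` returns `path`.
#' @export
writeMotion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMotion
#' @export
readMotion <- function(path) {
  as.matrix(utils::read.delim(path))
}

#' Render ROI time series into a synthetic 4D volume
#'
#' Every voxel whose center lies within an ROI sphere (world coordinates via the
#' affine) carries that ROI's time course plus i.i.d. Gaussian noise; background
#' voxels are pure noise. Spheres must not overlap.
#'
#' @param series a [RunTimeSeries-class] whose columns match `roiSet`.
#' @param roiSet a [RoiSet-class]; every center must fall inside the grid.
#' @param gridSpec list with `dim` (3 integers), `voxelSize` (mm, scalar) and
#'   `origin` (world mm of the center of voxel `[1,1,1]`).
#' @param noiseSd standard deviation of the added voxel noise.
#' @param seed integer RNG seed for the noise.
#' @return list with `volume` (4D array x,y,z,t) and `affine` (4x4 voxel-to-world
#'   matrix, 0-based voxel indices, RAS world axes).
#' @export
renderVolume <- function(series, roiSet, gridSpec, noiseSd = 0, seed = NULL) {
  dims <- as.integer(gridSpec$dim)
  vs <- gridSpec$voxelSize
  org <- gridSpec$origin
  stopifnot(length(dims) == 3, length(org) == 3, vs > 0)
  X <- seriesData(series)
  roi <- roiTable(roiSet)
  if (!identical(colnames(X), roi$name))
    stop("series columns must match the ROI set (same names, same order)")
  affine <- rbind(cbind(diag(vs, 3), org), c(0, 0, 0, 1))
  # world coordinates of voxel centers along each axis (0-based indices)
  ax <- lapply(1:3, function(k) org[k] + (seq_len(dims[k]) - 1) * vs)
  membership <- array(0L, dims)
  for (i in seq_len(nrow(roi))) {
    ctr <- as.numeric(roi[i, c("x", "y", "z")])
    rad <- roi$radius_mm[i]
    if (any(ctr < c(ax[[1]][1], ax[[2]][1], ax[[3]][1]) - vs / 2) ||
        any(ctr > c(max(ax[[1]]), max(ax[[2]]), max(ax[[3]])) + vs / 2))
      stop(sprintf("ROI '%s' center lies outside the grid", roi$name[i]))
    d2 <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                (ax[[3]] - ctr[3])^2, `+`)
    inside <- d2 <= rad^2
    if (!any(inside))
      stop(sprintf("ROI '%s' sphere contains no voxel centers", roi$name[i]))
    if (any(membership[inside] != 0L))
      stop(sprintf("ROI '%s' sphere overlaps another ROI", roi$name[i]))
    membership[inside] <- i
  }
  nFrames <- nrow(X)
  vol <- withSeed(seed, {
    v <- if (noiseSd > 0)
      array(stats::rnorm(prod(dims) * nFrames, sd = noiseSd),
            c(dims, nFrames))
    else array(0, c(dims, nFrames))
    for (i in seq_len(nrow(roi))) {
      idx <- which(membership == i)
      for (t in seq_len(nFrames))
        v[idx + (t - 1) * prod(dims)] <- v[idx + (t - 1) * prod(dims)] + X[t, i]
    }
    v
  })
  list(volume = vol, affine = affine, membership = membership)
}

#' Write / read a synthetic 4D volume as NIfTI-1
#'
#' @param rendered result of [renderVolume()] (or any list with `volume` and
#'   `affine`).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `writeVolumeNifti` returns `path`; `readVolumeNifti` returns a list
#'   with `volume` and `affine`.
#' @export
writeVolumeNifti <- function(rendered, path) {
  img <- RNifti::asNifti(rendered$volume)
  RNifti::sform(img) <- structure(rendered$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = as.array(img), affine = unclass(RNifti::xform(img)))
}

#' Psychometric observer model for same/different judgments
#'
#' Cumulative-Gaussian observer: on a "different" trial with stimulus offset
#' `x`, the probability of reporting "different" is
#' `guessRate + (1 - guessRate - lapseRate) * pnorm((x - pse) / slope)`,
#' which passes through 0.5 at the point of subjective equality when guess and
#' lapse rates are equal (and exactly 0.5 when both are zero). On a "same" trial
#' the same model is evaluated at offset 0, giving the false-alarm rate.
#'
#' @param pse point of subjective equality, in stimulus units (orientation
#'   degrees or onset-asynchrony ms).
#' @param slope standard deviation of the cumulative Gaussian (> 0).
#' @param lapseRate,guessRate asymptote parameters in `[0, 0.2]`.
#' @return list of class `observerModel`.
#' @examples
#' m <- observerModel(pse = 2, slope = 1)
#' pDifferent(m, 2)   # 0.5 at the PSE
#' @export
observerModel <- function(pse, slope, lapseRate = 0, guessRate = 0) {
  stopifnot(slope > 0, lapseRate >= 0, lapseRate <= 0.2,
            guessRate >= 0, guessRate <= 0.2)
  structure(list(pse = pse, slope = slope, lapseRate = lapseRate,
                 guessRate = guessRate), class = "observerModel")
}

#' @rdname observerModel
#' @param model an `observerModel`.
#' @param offset stimulus offset(s) in stimulus units.
#' @export
pDifferent <- function(model, offset) {
  model$guessRate + (1 - model$guessRate - model$lapseRate) *
    stats::pnorm((offset - model$pse) / model$slope)
}

#' Simulate one or more same/different responses
#'
#' @param model an [observerModel()].
#' @param offset stimulus offset per trial (used on "different" trials).
#' @param trialType `"different"` or `"same"`, recycled.
#' @param seed optional RNG seed.
#' @return character vector of responses, `"different"` or `"same"`.
#' @export
simulateObserverResponse <- function(model, offset,
                                     trialType = "different", seed = NULL) {
  n <- max(length(offset), length(trialType))
  offset <- rep_len(offset, n)
  trialType <- rep_len(trialType, n)
  p <- ifelse(trialType == "different", pDifferent(model, offset),
              pDifferent(model, 0))
  withSeed(seed, ifelse(stats::runif(n) < p, "different", "same"))
}

#' Simulate per-session behavioral accuracies for a cohort
#'
#' Each subject's accuracy follows a linear drift in logit space across training
#' days, with group-by-task learning rates and binomial trial noise. Phases are
#' `pre`, `day1` ... `day4`, `post`; learning accrued over the four training
#' days carries into the post-test, so a zero learning rate gives equal expected
#' pre and post accuracy.
#'
#' @param cohort cohort table from [generateCohort()].
#' @param learningRates named list: `learningRates[[group]][[task]]` is the
#'   logit-accuracy drift per training day. Defaults emulate an improvement in
#'   orientation discrimination for the Parietal group only, with the temporal
#'   task flat in every group.
#' @param baseline baseline accuracy at threshold (default 0.5).
#' @param nTrials trials per task per session used for binomial sampling.
#' @param subjectSd between-subject SD of baseline logit-accuracy.
#' @param seed integer RNG seed.
#' @return long data.frame: `subject`, `group`, `task`, `phase`, `accuracy`.
#' @export
simulateBehavioralCohort <- function(cohort,
                                     learningRates = list(
                                       Parietal = list(OD = 0.35, TOJ = 0),
                                       hMT = list(OD = 0, TOJ = 0),
                                       Sham = list(OD = 0, TOJ = 0)),
                                     baseline = 0.5, nTrials = 120,
                                     subjectSd = 0.15, seed = 1) {
  tasks <- c("OD", "TOJ")
  phases <- c("pre", "day1", "day2", "day3", "day4", "post")
  trainDays <- c(pre = 0, day1 = 1, day2 = 2, day3 = 3, day4 = 4, post = 4)
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(cohort)), function(i) {
      g <- cohort$group[i]
      rates <- learningRates[[g]]
      if (is.null(rates)) rates <- list(OD = 0, TOJ = 0)
      subjBase <- stats::qlogis(baseline) + stats::rnorm(1, 0, subjectSd)
      do.call(rbind, lapply(tasks, function(task) {
        rate <- if (is.null(rates[[task]])) 0 else rates[[task]]
        p <- stats::plogis(subjBase + rate * trainDays[phases])
        acc <- stats::rbinom(length(p), nTrials, p) / nTrials
        data.frame(subject = cohort$subject[i], group = g, task = task,
                   phase = phases, accuracy = acc, stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
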