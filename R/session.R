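## Cross-task session construction (randomly interleaved orientation and
## temporal-order trials with above-threshold catch trials) and accuracy
## scoring.

#' Session specification for the cross-task procedure
#'
#' A session interleaves two attention tasks on identical stimuli —
#' orientation discrimination (OD) and temporal order judgment (TOJ) — at the
#' observer's individual thresholds: 120 standard trials per task (240 total)
#' plus 6 easy catch trials per block (24 per session at the default 4 blocks),
#' with the test side balanced left/right within each task.
#'
#' @param trialsPerTask standard trials per task (default 120).
#' @param nBlocks blocks per session (default 4).
#' @param catchPerBlock easy catch trials per block (default 6).
#' @param catchOffsets named numeric: above-threshold offsets for catch trials
#'   (defaults about 150 ms for TOJ, about 20 degrees for OD).
#' @param sideBalance balance the test side left/right within each task?
#' @return list of class `sessionSpec`.
#' @export
sessionSpec <- function(trialsPerTask = 120, nBlocks = 4, catchPerBlock = 6,
                        catchOffsets = c(OD = 20, TOJ = 150),
                        sideBalance = TRUE) {
  stopifnot(trialsPerTask >= 1, nBlocks >= 1, catchPerBlock >= 0)
  if (sideBalance && trialsPerTask %% 2 != 0)
    stop("'trialsPerTask' must be even when side balancing is requested")
  if (trialsPerTask %% nBlocks != 0)
    stop("'trialsPerTask' must be divisible by 'nBlocks'")
  structure(list(trialsPerTask = as.integer(trialsPerTask),
                 nBlocks = as.integer(nBlocks),
                 catchPerBlock = as.integer(catchPerBlock),
                 catchOffsets = catchOffsets, sideBalance = sideBalance),
            class = "sessionSpec")
}

#' Build a randomized cross-task trial sequence
#'
#' Standard trials are presented at the task's threshold offset; catch trials at
#' the easy above-threshold offsets. Tasks are randomly interleaved within each
#' block, the test side is balanced left/right per task, and each trial records
#' the cue word naming the attended feature. Half of the standard trials per
#' task are "same" trials (offset effectively absent), half "different".
#'
#' @param spec a [sessionSpec()].
#' @param thresholds named numeric with elements `OD` and `TOJ` (stimulus
#'   offsets at threshold).
#' @param seed integer RNG seed.
#' @return data.frame with columns `trial`, `block`, `task`, `cue`, `side`,
#'   `offset`, `isCatch`, `truth` (`"same"`/`"different"`).
#' @export
buildSession <- function(spec = sessionSpec(), thresholds, seed = 1) {
  if (!all(c("OD", "TOJ") %in% names(thresholds)))
    stop("thresholds for both tasks ('OD', 'TOJ') are required")
  perBlock <- spec$trialsPerTask / spec$nBlocks
  withSeed(seed, {
    blocks <- lapply(seq_len(spec$nBlocks), function(b) {
      std <- do.call(rbind, lapply(c("OD", "TOJ"), function(task) {
        n <- perBlock
        truth <- sample(rep(c("same", "different"), length.out = n))
        side <- sample(rep(c("left", "right"), length.out = n))
        data.frame(task = task, side = side,
                   offset = ifelse(truth == "different",
                                   unname(thresholds[task]), 0),
                   isCatch = FALSE, truth = truth, stringsAsFactors = FALSE)
      }))
      catch <- if (spec$catchPerBlock > 0) {
        task <- sample(rep(c("OD", "TOJ"), length.out = spec$catchPerBlock))
        data.frame(task = task,
                   side = sample(c("left", "right"), spec$catchPerBlock,
                                 replace = TRUE),
                   offset = unname(spec$catchOffsets[task]),
                   isCatch = TRUE, truth = "different",
                   stringsAsFactors = FALSE)
      } else std[0, ]
      blk <- rbind(std, catch)
      blk <- blk[sample(nrow(blk)), ]
      blk$block <- b
      blk
    })
    out <- do.call(rbind, blocks)
    out$trial <- seq_len(nrow(out))
    out$cue <- ifelse(out$task == "OD", "Orientation", "Time")
    rownames(out) <- NULL
    out[, c("trial", "block", "task", "cue", "side", "offset", "isCatch",
            "truth")]
  })
}

#' Simulate observer responses for a built session
#'
#' @param session trial table from [buildSession()].
#' @param observers named list of [observerModel()]s, one per task.
#' @param seed integer RNG seed.
#' @return the session table with `response` and `correct` columns added.
#' @export
simulateSessionResponses <- function(session, observers, seed = NULL) {
  withSeed(seed, {
    resp <- vapply(seq_len(nrow(session)), function(i) {
      m <- observers[[session$task[i]]]
      simulateObserverResponse(m, session$offset[i], session$truth[i])
    }, character(1))
    session$response <- resp
    session$correct <- session$response == session$truth
    session
  })
}

#' Score a completed session into per-task behavioral records
#'
#' Accuracy is the proportion of correct responses over standard trials,
#' computed per task; catch-trial accuracy is reported separately and a subject
#' whose catch accuracy is consistent with chance (binomial test against 0.5)
#' is flagged for exclusion. Trials with missing responses are dropped from the
#' denominator and counted.
#'
#' @param trialLog session table with `response` and `correct` columns.
#' @param chanceAlpha significance level of the at-chance catch check; the
#'   exclusion flag fires when a one-sided binomial test cannot reject
#'   performance at or below chance.
#' @return data.frame, one row per task: `task`, `accuracy`, `nTrials`,
#'   `nMissing`, `catchAccuracy`, `nCatch`, `excludeFlag`.
#' @export
scoreSession <- function(trialLog, chanceAlpha = 0.05) {
  stopifnot(all(c("task", "isCatch", "correct") %in% colnames(trialLog)))
  do.call(rbind, lapply(sort(unique(trialLog$task)), function(task) {
    std <- trialLog[trialLog$task == task & !trialLog$isCatch, ]
    cat_ <- trialLog[trialLog$task == task & trialLog$isCatch, ]
    missing <- is.na(std$correct)
    acc <- mean(std$correct[!missing])
    catchAcc <- if (nrow(cat_)) mean(cat_$correct, na.rm = TRUE) else NA_real_
    exclude <- FALSE
    if (nrow(cat_) > 0) {
      nOK <- sum(cat_$correct, na.rm = TRUE)
      pv <- stats::binom.test(nOK, sum(!is.na(cat_$correct)), p = 0.5,
                              alternative = "greater")$p.value
      exclude <- pv > chanceAlpha   # cannot show above-chance catch performance
    }
    data.frame(task = task, accuracy = acc, nTrials = sum(!missing),
               nMissing = sum(missing), catchAccuracy = catchAcc,
               nCatch = nrow(cat_), excludeFlag = exclude,
               stringsAsFactors = FALSE)
  }))
}

#' Pre-to-post performance change
#'
#' `Delta = post - pre`, in proportion-correct units; negative when performance
#' decreased.
#'
#' @param pre,post accuracies in `[0, 1]`.
#' @return `post - pre`.
#' @examples
#' computeImprovement(0.5, 0.6)  # +0.10
#' @export
computeImprovement <- function(pre, post) {
  stopifnot(all(pre >= 0 & pre <= 1), all(post >= 0 & post <= 1))
  post - pre
}
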