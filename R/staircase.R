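## Adaptive 3-down-1-up staircase thresholding, point-of-subjective-equality
## estimation, threshold validation, cross-task session construction and
## accuracy scoring.

#' Staircase configuration
#'
#' An n-down-1-up staircase on a same/different task: a single incorrect
#' response moves the stimulus offset up (easier), `nDown` consecutive correct
#' responses move it down (harder). A reversal is logged whenever the movement
#' direction flips, and the run terminates after `nReversalsStop` reversals
#' (default 30) or at `maxTrials` (flagged unconverged).
#'
#' @param nDown consecutive-correct rule (default 3).
#' @param nUp errors needed to ease (fixed at 1 in this design).
#' @param stepSize level change per movement, in stimulus units.
#' @param nReversalsStop reversal count at which the run terminates.
#' @param maxTrials safety cap on trial count.
#' @param startLevel starting offset (an easy suprathreshold level).
#' @param reversalWindow number of final reversal levels averaged by the
#'   reversal-mean threshold estimate.
#' @param minLevel floor on the stimulus level.
#' @return list of class `staircaseConfig`.
#' @export
staircaseConfig <- function(nDown = 3, nUp = 1, stepSize = 0.5,
                            nReversalsStop = 30, maxTrials = 400,
                            startLevel = 8, reversalWindow = 8,
                            minLevel = 1e-6) {
  stopifnot(nDown >= 1, nUp >= 1, nReversalsStop >= 2,
            maxTrials > nReversalsStop, stepSize > 0, startLevel > 0)
  structure(list(nDown = as.integer(nDown), nUp = as.integer(nUp),
                 stepSize = stepSize, nReversalsStop = as.integer(nReversalsStop),
                 maxTrials = as.integer(maxTrials), startLevel = startLevel,
                 reversalWindow = as.integer(reversalWindow),
                 minLevel = minLevel),
            class = "staircaseConfig")
}

#' Initialize a fresh staircase state
#'
#' @param config a [staircaseConfig()].
#' @return a [StaircaseState-class] at the start level.
#' @export
newStaircase <- function(config = staircaseConfig()) {
  new("StaircaseState", currentLevel = config$startLevel,
      consecutiveCorrect = 0L, direction = "none",
      reversalLevels = numeric(0),
      trialLog = data.frame(level = numeric(0), response = character(0),
                            correct = logical(0), stringsAsFactors = FALSE),
      terminated = FALSE)
}

#' Advance a staircase by one trial
#'
#' Incorrect: the level moves easier (up) by one step and the correct counter
#' resets. Correct: the counter increments and, on reaching `nDown`, the level
#' moves harder (down) by one step and the counter resets. A reversal is logged
#' at the pre-step level whenever the movement direction flips. The level is
#' floored at `config$minLevel`.
#'
#' @param state a [StaircaseState-class] (not yet terminated).
#' @param correct was the response correct?
#' @param config a [staircaseConfig()].
#' @param response optional response label stored in the trial log.
#' @return the updated [StaircaseState-class].
#' @export
stepStaircase <- function(state, correct, config = staircaseConfig(),
                          response = NA_character_) {
  if (state@terminated) stop("cannot step a terminated staircase")
  lvl <- state@currentLevel
  state@trialLog <- rbind(state@trialLog,
                          data.frame(level = lvl, response = response,
                                     correct = correct,
                                     stringsAsFactors = FALSE))
  move <- NULL
  if (!correct) {
    state@consecutiveCorrect <- 0L
    move <- "easier"
  } else {
    state@consecutiveCorrect <- state@consecutiveCorrect + 1L
    if (state@consecutiveCorrect >= config$nDown) {
      state@consecutiveCorrect <- 0L
      move <- "harder"
    }
  }
  if (!is.null(move)) {
    if (state@direction != "none" && state@direction != move)
      state@reversalLevels <- c(state@reversalLevels, lvl)
    state@direction <- move
    delta <- if (move == "easier") config$stepSize else -config$stepSize
    state@currentLevel <- max(config$minLevel, lvl + delta)
  }
  if (length(state@reversalLevels) >= config$nReversalsStop)
    state@terminated <- TRUE
  state
}

#' Run a staircase against a simulated observer
#'
#' Trials are "different"-type trials at the current staircase level; the
#' observer responds via [simulateObserverResponse()] and a "different" response
#' is scored correct. Terminates at `nReversalsStop` reversals, or at
#' `maxTrials` with `converged = FALSE`.
#'
#' The threshold estimate depends on `method`:
#' \describe{
#'   \item{`"pse"`}{(default) a probit GLM is fitted to the full trial log
#'     (response ~ level) and the threshold is the 50 per cent point — the point
#'     of subjective equality. This is the estimate at which same/different
#'     judgments are expected to be at 50 per cent accuracy.}
#'   \item{`"reversal"`}{mean of the last `reversalWindow` reversal levels. An
#'     n-down-1-up rule converges where p(correct) = 0.5^(1/nDown) (about 79.4
#'     per cent for 3-down-1-up), so this estimate tracks that higher point on
#'     the psychometric function, not the PSE.}
#' }
#'
#' @param observer an [observerModel()].
#' @param config a [staircaseConfig()].
#' @param method `"pse"` or `"reversal"`.
#' @param seed integer RNG seed.
#' @return list with `estimate` (list: `task`-agnostic `value`, `method`,
#'   `converged`, `nTrials`, `nReversals`) and `state` (the final
#'   [StaircaseState-class]).
#' @export
runStaircase <- function(observer, config = staircaseConfig(),
                         method = c("pse", "reversal"), seed = NULL) {
  method <- match.arg(method)
  state <- newStaircase(config)
  withSeed(seed, {
    while (!state@terminated && nrow(state@trialLog) < config$maxTrials) {
      resp <- simulateObserverResponse(observer, state@currentLevel, "different")
      state <- stepStaircase(state, correct = (resp == "different"), config,
                             response = resp)
    }
  })
  converged <- state@terminated
  value <- estimateThreshold(state, config, method)
  list(estimate = list(value = value, method = method, converged = converged,
                       nTrials = nrow(state@trialLog),
                       nReversals = length(state@reversalLevels)),
       state = state)
}

#' Estimate a threshold from a completed staircase state
#'
#' @param state a [StaircaseState-class] with a populated trial log.
#' @param config the [staircaseConfig()] used for the run.
#' @param method see [runStaircase()].
#' @return threshold estimate in stimulus units (`NA` if inestimable).
#' @export
estimateThreshold <- function(state, config = staircaseConfig(),
                              method = c("pse", "reversal")) {
  method <- match.arg(method)
  if (method == "reversal") {
    rl <- state@reversalLevels
    if (length(rl) == 0) return(NA_real_)
    k <- min(config$reversalWindow, length(rl))
    return(mean(rl[(length(rl) - k + 1):length(rl)]))
  }
  log <- state@trialLog
  if (nrow(log) < 5 || length(unique(log$level)) < 2) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(stats::glm(correct ~ level, data = log,
                                family = stats::binomial("probit"))),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(stats::coef(fit)[2]) ||
      stats::coef(fit)[2] <= 0)
    return(NA_real_)
  pse <- -stats::coef(fit)[1] / stats::coef(fit)[2]
  unname(max(pse, 0))
}

#' Validate a threshold estimate with a short block of trials
#'
#' Presents `nTrials` "different"-type trials at the estimated level and returns
#' the proportion of correct ("different") responses; at the true point of
#' subjective equality the expected accuracy is 50 per cent. The estimate
#' passes when the observed accuracy lies within `band` of 0.5.
#'
#' @param observer an [observerModel()].
#' @param level the estimated threshold level.
#' @param nTrials number of validation trials (default 15).
#' @param band half-width of the acceptance band around 0.5.
#' @param seed integer RNG seed.
#' @return list with `accuracy`, `pass`, and the logged `responses`.
#' @export
validateThreshold <- function(observer, level, nTrials = 15, band = 0.2,
                              seed = NULL) {
  resp <- simulateObserverResponse(observer, rep(level, nTrials), "different",
                                   seed = seed)
  acc <- mean(resp == "different")
  list(accuracy = acc, pass = abs(acc - 0.5) <= band, responses = resp)
}
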