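## End-to-end orchestration: simulate a cohort, preprocess, compute
## connectivity, run the statistics battery, and emit report tables. Fully
## reproducible from a single config (YAML-serializable) with one seed.

#' Default pipeline configuration
#'
#' Study-shaped defaults: 3 stimulation groups of 10 subjects, 2 sessions,
#' 120-volume resting runs at TR 2 s, 10 attention-network + 10 default-mode
#' ROIs, exchangeable base correlation r = 0.25 within each network, and a
#' Fisher-z increment of 0.3 on the attention-network edges of the Parietal
#' group in session 2.
#'
#' @param seed integer master seed.
#' @param ... overrides of individual fields (`cohort`, `sim`, `effect`,
#'   `censor`, `filter`, `preprocess`, `behavior`).
#' @return list of class `runConfig`.
#' @export
runConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(groups = c("Parietal", "hMT", "Sham"), nPerGroup = 10,
                  sessions = 2),
    sim = list(nFrames = 120, tr = 2.0, arCoeff = 0.3, noiseSd = 1,
               baseR = 0.25),
    effect = list(targetGroup = "Parietal", targetNetwork = "DVAN",
                  sessionIndex = 2, deltaZ = 0.3),
    censor = list(fdThreshold = 0.5, runDiscardMm = 3.0,
                  initialVolumesDropped = 4, minRetainedSeconds = 180),
    filter = list(lowHz = 0.009, highHz = 0.08, oversampling = 8, order = 2),
    preprocess = TRUE,
    motion = list(spikeRate = 0.03, spikeAmplitude = 0.8),
    behavior = list(run = TRUE)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "runConfig")
}

#' Read / write a pipeline configuration as YAML
#' @param path file path.
#' @param config a `runConfig` list.
#' @return `readRunConfig` returns a `runConfig`; `writeRunConfig` returns
#'   `path` invisibly.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, c(list(seed = raw$seed %||% 1),
                       raw[setdiff(names(raw), "seed")]))
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exchangeable correlation target: unit diagonal, r off the diagonal.
exchangeableCorr <- function(p, r) {
  C <- matrix(r, p, p)
  diag(C) <- 1
  C
}

#' Run the full simulate - preprocess - connect - test pipeline
#'
#' Simulates a cohort with a localized connectivity effect, optionally runs the
#' full censoring-aware preprocessing on every run, computes Fisher-z
#' connectivity matrices and network means for the attention and default-mode
#' networks, session-2-minus-session-1 changes, the group-by-session mixed
#' ANOVA per network, the behavioral battery, and the connectivity-behavior
#' regression. Deterministic given `config$seed`.
#'
#' @param config a [runConfig()].
#' @param roiSets named list of [RoiSet-class] objects (defaults to the
#'   built-in attention and default-mode sets).
#' @return list of class `pipelineResult` with elements `networkMeans` (long
#'   data.frame), `deltas`, `anova` (per network), `behavior`,
#'   `behaviorAnova`, `regression`, `censorSummary`, `config`.
#' @export
runPipeline <- function(config = runConfig(),
                        roiSets = list(DVAN = dvanRois(), DMN = dmnRois())) {
  stopifnot(inherits(config, "runConfig") || is.list(config))
  withSeed(config$seed, {
    cohort <- generateCohort(config$cohort$groups, config$cohort$nPerGroup,
                             config$cohort$sessions,
                             seed = sample.int(2^31 - 1, 1))
    base <- lapply(roiSets, function(rs) exchangeableCorr(length(rs),
                                                          config$sim$baseR))
    eff <- with(config$effect,
                effectSpec(targetGroup, targetNetwork, sessionIndex, deltaZ))
    specs <- injectConnectivityEffect(base, eff, config$cohort$groups,
                                      config$cohort$sessions)
    ccfg <- do.call(censorConfig, config$censor)
    fspec <- do.call(filterSpec, config$filter)
    nm <- list(); deltas <- list(); censRows <- list()
    for (i in seq_len(nrow(cohort))) {
      subj <- cohort$subject[i]; grp <- cohort$group[i]
      mats <- list()
      for (s in seq_len(config$cohort$sessions)) {
        for (net in names(roiSets)) {
          run <- simulateRoiTimeSeries(
            roiSets[[net]], nFrames = config$sim$nFrames, tr = config$sim$tr,
            baseCorrelation = specs[[grp]][[s]][[net]]$corr,
            noiseSd = config$sim$noiseSd, arCoeff = config$sim$arCoeff,
            seed = sample.int(2^31 - 1, 1))
          if (isTRUE(config$preprocess)) {
            mot <- simulateMotion(config$sim$nFrames,
                                  spikeRate = config$motion$spikeRate,
                                  spikeAmplitude = config$motion$spikeAmplitude,
                                  seed = sample.int(2^31 - 1, 1))
            pp <- preprocessRun(run, mot$motion, ccfg, fspec,
                                seed = sample.int(2^31 - 1, 1))
            censRows[[length(censRows) + 1L]] <-
              data.frame(subject = subj, group = grp, session = s, network = net,
                         nCensored = pp$censorReport$nCensored,
                         retainedFrames = pp$censorReport$retainedFrames,
                         excluded = pp$excluded)
            if (pp$excluded) next
            run <- pp$run
          }
          cm <- connectivityMatrix(run, subject = subj, session = as.character(s),
                                   roiSetLabel = net)
          mats[[paste(net, s)]] <- cm
          s_ <- networkMean(cm)
          nm[[length(nm) + 1L]] <-
            data.frame(subject = subj, group = grp, session = paste0("S", s),
                       network = net, value = s_$meanZ,
                       stringsAsFactors = FALSE)
        }
      }
      for (net in names(roiSets)) {
        pre <- mats[[paste(net, 1)]]; post <- mats[[paste(net, 2)]]
        if (!is.null(pre) && !is.null(post)) {
          d <- deltaFC(pre, post)
          deltas[[length(deltas) + 1L]] <-
            data.frame(subject = subj, group = grp, network = net,
                       meanDelta = d$meanDelta, stringsAsFactors = FALSE)
        }
      }
    }
    networkMeans <- do.call(rbind, nm)
    deltaTab <- if (length(deltas)) do.call(rbind, deltas) else NULL
    anovas <- lapply(names(roiSets), function(net) {
      d <- networkMeans[networkMeans$network == net, ]
      complete <- names(which(table(d$subject) == config$cohort$sessions))
      d <- d[d$subject %in% complete, ]
      grpSizes <- table(unique(d[, c("subject", "group")])$group)
      if (length(unique(grpSizes)) > 1) {
        nmin <- min(grpSizes)
        keep <- unlist(lapply(split(unique(d[, c("subject", "group")]),
                                    unique(d[, c("subject", "group")])$group),
                              function(x) utils::head(x$subject, nmin)))
        d <- d[d$subject %in% keep, ]
      }
      mixedRmAnova(data.frame(subject = d$subject, group = d$group,
                              within = d$session, value = d$value))
    })
    names(anovas) <- names(roiSets)
    behavior <- NULL; behaviorAnova <- NULL; regression <- NULL
    if (isTRUE(config$behavior$run)) {
      behavior <- simulateBehavioralCohort(cohort,
                                           seed = sample.int(2^31 - 1, 1))
      pp <- behavior[behavior$phase %in% c("pre", "post") &
                     behavior$task == "OD", ]
      behaviorAnova <- mixedRmAnova(
        data.frame(subject = pp$subject, group = pp$group, within = pp$phase,
                   value = pp$accuracy))
      imp <- with(pp, tapply(accuracy, subject, function(v) v[2] - v[1]))
      impTab <- data.frame(subject = names(imp), improvement = as.numeric(imp))
      if (!is.null(deltaTab)) {
        dv <- deltaTab[deltaTab$network == "DVAN", ]
        m <- merge(impTab, dv, by = "subject")
        if (nrow(m) >= 3 && stats::sd(m$meanDelta) > 0)
          regression <- fcBehaviorRegression(m$meanDelta, m$improvement)
      }
    }
    structure(list(networkMeans = networkMeans, deltas = deltaTab,
                   anova = anovas, behavior = behavior,
                   behaviorAnova = behaviorAnova, regression = regression,
                   censorSummary = if (length(censRows))
                     do.call(rbind, censRows) else NULL,
                   config = config),
              class = "pipelineResult")
  })
}

#' Flatten pipeline statistics into a report table
#'
#' One row per tested effect, in the conventional reporting layout: effect, F,
#' df1, df2 (fractional when sphericity- or variance-corrected), p, partial eta
#' squared and the correction applied.
#'
#' @param results a `pipelineResult` from [runPipeline()], or a (possibly
#'   empty) list of `anovaResult` objects.
#' @return data.frame with columns `analysis`, `effect`, `F`, `df1`, `df2`,
#'   `p`, `petaSq`, `correction`.
#' @export
reportTables <- function(results) {
  pieces <- list()
  collect <- function(name, ar) {
    if (is.null(ar)) return()
    tab <- ar$table
    pieces[[length(pieces) + 1L]] <<-
      data.frame(analysis = name, effect = tab$effect, F = tab$F,
                 df1 = tab$df1, df2 = tab$df2, p = tab$p,
                 petaSq = tab$petaSq, correction = tab$correction,
                 stringsAsFactors = FALSE)
  }
  if (inherits(results, "pipelineResult")) {
    for (net in names(results$anova))
      collect(paste0("rsFC_", net), results$anova[[net]])
    collect("behavior_OD_prepost", results$behaviorAnova)
  } else if (is.list(results)) {
    for (nm in names(results)) collect(nm, results[[nm]])
  }
  if (!length(pieces))
    return(data.frame(analysis = character(0), effect = character(0),
                      F = numeric(0), df1 = numeric(0), df2 = numeric(0),
                      p = numeric(0), petaSq = numeric(0),
                      correction = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Write a report table as TSV
#' @param table data.frame from [reportTables()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
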