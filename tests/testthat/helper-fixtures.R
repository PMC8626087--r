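# Shared fixture builders (everything generated in code; no stored data).

exchangeableCorrFixture <- function(p, r) {
  C <- matrix(r, p, p)
  diag(C) <- 1
  C
}

toyRoiSet <- function(n = 2, spacing = 20, radius = 6, label = "toy") {
  RoiSet(data.frame(name = sprintf("R%d", seq_len(n)),
                    hemisphere = rep(c("L", "R"), length.out = n),
                    x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
                    radius_mm = radius),
         label = label)
}

toyGrid <- function(dim = c(12, 8, 8), voxelSize = 3, origin = c(-9, -9, -9)) {
  list(dim = dim, voxelSize = voxelSize, origin = origin)
}

# brute-force recount of direction flips from a trial log, given the staircase
# rules (independent of the package's reversal bookkeeping)
recountReversals <- function(trialLog, nDown = 3) {
  dir <- "none"; cc <- 0; rev <- 0
  for (i in seq_len(nrow(trialLog))) {
    move <- NULL
    if (!trialLog$correct[i]) { cc <- 0; move <- "easier" }
    else { cc <- cc + 1; if (cc >= nDown) { cc <- 0; move <- "harder" } }
    if (!is.null(move)) {
      if (dir != "none" && dir != move) rev <- rev + 1
      dir <- move
    }
  }
  rev
}

# exhaustive Benjamini-Hochberg step-up definition
bruteForceBH <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k / m * q) kmax <- k
  disc <- logical(m)
  if (kmax > 0) disc[ord[seq_len(kmax)]] <- TRUE
  disc
}

# FFT amplitude of a sinusoidal probe after filtering
probeGain <- function(freq, tr = 2, n = 4000) {
  t <- (seq_len(n) - 1) * tr
  x <- sin(2 * pi * freq * t)
  run <- RunTimeSeries(matrix(x, ncol = 1), tr = tr)
  y <- seriesData(bandpassSeries(run))[, 1]
  # measure amplitude away from the edges
  core <- seq(n %/% 4, 3 * n %/% 4)
  X <- stats::fft(x[core]); Y <- stats::fft(y[core])
  k <- which.max(Mod(X)[2:(length(core) %/% 2)]) + 1
  Mod(Y)[k] / Mod(X)[k]
}
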