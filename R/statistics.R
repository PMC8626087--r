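## Inferential battery: one-way and split-plot (mixed) repeated-measures
## ANOVAs with Mauchly sphericity / Greenhouse-Geisser and Levene /
## Brown-Forsythe corrections, pairwise t-tests with Cohen's d and Bonferroni
## adjustment, the connectivity-behavior regression, and multiplicity
## corrections.

#' One-way between-subjects ANOVA with optional Brown-Forsythe robustness
#'
#' Classical F with degrees of freedom (k-1, N-k) and partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`). Levene's homogeneity test is run
#' alongside; when it rejects (or `robust = TRUE`) the Brown-Forsythe F-ratio
#' with Satterthwaite-adjusted denominator df is reported as well, and the
#' reported `p` switches to it.
#'
#' @param value numeric response.
#' @param group group labels (coerced to factor, >= 2 levels, >= 2 per group).
#' @param robust always report the Brown-Forsythe F-ratio?
#' @param leveneCenter center for Levene's test, `"mean"` (classical) or
#'   `"median"`.
#' @param alpha Levene significance level driving the automatic switch.
#' @return list of class `anovaResult`: `table` (data.frame with `effect`,
#'   `ss`, `df1`, `df2`, `F`, `p`, `petaSq`, `correction`) and `homogeneity`
#'   (from [testHomogeneity()]).
#' @export
oneWayAnova <- function(value, group, robust = FALSE, leveneCenter = "mean",
                        alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups")
  ni <- table(group)
  if (any(ni < 2)) stop("every group needs at least 2 observations")
  N <- length(value)
  gm <- mean(value)
  mi <- tapply(value, group, mean)
  vi <- tapply(value, group, stats::var)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((value - mi[group])^2)
  df1 <- k - 1
  df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  petaSq <- ssb / (ssb + ssw)
  hom <- testHomogeneity(value, group, center = leveneCenter)
  useBF <- robust || hom$p < alpha
  tab <- data.frame(effect = "group", ss = ssb, df1 = df1, df2 = df2,
                    F = Fstat, p = p, petaSq = petaSq, correction = "none",
                    stringsAsFactors = FALSE)
  if (useBF) {
    wi <- (1 - ni / N) * vi
    Fbf <- ssb / sum(wi)
    ci <- wi / sum(wi)
    df2bf <- 1 / sum(ci^2 / (ni - 1))
    pbf <- stats::pf(Fbf, df1, df2bf, lower.tail = FALSE)
    tab <- rbind(tab,
                 data.frame(effect = "group", ss = ssb, df1 = df1,
                            df2 = df2bf, F = Fbf, p = pbf, petaSq = petaSq,
                            correction = "brown-forsythe",
                            stringsAsFactors = FALSE))
  }
  structure(list(table = tab, homogeneity = hom, brownForsytheUsed = useBF),
            class = "anovaResult")
}

#' Levene / Brown-Forsythe test of homogeneity of variances
#'
#' One-way ANOVA on absolute deviations from the group center: the mean
#' (classical Levene) or the median (Brown-Forsythe variant).
#'
#' @param value numeric response.
#' @param group group labels.
#' @param center `"mean"` or `"median"`.
#' @return list of class `homogeneityResult`: `statistic`, `df1`, `df2`, `p`,
#'   `center`.
#' @export
testHomogeneity <- function(value, group, center = c("mean", "median")) {
  center <- match.arg(center)
  group <- factor(group)
  ctr <- tapply(value, group, if (center == "mean") mean else stats::median)
  adev <- abs(value - ctr[group])
  group_ <- group
  fit <- stats::anova(stats::lm(adev ~ group_))
  structure(list(statistic = fit$`F value`[1], df1 = fit$Df[1],
                 df2 = fit$Df[2], p = fit$`Pr(>F)`[1], center = center),
            class = "homogeneityResult")
}

# Orthonormal polynomial-free contrast matrix spanning the space orthogonal to
# the unit vector (k x (k-1), columns orthonormal).
orthonormalContrasts <- function(k) {
  H <- cbind(rep(1 / sqrt(k), k), stats::contr.helmert(k))
  H <- qr.Q(qr(H))
  H[, -1, drop = FALSE]
}

#' Greenhouse-Geisser epsilon from a within-subject covariance matrix
#'
#' `epsilon = tr(T)^2 / ((k-1) tr(T^2))` with `T = M' S M`, where `S` is the
#' k x k covariance of the repeated measures and `M` holds orthonormal
#' contrasts. Bounded in `[1/(k-1), 1]`; exactly 1 for k = 2 and under compound
#' symmetry.
#'
#' @param S k x k covariance matrix of the within-subject levels.
#' @return the epsilon correction factor.
#' @export
greenhouseGeisser <- function(S) {
  k <- nrow(S)
  if (k < 2) stop("need at least 2 within-subject levels")
  if (k == 2) return(1)
  M <- orthonormalContrasts(k)
  T_ <- t(M) %*% S %*% M
  tr <- sum(diag(T_))
  tr2 <- sum(T_ * T_)   # tr(T %*% T) for symmetric T
  if (tr2 <= 0) {
    warning("singular within-subject covariance; epsilon floored at its lower bound")
    return(1 / (k - 1))
  }
  eps <- tr^2 / ((k - 1) * tr2)
  min(1, max(1 / (k - 1), eps))
}

#' Mauchly's test of sphericity from a pooled covariance matrix
#'
#' `W = det(T) / (tr(T)/(k-1))^(k-1)` on the orthonormal-contrast covariance
#' `T`, with the chi-square approximation on `k(k-1)/2 - 1` degrees of freedom;
#' `nd` is the error degrees of freedom of the pooled covariance (N - a for a
#' groups).
#'
#' @param S k x k pooled within-subject covariance.
#' @param nd degrees of freedom of `S`.
#' @return list: `W`, `chiSq`, `df`, `p`.
#' @export
mauchlyTest <- function(S, nd) {
  k <- nrow(S)
  if (k < 3) return(list(W = 1, chiSq = 0, df = 0, p = 1))
  M <- orthonormalContrasts(k)
  T_ <- t(M) %*% S %*% M
  km1 <- k - 1
  W <- det(T_) / (sum(diag(T_)) / km1)^km1
  d <- 1 - (2 * km1^2 + km1 + 2) / (6 * km1 * nd)
  chiSq <- -nd * d * log(max(W, .Machine$double.xmin))
  df <- k * km1 / 2 - 1
  list(W = W, chiSq = chiSq, df = df,
       p = stats::pchisq(chiSq, df, lower.tail = FALSE))
}

#' Mixed (split-plot) repeated-measures ANOVA
#'
#' Between-subjects factor `group`, within-subjects factor `within`, balanced
#' complete design (every subject observed at every within level, equal group
#' sizes). The univariate split-plot decomposition is used: the group effect is
#' tested against subjects-within-groups, the within effect and the
#' group-by-within interaction against the subject-by-within residual. With
#' more than two within levels, Mauchly's test is computed on the pooled
#' within-group covariance; when it rejects at `alpha` (or
#' `ggPolicy = "always"`), Greenhouse-Geisser epsilon multiplies the within and
#' interaction degrees of freedom and their p-values are recomputed.
#'
#' @param data data.frame with columns `subject`, `group`, `within`, `value`.
#' @param ggPolicy `"mauchly"` (correct when Mauchly rejects), `"always"` or
#'   `"never"`.
#' @param alpha Mauchly significance level.
#' @return list of class `anovaResult`: `table` (effects `group`, `within`,
#'   `group:within` with `ss`, `df1`, `df2`, `F`, `p`, `petaSq`,
#'   `correction`), `sphericity` (list with `W`, `chiSq`, `df`, `p`,
#'   `ggEpsilon`).
#' @export
mixedRmAnova <- function(data, ggPolicy = c("mauchly", "always", "never"),
                         alpha = 0.05) {
  ggPolicy <- match.arg(ggPolicy)
  stopifnot(all(c("subject", "group", "within", "value") %in% colnames(data)))
  data$subject <- factor(data$subject)
  data$group <- factor(data$group)
  data$within <- factor(data$within)
  a <- nlevels(data$group)
  k <- nlevels(data$within)
  wide <- stats::xtabs(value ~ subject + within, data = data)
  counts <- stats::xtabs(~ subject + within, data = data)
  if (any(counts != 1))
    stop("design must be complete and balanced: one observation per subject per within level")
  subjGroup <- data$group[match(rownames(wide), data$subject)]
  n <- as.integer(table(subjGroup)[1])
  if (!all(table(subjGroup) == n))
    stop("design must be balanced: equal subjects per group")
  Y <- as.matrix(wide)                     # subjects x within
  gm <- mean(Y)
  subjMeans <- rowMeans(Y)
  groupMeans <- tapply(subjMeans, subjGroup, mean)
  withinMeans <- colMeans(Y)
  cellMeans <- apply(Y, 2, function(col) tapply(col, subjGroup, mean))  # a x k
  ssTotal <- sum((Y - gm)^2)
  ssBetweenSubj <- k * sum((subjMeans - gm)^2)
  ssGroup <- n * k * sum((groupMeans - gm)^2)
  ssSubjWG <- ssBetweenSubj - ssGroup
  ssWithin <- a * n * sum((withinMeans - gm)^2)
  ssCells <- n * sum((cellMeans - gm)^2)
  ssInter <- ssCells - ssGroup - ssWithin
  ssErrW <- ssTotal - ssBetweenSubj - ssWithin - ssInter
  dfGroup <- a - 1; dfSubjWG <- a * (n - 1)
  dfWithin <- k - 1; dfInter <- (a - 1) * (k - 1)
  dfErrW <- a * (n - 1) * (k - 1)
  eff <- function(effect, ss, df1, ssErr, df2, eps = 1, tag = "none") {
    Fv <- (ss / df1) / (ssErr / df2)
    data.frame(effect = effect, ss = ss, df1 = df1 * eps, df2 = df2 * eps,
               F = Fv, p = stats::pf(Fv, df1 * eps, df2 * eps,
                                     lower.tail = FALSE),
               petaSq = ss / (ss + ssErr), correction = tag,
               stringsAsFactors = FALSE)
  }
  # pooled within-group covariance of the repeated measures
  Sg <- Reduce(`+`, lapply(levels(subjGroup), function(g) {
    Ysub <- Y[subjGroup == g, , drop = FALSE]
    crossprod(scale(Ysub, center = TRUE, scale = FALSE))
  })) / (a * n - a)
  sph <- mauchlyTest(Sg, nd = a * n - a)
  ggEps <- greenhouseGeisser(Sg)
  useGG <- k > 2 && (ggPolicy == "always" ||
                     (ggPolicy == "mauchly" && sph$p < alpha))
  epsW <- if (useGG) ggEps else 1
  tag <- if (useGG) "greenhouse-geisser" else "none"
  tab <- rbind(
    eff("group", ssGroup, dfGroup, ssSubjWG, dfSubjWG),
    eff("within", ssWithin, dfWithin, ssErrW, dfErrW, epsW, tag),
    eff("group:within", ssInter, dfInter, ssErrW, dfErrW, epsW, tag))
  structure(list(table = tab,
                 sphericity = c(sph, list(ggEpsilon = ggEps,
                                          ggApplied = useGG)),
                 ssError = c(subjectsWithinGroups = ssSubjWG,
                             withinResidual = ssErrW),
                 ssTotal = ssTotal),
            class = "anovaResult")
}

#' Pairwise t-tests with Cohen's d and Bonferroni adjustment
#'
#' All pairwise comparisons between the levels of `group` (independent
#' samples), or — when `paired = TRUE` — matched comparisons using `subject` to
#' align observations. Cohen's d uses the pooled SD for independent samples and
#' `mean(diff)/sd(diff)` for paired ones; its sign is negative when the first
#' level's mean is below the second's. Bonferroni multiplies each p by the
#' number of comparisons, capped at 1.
#'
#' @param value numeric response.
#' @param group labels whose levels are compared pairwise.
#' @param subject subject identifiers (required when `paired = TRUE`).
#' @param paired paired comparisons?
#' @param welch use Welch-Satterthwaite df for independent comparisons?
#' @param correction `"none"` or `"bonferroni"`.
#' @return data.frame, one row per comparison: `group1`, `group2`, `t`, `df`,
#'   `p`, `pAdj`, `cohensD`, `paired`, `correction`.
#' @export
pairwiseTTests <- function(value, group, subject = NULL, paired = FALSE,
                           welch = !paired,
                           correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  group <- factor(group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    x <- value[group == pr[1]]
    y <- value[group == pr[2]]
    if (paired) {
      if (is.null(subject)) stop("'subject' is required for paired tests")
      sx <- subject[group == pr[1]]
      sy <- subject[group == pr[2]]
      common <- intersect(sx, sy)
      if (length(common) < 2) stop("need at least 2 matched observations")
      x <- x[match(common, sx)]
      y <- y[match(common, sy)]
      d <- x - y
      tt <- stats::t.test(x, y, paired = TRUE)
      cd <- mean(d) / stats::sd(d)
    } else {
      if (length(x) < 2 || length(y) < 2) stop("need at least 2 per group")
      tt <- stats::t.test(x, y, var.equal = !welch)
      sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) /
                 (length(x) + length(y) - 2))
      cd <- (mean(x) - mean(y)) / sp
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, cohensD = cd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- if (correction == "bonferroni")
    bonferroniAdjust(out$p, m = nrow(out)) else out$p
  out$paired <- paired
  out$correction <- correction
  out
}

#' Connectivity-behavior linear regression
#'
#' Ordinary least squares of a per-subject behavioral change on a per-subject
#' connectivity summary, reporting the Pearson correlation, R-squared (equal to
#' r squared for the simple regression) and the slope's t-test p-value.
#'
#' @param x per-subject connectivity summary (e.g. post-session network-mean z).
#' @param y per-subject behavioral change.
#' @return list of class `regressionResult`: `slope`, `intercept`, `pearsonR`,
#'   `rSquared`, `p`, `n`.
#' @export
fcBehaviorRegression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 pearsonR = unname(stats::cor(x, y)),
                 rSquared = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regressionResult")
}

#' Multiplicity corrections
#'
#' `bonferroniAdjust` multiplies each p-value by `m` and caps at 1.
#' `fdrBH` applies the Benjamini-Hochberg step-up procedure at level `q`,
#' returning the adjusted p-values and the discovery mask.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @param q false-discovery-rate level.
#' @return `bonferroniAdjust`: adjusted p-values. `fdrBH`: list with
#'   `adjusted` and logical `discoveries`.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' @rdname bonferroniAdjust
#' @export
fdrBH <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, discoveries = adj <= q)
}
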