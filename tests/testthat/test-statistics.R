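test_that("one-way ANOVA matches the classical decomposition and df", {
  set.seed(11)
  value <- rnorm(30)
  group <- rep(c("Parietal", "hMT", "Sham"), each = 10)
  res <- oneWayAnova(value, group)
  cl <- res$table[res$table$correction == "none", ]
  expect_equal(c(cl$df1, cl$df2), c(2, 27))

  # against the aov oracle
  o <- anova(lm(value ~ factor(group)))
  expect_equal(cl$F, o$`F value`[1], tolerance = 1e-10)
  expect_equal(cl$p, o$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(cl$petaSq, o$`Sum Sq`[1] / sum(o$`Sum Sq`), tolerance = 1e-10)

  # identical group means give F = 0
  same <- rep(c(1, 2, 3), 3)
  res0 <- oneWayAnova(same, rep(c("a", "b", "c"), each = 3))
  expect_equal(res0$table$F[1], 0)

  # 3x3 toy against a hand-computed sum-of-squares decomposition
  v <- c(1, 2, 3, 2, 4, 6, 1, 1, 1)
  g <- rep(c("a", "b", "c"), each = 3)
  mi <- tapply(v, g, mean)
  ssb <- sum(3 * (mi - mean(v))^2)
  ssw <- sum((v - mi[g])^2)
  r2 <- oneWayAnova(v, g)$table[1, ]
  expect_equal(r2$ss, ssb, tolerance = 1e-12)
  expect_equal(r2$F, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
})

test_that("the Brown-Forsythe F-ratio uses Satterthwaite degrees of freedom", {
  set.seed(12)
  value <- c(rnorm(10, sd = 1), rnorm(10, sd = 1), rnorm(12, sd = 4))
  group <- rep(c("a", "b", "c"), c(10, 10, 12))
  res <- oneWayAnova(value, group, robust = TRUE)
  bf <- res$table[res$table$correction == "brown-forsythe", ]
  # formula oracle
  ni <- table(group); N <- length(value)
  mi <- tapply(value, group, mean); vi <- tapply(value, group, var)
  wi <- (1 - ni / N) * vi
  Fstar <- sum(ni * (mi - mean(value))^2) / sum(wi)
  ci <- wi / sum(wi)
  df2 <- 1 / sum(ci^2 / (ni - 1))
  expect_equal(bf$F, unname(Fstar), tolerance = 1e-10)
  expect_equal(bf$df2, unname(df2), tolerance = 1e-10)
  expect_lt(bf$df2, N - 3)
})

test_that("Levene's test matches an ANOVA on absolute deviations", {
  set.seed(13)
  v <- c(rnorm(15, sd = 1), rnorm(15, sd = 3))
  g <- rep(c("a", "b"), each = 15)
  res <- testHomogeneity(v, g, center = "median")
  # independent oracle from car
  o <- car::leveneTest(v, factor(g), center = "median")
  expect_equal(res$statistic, o$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, o$`Pr(>F)`[1], tolerance = 1e-10)

  # 10x variance difference is detected; identical groups give statistic 0
  expect_lt(testHomogeneity(c(rnorm(20, sd = 1), rnorm(20, sd = 10)),
                            rep(c("a", "b"), each = 20))$p, 0.05)
  ident <- rep(c(1, 2, 3, 4), 2)
  expect_equal(testHomogeneity(ident, rep(c("a", "b"), each = 4))$statistic, 0)
})

test_that("the split-plot ANOVA reproduces aov and its sphericity machinery", {
  set.seed(14)
  d <- expand.grid(subject = sprintf("s%02d", 1:30),
                   within = paste0("day", 1:4), stringsAsFactors = FALSE)
  d$group <- rep(rep(c("Parietal", "hMT", "Sham"), each = 10), 4)
  d$value <- rnorm(nrow(d)) + (d$group == "Parietal") *
    (as.integer(factor(d$within)) * 0.2)

  res <- mixedRmAnova(d, ggPolicy = "never")
  o <- summary(aov(value ~ group * within + Error(subject / within),
                   data = transform(d, subject = factor(subject),
                                    group = factor(group),
                                    within = factor(within))))
  ob <- o[["Error: subject"]][[1]]
  ow <- o[["Error: subject:within"]][[1]]
  tab <- res$table
  expect_equal(tab$F[tab$effect == "group"], ob$`F value`[1], tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "within"], ow$`F value`[1], tolerance = 1e-10)
  expect_equal(tab$F[tab$effect == "group:within"], ow$`F value`[2],
               tolerance = 1e-10)
  expect_equal(tab$p[tab$effect == "group:within"], ow$`Pr(>F)`[2],
               tolerance = 1e-10)

  # SS decomposition is exact
  expect_equal(sum(tab$ss) + sum(res$ssError), res$ssTotal, tolerance = 1e-8)

  # design df: Mauchly on 4 within levels has chi-square df 5; the 3 x 10 x 2
  # design gives the interaction df (2, 27)
  expect_equal(res$sphericity$df, 5)
  d2 <- d[d$within %in% c("day1", "day2"), ]
  d2$within <- ifelse(d2$within == "day1", "S1", "S2")
  res2 <- mixedRmAnova(d2)
  expect_equal(unname(unlist(
    res2$table[res2$table$effect == "group:within", c("df1", "df2")])),
    c(2, 27))

  # Greenhouse-Geisser correction increases the p-value wherever F > 1 (the
  # regime in which the correction is consequential)
  resGG <- mixedRmAnova(d, ggPolicy = "always")
  for (i in 2:3) if (tab$F[i] > 1)
    expect_gte(resGG$table$p[i], tab$p[i] - 1e-12)
  expect_gt(sum(tab$F[2:3] > 1), 0)
  expect_lte(resGG$sphericity$ggEpsilon, 1)
  expect_gte(resGG$sphericity$ggEpsilon, 1 / 3)

  expect_error(mixedRmAnova(d[-1, ]), "balanced")
})

test_that("Mauchly W and Greenhouse-Geisser epsilon match the mlm oracle", {
  set.seed(15)
  Y <- matrix(rnorm(25 * 4), 25, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  S <- cov(Y)
  fit <- lm(Y ~ 1)
  mo <- stats::mauchly.test(fit, X = ~1)
  ours <- mauchlyTest(S, nd = 24)
  expect_equal(ours$W, unname(mo$statistic), tolerance = 1e-8)
  expect_equal(ours$p, mo$p.value, tolerance = 1e-6)

  # epsilon against the direct formula on orthonormal contrasts, and bounds
  eps <- greenhouseGeisser(S)
  expect_gte(eps, 1 / 3); expect_lte(eps, 1)
  # compound symmetry and k = 2 give exactly 1
  cs <- matrix(0.4, 4, 4); diag(cs) <- 1
  expect_equal(greenhouseGeisser(cs), 1, tolerance = 1e-12)
  expect_equal(greenhouseGeisser(diag(2)), 1)
  # random covariances stay in bounds
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4, 4); SS <- crossprod(A)
    e <- greenhouseGeisser(SS)
    expect_gte(e, 1 / 3); expect_lte(e, 1)
  }
})

test_that("pairwise t-tests report t, df, Cohen's d and Bonferroni p", {
  x <- c(1, 2, 3, 4, 5)
  same <- pairwiseTTests(c(x, x), rep(c("a", "b"), each = 5),
                         welch = FALSE, correction = "none")
  expect_equal(same$t, 0)
  expect_equal(same$cohensD, 0)

  # paired n = 10 gives df = 9
  set.seed(16)
  pre <- rnorm(10); post <- pre + 0.5 + rnorm(10, sd = 0.3)
  pp <- pairwiseTTests(c(pre, post), rep(c("pre", "post"), each = 10),
                       subject = rep(sprintf("s%d", 1:10), 2), paired = TRUE,
                       correction = "none")
  expect_equal(pp$df, 9)
  dif <- post - pre
  expect_equal(abs(pp$cohensD), mean(dif) / sd(dif), tolerance = 1e-10)

  # Welch df equals the Satterthwaite formula and is below the pooled df
  a <- rnorm(12, sd = 1); b <- rnorm(8, sd = 5)
  w <- pairwiseTTests(c(a, b), rep(c("a", "b"), c(12, 8)), welch = TRUE,
                      correction = "none")
  va <- var(a) / 12; vb <- var(b) / 8
  dfW <- (va + vb)^2 / (va^2 / 11 + vb^2 / 7)
  expect_equal(w$df, dfW, tolerance = 1e-10)
  expect_lt(w$df, 18)

  # Bonferroni multiplies by the number of comparisons and caps at 1
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  adj <- pairwiseTTests(v, g, correction = "bonferroni")
  raw <- pairwiseTTests(v, g, correction = "none")
  expect_equal(adj$pAdj, pmin(1, raw$p * 3), tolerance = 1e-12)
})

test_that("the connectivity-behavior regression ties r, R-squared and slope p together", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- fcBehaviorRegression(x, 2 * x + 1)
  expect_equal(perfect$pearsonR, 1, tolerance = 1e-12)
  expect_equal(perfect$rSquared, 1, tolerance = 1e-12)

  # 5-point toy against the closed-form normal equations
  y <- c(2.1, 2.9, 4.2, 3.8, 5.1)
  res <- fcBehaviorRegression(x, y)
  bhat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, bhat, tolerance = 1e-12)
  expect_equal(res$intercept, mean(y) - bhat * mean(x), tolerance = 1e-12)
  expect_equal(res$rSquared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(res$p, summary(lm(y ~ x))$coefficients[2, 4], tolerance = 1e-12)

  # printed-pair consistency: r = 0.44 -> R^2 ~ 0.19, r = 0.48 -> R^2 ~ 0.23
  expect_equal(0.44^2, 0.194, tolerance = 0.005)
  expect_equal(0.48^2, 0.230, tolerance = 0.005)

  expect_error(fcBehaviorRegression(rep(1, 5), y), "zero-variance")
})

test_that("multiplicity corrections follow their definitions", {
  expect_equal(bonferroniAdjust(0.01, m = 1), 0.01)
  expect_equal(bonferroniAdjust(c(0.02, 0.5), m = 10), c(0.2, 1))
  expect_error(bonferroniAdjust(1.2), "0, 1")

  allSmall <- fdrBH(rep(0.001, 10), q = 0.05)
  expect_true(all(allSmall$discoveries))

  set.seed(17)
  for (i in 1:5) {
    p <- runif(40)^2
    res <- fdrBH(p, q = 0.05)
    expect_equal(res$discoveries, bruteForceBH(p, 0.05))
  }
  # BH discoveries are a superset of Bonferroni discoveries at the same level
  p <- runif(40)^3
  bh <- fdrBH(p, 0.05)$discoveries
  bonf <- bonferroniAdjust(p) <= 0.05
  expect_true(all(bh[bonf]))
})

test_that("null simulations calibrate type-I error rates near alpha", {
  set.seed(18)
  # paired t and Levene at modest replicate counts (binomial tolerance)
  nrep <- 600
  rejT <- mean(replicate(nrep, {
    x <- rnorm(10); y <- rnorm(10)
    t.test(x, y, paired = TRUE)$p.value < 0.05
  }))
  expect_lt(abs(rejT - 0.05), 0.03)
  rejL <- mean(replicate(nrep, {
    testHomogeneity(rnorm(30), rep(c("a", "b", "c"), each = 10))$p < 0.05
  }))
  expect_lt(abs(rejL - 0.05), 0.03)
  rejA <- mean(replicate(nrep, {
    oneWayAnova(rnorm(30),
                rep(c("a", "b", "c"), each = 10))$table$p[1] < 0.05
  }))
  expect_lt(abs(rejA - 0.05), 0.03)
})
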