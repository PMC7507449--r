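test_that("mixed ANOVA matches an independent sums-of-squares oracle", {
  set.seed(31)
  for (ns in list(c(4, 4), c(6, 6))) {
    g <- rep(c("A", "B"), ns)
    n <- sum(ns)
    b <- rnorm(n, 100, 12)
    a <- b + rnorm(n, c(4, -9)[as.integer(factor(g))], 6)
    mine <- rmAnova(b, a, g)
    ## brute-force split-plot decomposition from cell means (balanced)
    y <- c(b, a)
    subj <- rep(seq_len(n), 2)
    tim <- rep(0:1, each = n)
    grp <- rep(g, 2)
    grand <- mean(y)
    cellM <- tapply(y, list(grp, tim), mean)
    gM <- tapply(y, grp, mean); tM <- tapply(y, tim, mean)
    sM <- tapply(y, subj, mean)
    ssG <- 2 * sum(ns * (gM - grand)^2)
    ssT <- n * sum((tM - grand)^2)
    ssInt <- sum(2 * rep(ns, 2) *
                   (as.vector(cellM) - rep(gM, 2) -
                      rep(tM, each = 2) + grand)^2) / 2
    ssSubj <- 2 * sum((sM - gM[g])^2)
    ssTot <- sum((y - grand)^2)
    ssErr <- ssTot - ssG - ssT - ssInt - ssSubj
    dfe <- n - 2
    expect_equal(mine$F[1], (ssT / 1) / (ssErr / dfe), tolerance = 1e-8)
    expect_equal(mine$F[2], (ssG / 1) / (ssSubj / dfe), tolerance = 1e-8)
    expect_equal(mine$F[3], (ssInt / 1) / (ssErr / dfe), tolerance = 1e-8)
    expect_equal(mine$partialEtaSq[3], ssInt / (ssInt + ssErr),
                 tolerance = 1e-8)
    ## and against aov's split-plot table
    df <- data.frame(y = y, time = factor(tim), subj = factor(subj),
                     grp = factor(grp))
    av <- summary(aov(y ~ grp * time + Error(subj / time), data = df))
    expect_equal(mine$F[2], av[[1]][[1]]["grp", "F value"], tolerance = 1e-8)
    expect_equal(mine$F[1], av[[2]][[1]]["time", "F value"], tolerance = 1e-8)
    expect_equal(mine$F[3], av[[2]][[1]]["grp:time", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("mixed ANOVA with unbalanced groups matches type-III output", {
  skip_if_not_installed("car")
  set.seed(7)
  g <- rep(c("TR", "CTR"), c(13, 7))
  b <- rnorm(20, 2000, 250)
  a <- b + rnorm(20, c(30, -340)[as.integer(factor(g, c("TR", "CTR")))], 150)
  mine <- rmAnova(b, a, g)
  fit <- lm(cbind(b, a) ~ factor(g),
            contrasts = list("factor(g)" = contr.sum))
  aa <- car::Anova(fit, idata = data.frame(time = factor(c("b", "a"))),
                   idesign = ~time, type = 3)
  s <- summary(aa, multivariate = FALSE)$univariate.tests
  expect_equal(mine$F[2], s["factor(g)", "F value"], tolerance = 1e-8)
  expect_equal(mine$F[1], s["time", "F value"], tolerance = 1e-8)
  expect_equal(mine$F[3], s["factor(g):time", "F value"], tolerance = 1e-8)
  expect_equal(mine$SS, unname(s[2:4, "Sum Sq"])[c(2, 1, 3)],
               tolerance = 1e-8)
})

test_that("degenerate and null ANOVA constructions behave as documented", {
  g <- rep(c("A", "B"), each = 3)
  out <- rmAnova(rep(5, 6), rep(5, 6), g)
  expect_true(attr(out, "degenerate"))
  expect_true(all(out$SS == 0))
  ## additive group offset, no time effect, noise-free: interaction exactly 0
  b <- c(10, 11, 12, 20, 21, 22)
  out2 <- rmAnova(b, b + 0, g)
  expect_equal(out2$SS[1], 0)
  expect_equal(out2$SS[3], 0)
  expect_equal(out2$partialEtaSq[3], 0)
  expect_error(rmAnova(1:4, 1:4, rep("A", 4)), "two groups")
  expect_error(rmAnova(c(1, NA, 3, 4), 1:4, rep(c("A", "B"), 2)),
               "missing session")
})

test_that("within-group change gives the t interval", {
  out <- withinGroupChange(c(10, 20, 30), c(15, 25, 35))
  expect_equal(out$meanChange, 5)
  expect_equal(out$ciLow, out$ciHigh)   # zero spread
  set.seed(5)
  b <- rnorm(9, 100, 10); a <- b + rnorm(9, 3, 4)
  out2 <- withinGroupChange(b, a)
  d <- a - b
  half <- qt(0.975, 8) * sd(d) / 3
  expect_equal(out2$meanChange, mean(d), tolerance = 1e-10)
  expect_equal(out2$ciLow, mean(d) - half, tolerance = 1e-10)
  expect_equal(out2$ciHigh, mean(d) + half, tolerance = 1e-10)
  ## the interval is symmetric about the mean and contains it
  expect_lt(out2$ciLow, out2$meanChange)
  expect_gt(out2$ciHigh, out2$meanChange)
  expect_error(withinGroupChange(1, 2), "insufficient-data")
  ## published two-point arithmetic: mean change is the difference of means
  out3 <- withinGroupChange(rep(283.1, 2), rep(285.2, 2))
  expect_equal(out3$meanChange, 2.1, tolerance = 1e-9)
})

test_that("Aspin-Welch test matches the Welch-Satterthwaite formulas", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  out <- aspinWelch(x, y)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  set.seed(8)
  a <- rnorm(9, 0, 2); b <- rnorm(14, 1.5, 6)
  out2 <- aspinWelch(a, b)
  va <- var(a) / 9; vb <- var(b) / 14
  expect_equal(out2$df, (va + vb)^2 / (va^2 / 8 + vb^2 / 13),
               tolerance = 1e-8)
  tt <- t.test(a, b)
  expect_equal(out2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(out2$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(out2$p, tt$p.value, tolerance = 1e-10)
  ## reduces to Student's t for equal variances and sizes
  a2 <- rnorm(10); b2 <- rnorm(10)
  b2 <- (b2 - mean(b2)) / sd(b2) * sd(a2) + mean(b2)  # force equal variance
  st <- t.test(a2, b2, var.equal = TRUE)
  out3 <- aspinWelch(a2, b2)
  expect_equal(out3$t, unname(st$statistic), tolerance = 1e-8)
  expect_equal(out3$df, unname(st$parameter), tolerance = 1e-8)
  ## separation limit: p tends to 0 as jitter vanishes
  p <- vapply(c(1, 0.1, 0.01), function(j) {
    aspinWelch(c(0, 0, 0, 0) + j * c(0.1, -0.2, 0.3, -0.1),
               c(10, 10, 10, 10) + j * c(-0.3, 0.2, 0.1, -0.2))$p
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("correlation power reproduces the published post-hoc value", {
  expect_lt(abs(correlationPower(-0.626, 13) - 0.677), 0.03)
  expect_equal(correlationPower(1, 13), 1)
  set.seed(3)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.2)
  pw <- pearsonWithPower(x, y)
  expect_gt(pw$r, 0.9)
  expect_gt(pw$power, 0.99)
  ## independence: |r| small at large n
  x2 <- rnorm(1000); y2 <- rnorm(1000)
  expect_lt(abs(pearsonWithPower(x2, y2)$r), 0.1)
  expect_error(pearsonWithPower(rep(1, 5), rnorm(5)),
               "undefined-correlation")
  ## mean CIs are the t intervals
  ci <- pearsonWithPower(x, y)$ciX
  half <- qt(0.975, 11) * sd(x) / sqrt(12)
  expect_equal(ci, c(mean(x) - half, mean(x) + half), tolerance = 1e-10)
})

test_that("ICC(2,1) matches the mean-squares oracle", {
  m <- cbind(c(10, 12, 14, 16), c(10, 12, 14, 16))
  out <- icc21(m)
  expect_equal(out$icc, 1)
  expect_equal(out$sem, 0)
  ## noise-dominated limit
  set.seed(12)
  base <- rnorm(12, 100, 0.5)
  noisy <- cbind(base + rnorm(12, 0, 50), base + rnorm(12, 0, 50))
  expect_lt(abs(icc21(noisy)$icc), 0.3)
  ## random grid vs explicit two-way ANOVA mean squares
  set.seed(99)
  g <- matrix(rnorm(20, 50, 8), 10, 2) + rnorm(10, 0, 4)
  out2 <- icc21(g)
  y <- as.vector(g)
  subj <- factor(rep(1:10, 2)); rep_ <- factor(rep(1:2, each = 10))
  av <- anova(lm(y ~ subj + rep_))
  msr <- av["subj", "Mean Sq"]; msc <- av["rep_", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 10)
  expect_equal(out2$icc, icc, tolerance = 1e-10)
  expect_equal(out2$sem, sd(y) * sqrt(1 - icc), tolerance = 1e-10)
  expect_error(icc21(matrix(c(1, NA, 3, 4), 2, 2)), "incomplete")
})

test_that("Bonferroni adjustment is monotone and capped at one", {
  set.seed(17)
  g <- rep(c("A", "B"), each = 6)
  b <- rnorm(12, 100, 5); a <- b + rnorm(12, 1, 5)
  ph <- posthocTimeTests(b, a, g)
  expect_equal(ph$pAdjusted, pmin(1, ph$p * 2))
  expect_true(all(ph$pAdjusted >= ph$p))
  expect_true(all(ph$pAdjusted <= 1))
})

test_that("partial eta squared stays within [0, 1] across random designs", {
  set.seed(55)
  for (i in 1:20) {
    ns <- sample(3:9, 2)
    g <- rep(c("A", "B"), ns)
    b <- rnorm(sum(ns), 100, runif(1, 1, 30))
    a <- b + rnorm(sum(ns), runif(2, -20, 20)[as.integer(factor(g))],
                   runif(1, 1, 15))
    out <- rmAnova(b, a, g)
    expect_true(all(out$partialEtaSq >= 0 & out$partialEtaSq <= 1))
    expect_equal(out$partialEtaSq,
                 out$SS / (out$SS + out$SSerror), tolerance = 1e-12)
  }
})

test_that("cohortStats assembles the full battery per structure", {
  em <- defaultEffectModel(structures = c("RF", "VL"))
  co <- generateCohort(cohortDesign(c(TR = 6, CTR = 6), em, seed = 44))
  st <- cohortStats(co$volumes)
  expect_setequal(unique(st$anova$structure), c("RF", "VL"))
  expect_equal(nrow(st$anova), 6)   # three effects per structure
  expect_true(all(c("time", "group", "time:group") %in% st$anova$effect))
  expect_equal(nrow(st$changes), 4)
  expect_true(all(st$percentChange$structure %in% c("RF", "VL")))
})
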