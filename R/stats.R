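#' Two-factor mixed repeated-measures ANOVA
#'
#' Time (before/after, within-subject) by group (between-subject) ANOVA
#' computed directly from sums of squares, so that the F ratios, degrees
#' of freedom and partial eta squared are fully transparent. The
#' within-subject part is decomposed through per-subject sums and
#' differences; with unequal group sizes the time main effect uses
#' unweighted (type III) group means, matching conventional statistical
#' packages. Partial eta squared is SS_effect / (SS_effect + SS_error)
#' with the error stratum appropriate to each effect.
#'
#' @param before,after numeric vectors of per-subject values.
#' @param group factor or character vector of group labels.
#' @return data.frame(effect, F, df1, df2, p, partialEtaSq, SS, SSerror)
#'   with rows time, group and time:group. With zero error variance the
#'   F statistics are reported as computed (NaN/Inf) and a degenerate
#'   attribute is set.
#' @export
#' @examples
#' set.seed(1)
#' g <- rep(c("TR", "CTR"), each = 4)
#' b <- rnorm(8, 100, 10); a <- b + rnorm(8, c(2, -10)[as.integer(factor(g))], 4)
#' rmAnova(b, a, g)
rmAnova <- function(before, after, group) {
  if (length(before) != length(after) || length(before) != length(group))
    stop("input error: before, after and group must have equal length")
  if (any(!is.finite(before)) || any(!is.finite(after)))
    stop("input error: missing session value")
  group <- factor(group)
  if (nlevels(group) < 2L) stop("design error: need at least two groups")
  if (any(table(group) < 2L)) stop("design error: need >= 2 subjects per group")
  n <- length(before)
  G <- nlevels(group)
  ng <- as.numeric(table(group))
  m <- (before + after) / 2      # subject means
  d <- after - before            # within-subject differences

  ## between-subject stratum (on the original response scale: x2)
  mg <- tapply(m, group, mean)
  ssGroup <- 2 * sum(ng * (mg - sum(ng * mg) / n)^2)
  ssSubj <- 2 * sum((m - mg[group])^2)
  dfSubj <- n - G

  ## within-subject stratum
  dg <- tapply(d, group, mean)
  ssErrW <- sum((d - dg[group])^2) / 2
  ## time main effect: unweighted mean of the group time-effects
  u <- mean(dg)
  ssTime <- u^2 / (sum(1 / ng) / G^2) / 2
  ## interaction: heterogeneity of the group time-effects
  dw <- sum(ng * dg) / n
  ssInt <- sum(ng * (dg - dw)^2) / 2

  msSubj <- ssSubj / dfSubj
  msErrW <- ssErrW / dfSubj
  out <- data.frame(
    effect = c("time", "group", "time:group"),
    F = c((ssTime / 1) / msErrW, (ssGroup / (G - 1)) / msSubj,
          (ssInt / (G - 1)) / msErrW),
    df1 = c(1L, G - 1L, G - 1L),
    df2 = c(dfSubj, dfSubj, dfSubj),
    SS = c(ssTime, ssGroup, ssInt),
    SSerror = c(ssErrW, ssSubj, ssErrW))
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$partialEtaSq <- ifelse(out$SS + out$SSerror > 0,
                             out$SS / (out$SS + out$SSerror), 0)
  out <- out[c("effect", "F", "df1", "df2", "p", "partialEtaSq",
               "SS", "SSerror")]
  attr(out, "degenerate") <- ssErrW == 0 || ssSubj == 0
  out
}

#' Bonferroni-adjusted paired post-hoc tests by group
#'
#' Paired t-test of after vs before within each group; p values are
#' Bonferroni-adjusted for the number of groups compared and capped at 1.
#' Cohen's d for the paired contrast is the mean change divided by the
#' standard deviation of the changes.
#'
#' @inheritParams rmAnova
#' @return data.frame(comparison, t, df, p, pAdjusted, cohenD).
#' @export
posthocTimeTests <- function(before, after, group) {
  group <- factor(group)
  rows <- lapply(levels(group), function(g) {
    i <- group == g
    d <- after[i] - before[i]
    n <- length(d)
    sdd <- stats::sd(d)
    t <- if (sdd == 0) 0 else mean(d) / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    data.frame(comparison = paste0(g, ": after vs before"),
               t = t, df = n - 1, p = p,
               cohenD = if (sdd == 0) 0 else mean(d) / sdd)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- pmin(1, out$p * nrow(out))
  out[c("comparison", "t", "df", "p", "pAdjusted", "cohenD")]
}

#' Within-group change with a 95 percent confidence interval
#'
#' Mean of the per-subject changes (after - before) with the t-based
#' confidence interval mean +/- t(0.975, n-1) sd / sqrt(n).
#'
#' @param before,after paired numeric vectors (n >= 2).
#' @param level confidence level (default 0.95).
#' @return data.frame(meanChange, ciLow, ciHigh, n, sd).
#' @export
#' @examples
#' withinGroupChange(c(100, 110), c(105, 115))
withinGroupChange <- function(before, after, level = 0.95) {
  if (length(before) != length(after))
    stop("input error: unpaired values")
  n <- length(before)
  if (n < 2L) stop("insufficient-data error: need n >= 2 pairs")
  d <- after - before
  mu <- mean(d)
  sdd <- stats::sd(d)
  half <- stats::qt(1 - (1 - level) / 2, n - 1) * sdd / sqrt(n)
  data.frame(meanChange = mu, ciLow = mu - half, ciHigh = mu + half,
             n = n, sd = sdd)
}

#' Aspin-Welch unequal-variance t-test
#'
#' Two-sample t statistic with the Welch-Satterthwaite approximation to
#' the degrees of freedom, plus Cohen's d computed with the pooled
#' standard deviation of the two groups.
#'
#' @param a,b numeric vectors (n >= 2 each), e.g. percentage changes of
#'   two groups.
#' @return data.frame(t, df, p, cohenD, meanA, meanB).
#' @export
#' @examples
#' aspinWelch(rnorm(8), rnorm(7, 1))
aspinWelch <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("input error: need n >= 2 per group")
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  delta <- mean(a) - mean(b)
  if (se2 == 0) {
    t <- 0; df <- na + nb - 2; p <- 1
  } else {
    t <- delta / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  d <- if (sp == 0) 0 else delta / sp
  data.frame(t = t, df = df, p = p, cohenD = d,
             meanA = mean(a), meanB = mean(b))
}

#' Post-hoc power of a two-sided Pearson correlation test
#'
#' Power at the observed effect size |r| and sample size n, via the
#' Fisher z approximation with the conventional small-sample bias
#' correction atanh(r) + r / (2 (n - 1)) and the critical r taken from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param r observed correlation (its sign is ignored).
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in [0, 1].
#' @export
#' @examples
#' correlationPower(-0.626, 13)
correlationPower <- function(r, n, alpha = 0.05) {
  if (n < 4L) stop("input error: need n >= 4")
  r <- abs(r)
  if (r >= 1) return(1)
  dfree <- n - 2
  tc <- stats::qt(1 - alpha / 2, dfree)
  rc <- sqrt(tc^2 / (tc^2 + dfree))
  zr <- atanh(r) + r / (2 * (n - 1))
  zc <- atanh(rc)
  s <- sqrt(n - 3)
  stats::pnorm((zr - zc) * s) + stats::pnorm((-zr - zc) * s)
}

#' Pearson correlation with confidence intervals and post-hoc power
#'
#' Correlation coefficient and two-sided p value, the t-based 95 percent
#' confidence intervals of the two variables' means (the descriptive
#' intervals reported alongside percentage-change correlations), and the
#' post-hoc power of the correlation test at the observed |r|.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param alpha significance level for the power computation.
#' @return List with r, p, n, ciX, ciY (each c(low, high)), power.
#' @export
pearsonWithPower <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("input error: unpaired values")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("input error: non-finite values")
  n <- length(x)
  if (n < 3L) stop("input error: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  ciOf <- function(z) {
    mu <- mean(z); half <- stats::qt(0.975, n - 1) * stats::sd(z) / sqrt(n)
    c(mu - half, mu + half)
  }
  list(r = unname(ct$estimate), p = ct$p.value, n = n,
       ciX = ciOf(x), ciY = ciOf(y),
       power = if (n >= 4) correlationPower(ct$estimate, n, alpha) else NA_real_)
}

#' ICC(2,1) and standard error of measurement
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the mean squares of the subjects x repetitions table:
#' ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The standard error of measurement is sd x sqrt(1 - ICC) with sd the
#' standard deviation of all measurements.
#'
#' @param measurements numeric matrix, subjects in rows, repetitions in
#'   columns; the grid must be complete.
#' @return data.frame(icc, sem, n, k).
#' @export
#' @examples
#' m <- cbind(c(10, 12, 14, 16), c(10.2, 11.9, 14.1, 15.8))
#' icc21(m)
icc21 <- function(measurements) {
  m <- as.matrix(measurements)
  if (any(!is.finite(m))) stop("input error: incomplete measurement grid")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("input error: need >= 2 subjects and >= 2 repetitions")
  rowM <- rowMeans(m); colM <- colMeans(m); grand <- mean(m)
  ssR <- k * sum((rowM - grand)^2)
  ssC <- n * sum((colM - grand)^2)
  ssT <- sum((m - grand)^2)
  ssE <- ssT - ssR - ssC
  msR <- ssR / (n - 1)
  msC <- ssC / (k - 1)
  msE <- ssE / ((n - 1) * (k - 1))
  icc <- (msR - msE) / (msR + (k - 1) * msE + k * (msC - msE) / n)
  sem <- stats::sd(as.vector(m)) * sqrt(max(0, 1 - icc))
  data.frame(icc = icc, sem = sem, n = n, k = k)
}

#' Full statistical battery for a longitudinal volume table
#'
#' For every structure: the time x group mixed ANOVA on before/after
#' volumes, Bonferroni post-hoc paired tests per group, within-group
#' changes with confidence intervals, and the Aspin-Welch comparison of
#' the groups' percentage changes.
#'
#' @param volumes data.frame(subject, group, session, structure, volume)
#'   with session in c("before", "after").
#' @param alpha significance level used in summaries.
#' @return Named list of data.frames: anova, posthoc, changes,
#'   percentChange.
#' @export
cohortStats <- function(volumes, alpha = 0.05) {
  need <- c("subject", "group", "session", "structure", "volume")
  if (!all(need %in% names(volumes)))
    stop("input error: volume table must have columns ",
         paste(need, collapse = ", "))
  anovaRows <- list(); posthocRows <- list(); changeRows <- list()
  pcRows <- list()
  for (st in unique(volumes$structure)) {
    v <- volumes[volumes$structure == st, ]
    wide <- merge(v[v$session == "before",
                    c("subject", "group", "volume")],
                  v[v$session == "after", c("subject", "volume")],
                  by = "subject", suffixes = c("Before", "After"))
    if (any(!stats::complete.cases(wide)))
      stop("input error: missing session for structure ", st)
    an <- rmAnova(wide$volumeBefore, wide$volumeAfter, wide$group)
    an$structure <- st
    anovaRows[[st]] <- an
    ph <- posthocTimeTests(wide$volumeBefore, wide$volumeAfter, wide$group)
    ph$structure <- st
    posthocRows[[st]] <- ph
    for (g in unique(wide$group)) {
      i <- wide$group == g
      ch <- withinGroupChange(wide$volumeBefore[i], wide$volumeAfter[i])
      ch$structure <- st; ch$group <- g
      changeRows[[paste(st, g)]] <- ch
    }
    gs <- unique(wide$group)
    if (length(gs) == 2L) {
      pc1 <- percentChange(wide$volumeBefore[wide$group == gs[1]],
                           wide$volumeAfter[wide$group == gs[1]])
      pc2 <- percentChange(wide$volumeBefore[wide$group == gs[2]],
                           wide$volumeAfter[wide$group == gs[2]])
      aw <- aspinWelch(pc1, pc2)
      aw$structure <- st
      aw$groupA <- gs[1]; aw$groupB <- gs[2]
      pcRows[[st]] <- aw
    }
  }
  list(anova = do.call(rbind, c(anovaRows, make.row.names = FALSE)),
       posthoc = do.call(rbind, c(posthocRows, make.row.names = FALSE)),
       changes = do.call(rbind, c(changeRows, make.row.names = FALSE)),
       percentChange = do.call(rbind, c(pcRows, make.row.names = FALSE)))
}
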