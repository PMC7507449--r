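## Published group-level summaries used as study conditions.
##
## Longitudinal means +/- sd and within-group changes (with 95% CI) of
## thigh structure volumes for a resistance-exercise intervention group
## (TR, n = 13) and a non-exercise bed-rest control group (CTR, n = 7):
## muscle tissue volume per muscle and group, IntraMAT volume, and
## SAT/InterMAT volumes.  These printed summaries parameterize the
## synthetic cohort generator and the worked examples; they are inputs,
## not results, of this package.

#' Published longitudinal summary table
#'
#' Group-level before/after means, standard deviations and within-group
#' changes (with 95 percent confidence intervals) of thigh muscle-tissue,
#' IntraMAT, SAT and InterMAT volumes in a 8-week bed-rest study with a
#' pooled resistance-exercise group (TR, n = 13) and a control group
#' (CTR, n = 7). Used as the effect-size source for the synthetic cohort
#' generator. A few printed change values are internally inconsistent
#' with their own session means (see the methods vignette); the table
#' reports them verbatim.
#'
#' @param measure one of "muscle", "intramat", "fat" (SAT/InterMAT) or
#'   "all".
#' @return data.frame(measure, structure, group, n, beforeMean, beforeSd,
#'   afterMean, afterSd, changeMean, ciLow, ciHigh), volumes in cm^3.
#' @export
#' @examples
#' head(studyChangeTable("muscle"))
studyChangeTable <- function(measure = c("all", "muscle", "intramat", "fat")) {
  measure <- match.arg(measure)
  row <- function(meas, st, g, n, bm, bs, am, as_, cm, lo, hi)
    data.frame(measure = meas, structure = st, group = g, n = n,
               beforeMean = bm, beforeSd = bs, afterMean = am,
               afterSd = as_, changeMean = cm, ciLow = lo, ciHigh = hi)
  m <- rbind(
    row("muscle", "RF",  "TR", 13, 283.1, 50.8, 285.2, 45.5, 2.1, -6.4, 10.7),
    row("muscle", "RF",  "CTR", 7, 305.0, 48.8, 285.6, 51.0, -19.4, -43.6, 4.8),
    row("muscle", "VL",  "TR", 13, 684.6, 161.4, 718.8, 135.7, 34.2, -20.9, 89.3),
    row("muscle", "VL",  "CTR", 7, 719.9, 158.3, 574.6, 132.9, -145.3, -208.7, -81.9),
    row("muscle", "VI",  "TR", 13, 515.4, 82.1, 509.4, 87.4, -6.0, -32.1, 20.2),
    row("muscle", "VI",  "CTR", 7, 524.4, 62.7, 417.0, 75.5, -107.5, -154.0, -60.9),
    row("muscle", "VM",  "TR", 13, 510.8, 99.9, 517.3, 113.1, 6.5, -26.9, 39.9),
    row("muscle", "VM",  "CTR", 7, 562.3, 55.5, 492.2, 63.5, -70.1, -122.5, -17.6),
    row("muscle", "QF",  "TR", 13, 1993.9, 361.5, 2030.7, 346.1, 36.9, -64.4, 138.2),
    row("muscle", "QF",  "CTR", 7, 2111.6, 182.2, 1769.4, 211.7, -342.2, -499.6, -184.8),
    row("muscle", "BFs", "TR", 13, 109.7, 23.0, 108.9, 25.2, -0.8, -8.1, 6.4),
    row("muscle", "BFs", "CTR", 7, 113.6, 20.8, 113.6, 29.0, 0.0, -19.3, 19.3),
    row("muscle", "BFl", "TR", 13, 210.0, 42.3, 183.0, 35.5, -27.2, -37.7, -16.7),
    row("muscle", "BFl", "CTR", 7, 228.3, 20.6, 196.2, 30.6, -19.2, -51.9, -12.3),
    row("muscle", "ST",  "TR", 13, 190.4, 46.1, 189.6, 44.3, -0.8, -10.0, 8.3),
    row("muscle", "ST",  "CTR", 7, 201.2, 38.6, 197.1, 30.6, -4.1, -17.6, 9.4),
    row("muscle", "SM",  "TR", 13, 241.5, 50.9, 211.0, 48.2, -30.5, -41.5, -19.6),
    row("muscle", "SM",  "CTR", 7, 272.6, 34.9, 235.9, 37.1, -36.7, -48.4, -25.0),
    row("muscle", "HM",  "TR", 13, 751.8, 133.7, 692.4, 133.7, -59.4, -90.1, -28.6),
    row("muscle", "HM",  "CTR", 7, 815.6, 66.7, 742.7, 80.0, -72.9, -97.5, -48.3),
    row("muscle", "AL",  "TR", 13, 174.3, 41.4, 178.0, 34.8, 3.6, -6.4, 13.7),
    row("muscle", "AL",  "CTR", 7, 182.1, 26.0, 166.0, 30.5, -15.6, -31.5, 0.24),
    row("muscle", "AM",  "TR", 13, 570.6, 108.6, 577.8, 98.3, 1.6, -21.5, 24.6),
    row("muscle", "AM",  "CTR", 7, 525.6, 56.6, 482.3, 46.1, -50.8, -111.2, 9.7),
    row("muscle", "AB",  "TR", 13, 119.2, 34.9, 118.3, 32.5, -0.9, -10.7, 8.8),
    row("muscle", "AB",  "CTR", 7, 133.9, 13.0, 140.4, 24.5, 0.4, -10.3, 11.1),
    row("muscle", "Sar", "TR", 13, 129.2, 40.2, 129.8, 37.0, 0.6, -6.1, 7.3),
    row("muscle", "Sar", "CTR", 7, 134.0, 23.4, 131.8, 30.3, -2.2, -11.5, 7.2),
    row("muscle", "Gr",  "TR", 13, 103.8, 24.3, 107.2, 21.6, 3.4, -1.1, 8.0),
    row("muscle", "Gr",  "CTR", 7, 95.7, 18.0, 99.6, 21.1, 3.9, -2.1, 9.8),
    row("muscle", "AD",  "TR", 13, 1067.6, 196.0, 1075.9, 182.8, 8.3, -26.4, 42.9),
    row("muscle", "AD",  "CTR", 7, 1071.2, 59.5, 1020.1, 75.1, -64.3, -137.2, 8.5),
    row("muscle", "whole thigh", "TR", 13, 3780.0, 696.2, 3796.1, 643.4, 16.6, -84.5, 117.7),
    row("muscle", "whole thigh", "CTR", 7, 3998.5, 190.5, 3532.7, 311.8, 137.3, 74.9, 199.7))
  i <- rbind(
    row("intramat", "RF",  "TR", 13, 36.5, 7.5, 30.3, 5.2, -6.1, -9.9, -2.3),
    row("intramat", "RF",  "CTR", 7, 40.8, 7.9, 38.0, 9.2, -2.8, -5.3, -0.3),
    row("intramat", "VL",  "TR", 13, 144.4, 45.5, 133.4, 51.4, -11.0, -23.1, 1.0),
    row("intramat", "VL",  "CTR", 7, 133.4, 16.3, 107.0, 16.8, -26.4, -46.2, -6.6),
    row("intramat", "VI",  "TR", 13, 102.7, 26.6, 94.8, 33.5, -7.9, -18.1, 2.3),
    row("intramat", "VI",  "CTR", 7, 109.6, 27.7, 109.0, 29.2, -13.0, -26.9, 0.8),
    row("intramat", "VM",  "TR", 13, 110.1, 36.5, 93.4, 32.8, -16.7, -32.1, -1.2),
    row("intramat", "VM",  "CTR", 7, 103.7, 23.0, 96.6, 26.4, -6.0, -16.7, 4.6),
    row("intramat", "QF",  "TR", 13, 393.7, 106.4, 351.9, 111.9, -41.7, -65.8, -17.6),
    row("intramat", "QF",  "CTR", 7, 387.5, 51.2, 344.0, 71.8, -48.2, -79.8, -16.8),
    row("intramat", "BFs", "TR", 13, 25.6, 4.7, 21.8, 6.9, -3.8, -6.0, -1.6),
    row("intramat", "BFs", "CTR", 7, 27.6, 8.3, 24.1, 8.9, -3.5, -10.0, 3.1),
    row("intramat", "BFl", "TR", 13, 49.3, 21.5, 42.6, 23.2, -6.7, -12.3, -1.1),
    row("intramat", "BFl", "CTR", 7, 51.9, 12.3, 41.6, 15.4, -10.3, -24.7, 4.1),
    row("intramat", "ST",  "TR", 13, 37.4, 16.6, 27.2, 10.9, -10.2, -14.6, -5.9),
    row("intramat", "ST",  "CTR", 7, 48.3, 16.0, 36.4, 9.6, -11.8, -26.1, 2.3),
    row("intramat", "SM",  "TR", 13, 58.1, 19.5, 55.0, 21.6, -3.1, -9.3, 3.0),
    row("intramat", "SM",  "CTR", 7, 55.2, 12.7, 54.7, 15.8, -0.5, -18.7, 17.6),
    row("intramat", "HM",  "TR", 13, 170.5, 55.3, 146.6, 56.3, -23.9, -36.4, -11.3),
    row("intramat", "HM",  "CTR", 7, 183.0, 38.0, 156.9, 44.2, -26.2, -72.7, 20.3),
    row("intramat", "AL",  "TR", 13, 24.8, 7.3, 20.4, 8.1, -4.4, -6.8, -2.0),
    row("intramat", "AL",  "CTR", 7, 29.7, 5.1, 27.2, 6.8, -2.7, -6.3, 0.8),
    row("intramat", "AM",  "TR", 13, 128.0, 50.0, 112.9, 46.3, -15.1, -25.3, -5.0),
    row("intramat", "AM",  "CTR", 7, 126.9, 16.5, 101.0, 23.5, -22.3, -39.6, -5.2),
    row("intramat", "AB",  "TR", 13, 16.0, 5.5, 13.2, 4.7, -2.8, -4.7, -0.9),
    row("intramat", "AB",  "CTR", 7, 28.7, 6.9, 28.6, 18.5, 0.4, -3.2, 4.0),
    row("intramat", "Sar", "TR", 13, 44.3, 12.5, 39.6, 13.7, -4.7, -8.4, -1.0),
    row("intramat", "Sar", "CTR", 7, 53.9, 17.4, 47.9, 19.1, -6.0, -13.3, 1.3),
    row("intramat", "Gr",  "TR", 13, 22.0, 7.9, 19.0, 7.5, -3.0, -5.3, -0.6),
    row("intramat", "Gr",  "CTR", 7, 24.9, 5.1, 20.8, 4.1, -4.1, -7.2, -0.9),
    row("intramat", "AD",  "TR", 13, 235.2, 70.7, 205.2, 68.7, -30.0, -43.8, -16.3),
    row("intramat", "AD",  "CTR", 7, 264.1, 32.3, 215.3, 49.8, -41.4, -62.3, -20.5),
    row("intramat", "whole thigh", "TR", 13, 795.5, 225.1, 703.4, 233.3, -92.1, -139.4, -44.7),
    row("intramat", "whole thigh", "CTR", 7, 834.6, 67.3, 721.7, 161.7, -111.2, -196.0, -26.3))
  f <- rbind(
    row("fat", "SAT", "TR", 13, 1217.6, 613.1, 1244.8, 571.7, 27.2, -25.6, 80.0),
    row("fat", "SAT", "CTR", 7, 1190.3, 253.6, 1327.6, 233.0, 137.3, 74.9, 199.7),
    row("fat", "InterMAT", "TR", 13, 427.4, 219.3, 432.2, 206.8, 4.8, -35.4, 44.9),
    row("fat", "InterMAT", "CTR", 7, 375.0, 128.4, 355.5, 182.4, 15.3, -43.3, 73.8))
  out <- rbind(m, i, f)
  rownames(out) <- NULL
  if (measure != "all") out <- out[out$measure == measure, , drop = FALSE]
  out
}

#' Effect model derived from the published summaries
#'
#' Converts the printed group summaries into the per-structure effect
#' model used by \code{\link{generateCohort}}: the baseline distribution
#' is Normal(beforeMean, beforeSd) and the before-to-after change is
#' Normal(changeMean, changeSd), where changeSd is recovered from the
#' printed 95 percent confidence interval half-width via
#' sd = halfwidth x sqrt(n) / t(0.975, n - 1).
#'
#' @param measure which measure to model (default "muscle").
#' @param structures which structures to keep (default: the 13 muscles).
#' @return data.frame(structure, group, baselineMean, baselineSd,
#'   changeMean, changeSd) suitable for \code{\link{cohortDesign}}.
#' @export
#' @examples
#' defaultEffectModel(structures = "QF")
defaultEffectModel <- function(measure = "muscle",
                               structures = thighMuscles()) {
  tab <- studyChangeTable(measure)
  tab <- tab[tab$structure %in% structures, , drop = FALSE]
  half <- (tab$ciHigh - tab$ciLow) / 2
  data.frame(structure = tab$structure, group = tab$group,
             baselineMean = tab$beforeMean, baselineSd = tab$beforeSd,
             changeMean = tab$changeMean,
             changeSd = half * sqrt(tab$n) / stats::qt(0.975, tab$n - 1))
}
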