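#' Cross-sectional area from a pixel count
#'
#' CSA in cm^2 is the pixel count times the squared pixel spacing,
#' \code{count x (FOV / matrix)^2}, with the spacing expressed in cm.
#' At the default geometry one pixel is (45.0 / 320)^2 = 0.019775 cm^2.
#'
#' @param pixelCount number of pixels (vectorized).
#' @param geom an \linkS4class{AcquisitionGeometry}.
#' @return CSA in cm^2.
#' @export
#' @examples
#' csaFromPixels(1000, acquisitionGeometry())
csaFromPixels <- function(pixelCount, geom) {
  if (any(pixelCount < 0)) stop("input error: negative pixel count")
  pixelCount * pixelAreaCm2(geom)
}

#' Integrate per-slice CSAs to a volume
#'
#' Volume in cm^3 is the rectangle-rule sum \code{sum(e_i x CSA_i)} with
#' \code{e_i} the centre-to-centre slice spacing in cm (identical for all
#' slices of one acquisition).
#'
#' @param csas numeric vector of per-slice CSAs in cm^2.
#' @param geom an \linkS4class{AcquisitionGeometry} (its
#'   \code{sliceSpacingMm} supplies e_i), or a numeric slice spacing in cm.
#' @return Volume in cm^3.
#' @export
#' @examples
#' integrateVolume(rep(10, 5), 2.4)  # 120 cm^3
integrateVolume <- function(csas, geom) {
  if (length(csas) == 0L) stop("input error: no slices to integrate")
  e <- if (is(geom, "AcquisitionGeometry")) geom@sliceSpacingMm / 10 else geom
  if (e <= 0) stop("input error: slice spacing must be positive")
  sum(e * csas)
}

#' IntraMAT content
#'
#' IntraMAT volume as a percentage of the total muscle compartment volume,
#' \code{100 x IntraMAT / (muscle tissue + IntraMAT)}.
#'
#' @param muscleVol muscle tissue volume (cm^3).
#' @param intramatVol IntraMAT volume (cm^3).
#' @return Percentage in [0, 100].
#' @export
#' @examples
#' intramatContent(90, 10)  # 10
intramatContent <- function(muscleVol, intramatVol) {
  if (any(muscleVol < 0) || any(intramatVol < 0))
    stop("input error: volumes must be >= 0")
  tot <- muscleVol + intramatVol
  if (any(tot == 0))
    stop("undefined-content error: muscle and IntraMAT volume both zero")
  100 * intramatVol / tot
}

#' Percentage change
#'
#' \code{100 x (after - before) / before}.
#'
#' @param before,after values before and after (before must be > 0).
#' @return Percentage change.
#' @export
percentChange <- function(before, after) {
  if (any(before <= 0)) stop("input error: baseline must be positive")
  100 * (after - before) / before
}

#' Append muscle-group rows to a CSA or volume table
#'
#' Adds rows for the quadriceps femoris (QF), hamstrings (HM), hip
#' adductors (AD) and the whole thigh, each the sum of its member muscles,
#' per subject/session/slice. Groups none of whose members appear are
#' skipped; a group with only part of its members present raises an error
#' naming the missing muscle. The whole-thigh row is added where all three
#' groups are complete.
#'
#' @param tab data.frame with columns structure and the value columns
#'   (tissueCSA/intramatCSA or tissueVolume/intramatVolume), plus any of
#'   subject, session, slice used as grouping keys.
#' @param partial what to do with a group only some of whose members are
#'   present: "error" (default) names the missing muscles, "skip" leaves
#'   the group out (used when tabulating phantoms built from muscle
#'   subsets).
#' @return The table with group rows appended (member rows preserved).
#' @export
aggregateStructures <- function(tab, partial = c("error", "skip")) {
  partial <- match.arg(partial)
  valueCols <- intersect(c("tissueCSA", "intramatCSA",
                           "tissueVolume", "intramatVolume"), names(tab))
  if (!length(valueCols)) stop("no value columns to aggregate")
  keys <- intersect(c("subject", "session", "slice"), names(tab))
  groups <- muscleGroups()
  present <- unique(tab$structure)
  addGroup <- character()
  for (g in names(groups)) {
    mem <- groups[[g]]
    have <- mem %in% present
    if (!any(have)) next
    if (!all(have)) {
      if (partial == "skip") next
      stop("aggregation error: missing member muscle ",
           paste(mem[!have], collapse = ", "), " for group ", g)
    }
    addGroup <- c(addGroup, g)
  }
  sumRows <- function(members, label) {
    sub <- tab[tab$structure %in% members, , drop = FALSE]
    if (length(keys)) {
      agg <- stats::aggregate(sub[valueCols], by = sub[keys],
                              FUN = function(z) sum(z))
    } else {
      agg <- as.data.frame(lapply(sub[valueCols], sum))
    }
    agg$structure <- label
    agg
  }
  out <- tab
  for (g in addGroup) out <- rbindMatched(out, sumRows(groups[[g]], g))
  if (all(c("QF", "HM", "AD") %in% c(present, addGroup)))
    out <- rbindMatched(out, sumRows(unlist(groups), "whole thigh"))
  rownames(out) <- NULL
  out
}

## rbind with column alignment (missing columns filled with NA)
rbindMatched <- function(a, b) {
  for (cl in setdiff(names(a), names(b))) b[[cl]] <- NA
  rbind(a, b[names(a)])
}

#' Per-slice CSA table from a tissue label map
#'
#' Counts pixels per class and slice and converts them to CSAs. Muscle
#' rows carry both the muscle-tissue CSA and the IntraMAT CSA of that
#' muscle; InterMAT, SAT, femur and unassigned rows carry their area in
#' the tissueCSA column; the total-thigh row is the area of all
#' non-background pixels.
#'
#' @param labelMap a \linkS4class{TissueLabelMap}.
#' @param subject,session optional identifiers copied into the table.
#' @return data.frame(subject, session, slice, structure, tissueCSA,
#'   intramatCSA) with areas in cm^2.
#' @export
labelCSATable <- function(labelMap, subject = "", session = "") {
  geom <- labelMap@geometry
  pa <- pixelAreaCm2(geom)
  legend <- labelMap@legend
  muscles <- intersect(thighMuscles(), names(legend))
  rows <- list()
  for (s in seq_along(labelMap@slices)) {
    lab <- labelMap@slices[[s]]
    cnt <- tabulate(as.vector(lab) + 1L, nbins = max(legend) + 1L)
    nOf <- function(code) cnt[code + 1L]
    for (m in muscles) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, session = session, slice = s, structure = m,
        tissueCSA = nOf(legend[[m]]) * pa,
        intramatCSA = nOf(legend[[paste0("IntraMAT:", m)]]) * pa)
    }
    for (nm in c("InterMAT", "SAT", "femur", "unassigned")) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, session = session, slice = s, structure = nm,
        tissueCSA = nOf(legend[[nm]]) * pa, intramatCSA = NA_real_)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subject = subject, session = session, slice = s,
      structure = "total thigh",
      tissueCSA = sum(cnt) * pa - nOf(legend[["background"]]) * pa,
      intramatCSA = NA_real_)
  }
  tab <- do.call(rbind, rows)
  ## keep only muscles actually present (phantoms may use a subset)
  used <- vapply(split(tab$tissueCSA + ifelse(is.na(tab$intramatCSA), 0,
                                              tab$intramatCSA),
                       tab$structure), function(z) any(z > 0), logical(1))
  keepAlways <- c("InterMAT", "SAT", "femur", "unassigned", "total thigh")
  tab <- tab[tab$structure %in% c(names(used)[used], keepAlways), ,
             drop = FALSE]
  rownames(tab) <- NULL
  aggregateStructures(tab, partial = "skip")
}

#' Volume table from a per-slice CSA table
#'
#' Integrates per-slice CSAs over the chosen slice range and derives the
#' IntraMAT content of each muscle row.
#'
#' @param csa table as produced by \code{\link{labelCSATable}}.
#' @param geom an \linkS4class{AcquisitionGeometry}.
#' @param slices optional slice indices to integrate over (default: all
#'   slices present).
#' @return data.frame(subject, session, structure, tissueVolume,
#'   intramatVolume, intramatContent) with volumes in cm^3 and content
#'   in percent.
#' @export
volumeTableFromCSA <- function(csa, geom, slices = NULL) {
  if (!is.null(slices)) csa <- csa[csa$slice %in% slices, , drop = FALSE]
  if (!nrow(csa)) stop("input error: no slices selected")
  e <- geom@sliceSpacingMm / 10
  key <- interaction(csa$subject, csa$session, csa$structure, drop = TRUE)
  parts <- split(csa, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    iv <- if (all(is.na(p$intramatCSA))) NA_real_ else
      sum(e * p$intramatCSA)
    data.frame(subject = p$subject[1], session = p$session[1],
               structure = p$structure[1],
               tissueVolume = sum(e * p$tissueCSA),
               intramatVolume = iv)
  }))
  out$intramatContent <- ifelse(
    !is.na(out$intramatVolume) & (out$tissueVolume + out$intramatVolume) > 0,
    100 * out$intramatVolume / (out$tissueVolume + out$intramatVolume),
    NA_real_)
  rownames(out) <- NULL
  out
}
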