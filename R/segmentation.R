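#' Muscle and subcutaneous-fat ROI sample for threshold determination
#'
#' Three disk ROIs in muscle tissue and three in subcutaneous adipose
#' tissue, pooled into one intensity sample whose bimodal histogram yields
#' the muscle/fat threshold.
#'
#' @param muscle,sat lists of three disks, each \code{c(x, y, r)} in
#'   0-based pixel units.
#' @return Object of class \code{"RoiSample"} (a validated list).
#' @export
roiSample <- function(muscle, sat) {
  stopifnot(length(muscle) >= 1L, length(sat) >= 1L)
  for (d in c(muscle, sat))
    if (length(d) != 3L || d[3] <= 0)
      stop("each ROI must be c(x, y, r) with r > 0")
  structure(list(muscle = muscle, sat = sat), class = "RoiSample")
}

## pixel intensities inside a disk, after clipping to the image
diskValues <- function(slice, disk) {
  msk <- diskMask(disk[1:2], disk[3], dim(slice))
  if (!any(msk)) stop("geometry error: ROI outside image")
  slice[msk]
}

#' Automatic ROI placement on a slice
#'
#' Places three muscle ROIs at the centroids of the three largest traced
#' muscles and three subcutaneous-fat ROIs in the supra-background ring
#' outside the fascia, along three equally spaced directions.
#'
#' @param slice intensity matrix.
#' @param outlines a \linkS4class{SliceOutlineSet} with fascia outline.
#' @param radius nominal ROI radius in pixels.
#' @param backgroundThreshold intensity separating tissue from air.
#' @return A \code{"RoiSample"}.
#' @export
autoRoiSample <- function(slice, outlines, radius = 4,
                          backgroundThreshold = NULL) {
  polys <- outlines@polygons
  muscles <- polys[intersect(names(polys), thighMuscles())]
  if (length(muscles) < 1L) stop("input error: no muscle outlines")
  if (is.null(polys$fascia)) stop("input error: missing fascia outline")
  areas <- vapply(muscles, polygonArea, numeric(1))
  pick <- names(sort(areas, decreasing = TRUE))[seq_len(min(3L, length(muscles)))]
  mrois <- lapply(muscles[pick], function(p) {
    ctr <- colMeans(p)
    c(ctr[1], ctr[2], radius)
  })
  if (length(mrois) < 3L) mrois <- rep(mrois, length.out = 3L)
  fasciaM <- polygonMask(polys$fascia, dim(slice))
  if (is.null(backgroundThreshold))
    backgroundThreshold <- stats::median(slice[fasciaM]) / 2
  ring <- (slice >= backgroundThreshold) & !fasciaM
  ctr <- colMeans(polys$fascia)
  srois <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(th) {
    dmax <- max(dim(slice))
    t <- seq(1, dmax, by = 1)
    xs <- round(ctr[1] + t * cos(th)); ys <- round(ctr[2] + t * sin(th))
    ok <- xs >= 0 & xs < ncol(slice) & ys >= 0 & ys < nrow(slice)
    xs <- xs[ok]; ys <- ys[ok]; t <- t[ok]
    inRing <- ring[cbind(ys + 1L, xs + 1L)]
    if (!any(inRing)) stop("geometry error: no subcutaneous ring along ray")
    tr <- t[inRing]
    tm <- stats::median(tr)
    ## keep a margin so the later jitter cannot push the disk out of the ring
    r <- min(radius, max(1.5, (max(tr) - min(tr)) / 2 - 1))
    c(ctr[1] + tm * cos(th), ctr[2] + tm * sin(th), r)
  })
  roiSample(muscle = mrois, sat = srois)
}

## default bin count: 256 for large samples, scaled down as ~2 sqrt(n)
## for small ROI samples whose 256-bin histogram would be mostly empty
defaultBins <- function(n) min(256L, max(32L, 2L * ceiling(sqrt(n))))

## Gaussian-smoothed histogram of a sample; kernel renormalized at the
## edges so smoothing does not leak mass out of the range
smoothedHistogram <- function(sample, nBins = NULL, smoothSigma = 2) {
  if (is.null(nBins)) nBins <- defaultBins(length(sample))
  rg <- range(sample)
  if (diff(rg) == 0)
    stop("bimodality error: sample is constant")
  bw <- diff(rg) / nBins
  mids <- seq(rg[1] + bw / 2, rg[2] - bw / 2, length.out = nBins)
  idx <- pmin(pmax(floor((sample - rg[1]) / bw) + 1L, 1L), nBins)
  counts <- tabulate(idx, nBins)
  half <- ceiling(4 * smoothSigma)
  k <- stats::dnorm(-half:half, sd = smoothSigma)
  k <- k / sum(k)
  padded <- c(rep(0, half), counts, rep(0, half))
  sm <- stats::filter(padded, k, sides = 2)
  norm <- stats::filter(c(rep(0, half), rep(1, nBins), rep(0, half)), k,
                        sides = 2)
  sm <- (sm / norm)[(half + 1):(half + nBins)]
  list(mids = mids, counts = counts, smoothed = as.numeric(sm), binWidth = bw)
}

## windowed local maxima of a vector (strictly the window maximum)
windowedMaxima <- function(z, w = 5L) {
  n <- length(z)
  which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    z[i] == max(z[lo:hi]) && z[i] > 0
  }, logical(1)))
}

#' Threshold at the base of the first histogram peak
#'
#' Builds a smoothed histogram of the pooled sample, locates the first
#' (lowest-intensity) mode, and returns the intensity at its base: the
#' first local minimum after that mode. When the between-mode region is
#' an (effectively) flat plateau -- which happens whenever the two modes
#' are well separated and the valley counts underflow to zero -- the
#' plateau midpoint is returned, which coincides with the minimum of the
#' generating mixture density for symmetric modes. A sample whose
#' smoothed histogram shows no second mode raises a bimodality error.
#'
#' @param sample numeric vector of pooled ROI intensities.
#' @param nBins histogram bins; the default scales as 2 sqrt(n), capped
#'   at 256, so that sparse ROI samples are not spread over mostly empty
#'   bins.
#' @param smoothSigma Gaussian smoothing sd in bins (default 2).
#' @param window half-window (bins) defining local extrema (default 5).
#' @return List with \code{threshold}, \code{histogram}, and the two mode
#'   locations \code{modes}.
#' @export
histogramThreshold <- function(sample, nBins = NULL, smoothSigma = 2,
                               window = 5L) {
  hs <- smoothedHistogram(sample, nBins, smoothSigma)
  sm <- hs$smoothed
  n <- length(sm)
  maxima <- windowedMaxima(sm, window)
  ## only prominent maxima count as modes; stray tail bumps do not
  maxima <- maxima[sm[maxima] >= 0.05 * max(sm)]
  if (length(maxima) < 1L)
    stop("bimodality error: no histogram mode found")
  i1 <- maxima[1L]
  later <- maxima[maxima > i1]
  ## drop maxima that are part of the first peak's own plateau
  later <- later[vapply(later, function(k)
    min(sm[i1:k]) < 0.8 * min(sm[i1], sm[k]), logical(1))]
  if (!length(later))
    stop("bimodality error: sample histogram is unimodal")
  i2 <- later[1L]
  valley <- sm[(i1 + 1L):(i2 - 1L)]
  if (!length(valley))
    stop("bimodality error: adjacent modes")
  vmin <- min(valley)
  ## bins statistically indistinguishable from the minimum (Poisson
  ## counting noise scale) form the base plateau; its midpoint is the
  ## threshold, which resolves empty-valley runs to their centre
  flat <- which(valley <= vmin + sqrt(vmin + 1))
  runs <- split(flat, cumsum(c(1L, diff(flat) != 1L)))
  am <- which.min(valley)
  plateau <- runs[[1L]]
  for (r in runs) if (am %in% r) plateau <- r
  j <- i1 + plateau[ceiling(length(plateau) / 2)]
  list(threshold = hs$mids[j], histogram = hs,
       modes = hs$mids[c(i1, i2)])
}

#' Muscle/fat threshold from repeated ROI histograms
#'
#' Pools the intensities of the muscle and subcutaneous-fat ROIs, finds
#' the threshold at the base of the first peak of their bimodal histogram
#' (\code{\link{histogramThreshold}}), repeats \code{nRepetitions} times
#' with the ROI disk centres re-jittered by up to \code{jitterPx} pixels
#' (seeded), and averages the repetitions.
#'
#' @param slice intensity matrix.
#' @param rois a \code{"RoiSample"}.
#' @param nRepetitions number of repetitions (default 3).
#' @param seed integer seed for the jitter.
#' @param jitterPx maximum absolute integer jitter per axis (default 2).
#' @param nBins,smoothSigma,window histogram settings, see
#'   \code{\link{histogramThreshold}}.
#' @return A \linkS4class{ThresholdResult}.
#' @export
computeThreshold <- function(slice, rois, nRepetitions = 3L, seed = 1L,
                             jitterPx = 2L, nBins = NULL, smoothSigma = 2,
                             window = 5L) {
  stopifnot(inherits(rois, "RoiSample"), nRepetitions >= 1L)
  disks <- c(rois$muscle, rois$sat)
  nm <- length(rois$muscle)
  ## ROI bounds check against the slice
  for (d in disks)
    if (d[1] - d[3] - jitterPx < 0 || d[2] - d[3] - jitterPx < 0 ||
        d[1] + d[3] + jitterPx > ncol(slice) - 1 ||
        d[2] + d[3] + jitterPx > nrow(slice) - 1)
      stop("geometry error: ROI extends outside the image")
  thresholds <- numeric(nRepetitions)
  lastHist <- NULL
  withSeed(seed, {
    for (rep in seq_len(nRepetitions)) {
      vals <- list(muscle = numeric(), sat = numeric())
      for (i in seq_along(disks)) {
        d <- disks[[i]]
        jit <- sample(seq(-jitterPx, jitterPx), 2L, replace = TRUE)
        dj <- c(d[1] + jit[1], d[2] + jit[2], d[3])
        cls <- if (i <= nm) "muscle" else "sat"
        vals[[cls]] <- c(vals[[cls]], diskValues(slice, dj))
      }
      if (length(vals$muscle) < 30L || length(vals$sat) < 30L)
        stop("input error: need at least 30 pooled pixels per tissue class")
      pooled <- c(vals$muscle, vals$sat)
      ## ROIs sit in tissue by construction; intensities far below the
      ## sample median can only be air picked up at a ring edge and would
      ## fake a low first mode, so they are discarded
      pooled <- pooled[pooled >= 0.25 * stats::median(pooled)]
      ht <- histogramThreshold(pooled, nBins, smoothSigma, window)
      thresholds[rep] <- ht$threshold
      lastHist <- ht$histogram
    }
  })
  new("ThresholdResult", thresholds = thresholds,
      threshold = mean(thresholds), histogram = lastHist)
}

#' Count muscle and IntraMAT pixels within one traced muscle
#'
#' Within the polygon, pixels with intensity lower than (or equal to) the
#' threshold are muscle tissue and pixels above it are IntraMAT, so that
#' total = muscle + IntraMAT. Equality is assigned to muscle: the
#' published rule assigns "lower than" to muscle and "higher than" to
#' adipose and leaves ties open; ties go to muscle here.
#'
#' @param slice intensity matrix.
#' @param polygon two-column vertex matrix of the muscle outline.
#' @param threshold intensity threshold.
#' @return Named integer vector c(total, muscle, intramat).
#' @export
classifyMusclePixels <- function(slice, polygon, threshold) {
  if (!is.finite(threshold)) stop("input error: non-finite threshold")
  msk <- polygonMask(polygon, dim(slice))
  total <- sum(msk)
  if (total == 0L) stop("geometry error: empty polygon")
  muscle <- sum(slice[msk] <= threshold)
  c(total = total, muscle = muscle, intramat = total - muscle)
}

#' Classify every pixel of a slice into tissue classes
#'
#' Muscle polygons are classified with
#' \code{\link{classifyMusclePixels}}; InterMAT is every pixel inside the
#' fascia, outside all muscle polygons and the femur, with intensity
#' above the threshold; within-fascia sub-threshold pixels outside the
#' muscles are labelled unassigned (they belong to no published tissue
#' class and are reported rather than silently folded into InterMAT);
#' SAT is the region between the fascia and the outer skin boundary,
#' taken as the supra-background connected component containing the
#' fascia; the femur polygon interior is femur. The classes partition
#' the image by construction.
#'
#' @param slice intensity matrix.
#' @param outlines a \linkS4class{SliceOutlineSet} containing the fascia
#'   and femur outlines plus the traced muscles.
#' @param threshold intensity threshold from \code{\link{computeThreshold}}.
#' @param backgroundThreshold intensity separating tissue from air
#'   (default: half the muscle/fat threshold).
#' @param geom optional \linkS4class{AcquisitionGeometry} for the returned
#'   label map (default: unit 1 mm pixel spacing).
#' @return A \linkS4class{TissueLabelMap} with one slice.
#' @export
classifySlice <- function(slice, outlines, threshold,
                          backgroundThreshold = threshold / 2,
                          geom = NULL) {
  polys <- outlines@polygons
  if (is.null(polys$fascia)) stop("input error: missing fascia outline")
  if (is.null(polys$femur)) stop("input error: missing femur outline")
  dimHW <- dim(slice)
  legend <- .labelLegend()
  lab <- matrix(legend[["background"]], dimHW[1], dimHW[2])

  fasciaM <- polygonMask(polys$fascia, dimHW)
  femurM <- polygonMask(polys$femur, dimHW)
  supra <- slice >= backgroundThreshold
  comp <- EBImage::bwlabel(supra * 1)
  inFascia <- comp[fasciaM]
  inFascia <- inFascia[inFascia > 0]
  if (length(inFascia)) {
    main <- as.integer(names(which.max(table(inFascia))))
    thigh <- comp == main | fasciaM
  } else thigh <- fasciaM
  satM <- thigh & !fasciaM
  lab[satM] <- legend[["SAT"]]

  inner <- fasciaM & !femurM
  lab[inner & slice > threshold] <- legend[["InterMAT"]]
  lab[inner & slice <= threshold] <- legend[["unassigned"]]

  muscles <- intersect(names(polys), thighMuscles())
  for (m in muscles) {
    msk <- polygonMask(polys[[m]], dimHW) & !femurM
    if (!any(msk)) stop("geometry error: empty polygon: ", m)
    lab[msk & slice <= threshold] <- legend[[m]]
    lab[msk & slice > threshold] <- legend[[paste0("IntraMAT:", m)]]
  }
  lab[femurM] <- legend[["femur"]]
  if (is.null(geom))
    geom <- acquisitionGeometry(fovMm = dimHW * 1.0, matrixPx = dimHW,
                                sliceThicknessMm = 1, intersliceGapMm = 0)
  new("TissueLabelMap", slices = list(lab), legend = legend,
      geometry = geom)
}

#' Classify a whole corrected stack
#'
#' Runs ROI placement, threshold determination and per-slice
#' classification for every slice of a stack.
#'
#' @param stack an \linkS4class{AxialImageStack} (bias-corrected).
#' @param outlines list of \linkS4class{SliceOutlineSet}, one per slice.
#' @param seed integer seed for the ROI jitter.
#' @param nRepetitions threshold repetitions per slice.
#' @return List with \code{labels} (a \linkS4class{TissueLabelMap}) and
#'   \code{thresholds} (data.frame of per-slice thresholds).
#' @export
classifyStack <- function(stack, outlines, seed = 1L, nRepetitions = 3L) {
  stopifnot(length(outlines) == nSlices(stack))
  legend <- .labelLegend()
  labs <- vector("list", nSlices(stack))
  thr <- data.frame(slice = seq_len(nSlices(stack)), threshold = NA_real_)
  for (s in seq_len(nSlices(stack))) {
    sl <- getSlice(stack, s)
    rois <- autoRoiSample(sl, outlines[[s]])
    tr <- computeThreshold(sl, rois, nRepetitions = nRepetitions,
                           seed = seed + s)
    thr$threshold[s] <- tr@threshold
    lm1 <- classifySlice(sl, outlines[[s]], tr@threshold)
    labs[[s]] <- lm1@slices[[1L]]
  }
  list(labels = new("TissueLabelMap", slices = labs, legend = legend,
                    geometry = stack@geometry),
       thresholds = thr)
}
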