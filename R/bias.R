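#' Parameters of the intensity-nonuniformity correction
#'
#' The seven tunables of the iterative histogram-sharpening (N3-style)
#' bias-field estimator. Defaults are the optimized values used with
#' 1.5 T T1-weighted thigh imaging: end tolerance 0.0001, at most 100
#' iterations, signal threshold 1 (pixels below it are excluded from
#' fitting), control-point distance 25 mm for the smoothing spline,
#' subsampling factor 4, sharpening-kernel full width at half maximum
#' 0.15 (in log-intensity units) and Wiener filter noise constant 0.01.
#'
#' @param endTolerance convergence tolerance on the coefficient of
#'   variation of the ratio between successive field estimates.
#' @param maxIterations maximum sharpening/smoothing cycles.
#' @param signalThreshold intensity below which pixels are ignored.
#' @param fieldDistanceMm control-point spacing of the smoothing spline.
#' @param subsamplingFactor grid subsampling for field fitting.
#' @param kernelFwhm full width at half maximum of the Gaussian blur
#'   deconvolved from the log-intensity histogram.
#' @param wienerNoise Wiener deconvolution noise constant.
#' @param nBins number of histogram bins.
#' @return Named list of validated parameters.
#' @export
#' @examples
#' n3Params(maxIterations = 50)
n3Params <- function(endTolerance = 1e-4, maxIterations = 100L,
                     signalThreshold = 1, fieldDistanceMm = 25,
                     subsamplingFactor = 4L, kernelFwhm = 0.15,
                     wienerNoise = 0.01, nBins = 200L) {
  p <- list(endTolerance = endTolerance,
            maxIterations = as.integer(maxIterations),
            signalThreshold = signalThreshold,
            fieldDistanceMm = fieldDistanceMm,
            subsamplingFactor = as.integer(subsamplingFactor),
            kernelFwhm = kernelFwhm, wienerNoise = wienerNoise,
            nBins = as.integer(nBins))
  if (any(unlist(p[c("endTolerance", "signalThreshold", "fieldDistanceMm",
                     "kernelFwhm", "wienerNoise")]) <= 0))
    stop("all N3 parameters must be strictly positive")
  if (p$maxIterations < 1L) stop("maxIterations must be >= 1")
  if (p$subsamplingFactor < 1L) stop("subsamplingFactor must be >= 1")
  p
}

#' Estimate the multiplicative bias field of one slice
#'
#' Iterative histogram-sharpening estimation of a smooth multiplicative
#' intensity nonuniformity. Each cycle (i) forms the histogram of
#' current corrected log intensities of the signal pixels (subsampled by
#' \code{subsamplingFactor}), with linear mass-splitting between adjacent
#' bins and the bin domain padded beyond the observed range so that
#' deconvolution ringing is never truncated; (ii) sharpens it by Wiener
#' deconvolution of a Gaussian kernel of width \code{kernelFwhm};
#' (iii) maps every pixel to its expected true log intensity under the
#' sharpened distribution and takes the residual as the local log-field
#' estimate; (iv) smooths the residuals with a tensor-product cubic
#' B-spline whose control points are \code{fieldDistanceMm} apart, and
#' accumulates. Iteration stops when the coefficient of variation of the
#' ratio between successive fields drops below \code{endTolerance}, or at
#' \code{maxIterations}. The returned field has mean 1 over signal pixels.
#'
#' @param slice numeric matrix of nonnegative intensities.
#' @param params list from \code{\link{n3Params}}.
#' @param pixelSpacingMm in-plane pixel spacing in mm (used to convert the
#'   control-point distance to pixels).
#' @return A \linkS4class{BiasField}.
#' @export
#' @examples
#' sl <- matrix(100, 40, 40)
#' estimateBiasField(sl, n3Params(), pixelSpacingMm = 1.40625)
estimateBiasField <- function(slice, params = n3Params(),
                              pixelSpacingMm = 1.40625) {
  if (any(!is.finite(slice))) stop("input error: non-finite intensities")
  if (any(slice < 0)) stop("input error: negative intensities")
  H <- nrow(slice); W <- ncol(slice)
  mask <- slice >= params$signalThreshold
  if (!any(mask)) stop("no-signal error: all pixels below signal threshold")

  subm <- matrix(FALSE, H, W)
  subm[seq(1L, H, by = params$subsamplingFactor),
       seq(1L, W, by = params$subsamplingFactor)] <- TRUE
  fitm <- mask & subm
  sel <- which(fitm, arr.ind = TRUE)
  v0 <- log(slice[fitm])

  ## tensor-product cubic B-spline smoother with control points every
  ## fieldDistanceMm; ridge-stabilized normal equations factored once
  dpx <- params$fieldDistanceMm / pixelSpacingMm
  knotsFor <- function(n) seq(-3 * dpx, (n - 1) + 4 * dpx, by = dpx)
  Br <- splines::splineDesign(knotsFor(H), 0:(H - 1), ord = 4,
                              outer.ok = TRUE)
  Bc <- splines::splineDesign(knotsFor(W), 0:(W - 1), ord = 4,
                              outer.ok = TRUE)
  Kr <- ncol(Br); Kc <- ncol(Bc)
  Dr <- Br[sel[, 1], , drop = FALSE]; Dc <- Bc[sel[, 2], , drop = FALSE]
  D <- matrix(0, nrow(sel), Kr * Kc)
  for (j in seq_len(Kc))
    D[, ((j - 1) * Kr + 1):(j * Kr)] <- Dr * Dc[, j]
  DtD <- crossprod(D)
  diag(DtD) <- diag(DtD) + 1e-6 * mean(diag(DtD))
  ch <- chol(DtD)
  smoothFit <- function(r) {
    cf <- backsolve(ch, forwardsolve(t(ch), crossprod(D, r)))
    Br %*% matrix(cf, Kr, Kc) %*% t(Bc)
  }

  sigmaLog <- params$kernelFwhm / (2 * sqrt(2 * log(2)))
  nbins <- params$nBins
  L <- 2^ceiling(log2(2 * nbins + 64))
  off <- c(0:(L / 2), -(L / 2 - 1):-1)

  logf <- matrix(0, H, W)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(params$maxIterations)) {
    iterations <- it
    uvec <- v0 - logf[fitm]
    pad <- 6 * sigmaLog
    rg <- range(uvec) + c(-pad, pad)
    bw <- diff(rg) / nbins
    mids <- seq(rg[1] + bw / 2, rg[2] - bw / 2, length.out = nbins)
    ## histogram with linear mass-splitting between the two nearest bins
    pos <- (uvec - mids[1]) / bw
    lo <- floor(pos); wg <- pos - lo
    i1 <- pmin(pmax(lo + 1L, 1L), nbins)
    i2 <- pmin(pmax(lo + 2L, 1L), nbins)
    h <- numeric(nbins)
    t1 <- rowsum(1 - wg, i1)
    h[as.integer(rownames(t1))] <- h[as.integer(rownames(t1))] + t1[, 1]
    t2 <- rowsum(wg, i2)
    h[as.integer(rownames(t2))] <- h[as.integer(rownames(t2))] + t2[, 1]
    ## Wiener sharpening
    sb <- sigmaLog / bw
    g <- exp(-0.5 * (off / sb)^2); g <- g / sum(g)
    Gf <- stats::fft(g)
    Hf <- stats::fft(c(h, rep(0, L - nbins)))
    fs <- Re(stats::fft(Hf * Conj(Gf) / (Mod(Gf)^2 + params$wienerNoise),
                        inverse = TRUE)) / L
    fs[fs < 0] <- 0
    fs <- fs[seq_len(nbins)]
    ## expected true log intensity given the observed value
    num <- Re(stats::fft(stats::fft(c(fs * mids, rep(0, L - nbins))) * Gf,
                         inverse = TRUE)) / L
    den <- Re(stats::fft(stats::fft(c(fs, rep(0, L - nbins))) * Gf,
                         inverse = TRUE)) / L
    num <- num[seq_len(nbins)]; den <- den[seq_len(nbins)]
    ok <- den > max(den) * 1e-10
    mp <- mids
    mp[ok] <- num[ok] / den[ok]
    eu <- stats::approx(mids, mp, xout = uvec, rule = 2)$y
    resid <- uvec - eu
    inc <- smoothFit(resid)
    logfNew <- logf + inc
    logfNew <- logfNew - mean(logfNew[mask])
    ratio <- exp(logfNew - logf)[mask]
    cv <- stats::sd(ratio) / mean(ratio)
    logf <- logfNew
    if (cv < params$endTolerance) { converged <- TRUE; break }
  }
  field <- exp(logf)
  field <- field / mean(field[mask])
  new("BiasField", field = field, iterations = iterations,
      converged = converged, mask = mask)
}

#' Divide out an estimated bias field
#'
#' Returns \code{slice / field}, rescaled so that the mean intensity over
#' the signal pixels used in the field fit is unchanged.
#'
#' @param slice numeric matrix.
#' @param field a \linkS4class{BiasField} (or a positive matrix).
#' @return Corrected slice, same dimensions.
#' @export
applyCorrection <- function(slice, field) {
  f <- if (is(field, "BiasField")) field@field else field
  msk <- if (is(field, "BiasField")) field@mask else
    matrix(TRUE, nrow(slice), ncol(slice))
  if (!all(dim(slice) == dim(f)))
    stop("input error: slice and field dimensions differ")
  if (any(f <= 0)) stop("input error: field must be strictly positive")
  out <- slice / f
  m0 <- mean(slice[msk]); m1 <- mean(out[msk])
  if (m1 > 0) out <- out * (m0 / m1)
  out
}

#' Bias-correct every slice of a stack
#'
#' Convenience wrapper running \code{\link{estimateBiasField}} and
#' \code{\link{applyCorrection}} slice by slice (the correction is 2-D:
#' slices are acquired with a large gap and treated independently).
#'
#' @param stack an \linkS4class{AxialImageStack}.
#' @param params list from \code{\link{n3Params}}.
#' @return List with \code{corrected} (an \linkS4class{AxialImageStack})
#'   and \code{fields} (list of \linkS4class{BiasField}).
#' @export
correctStack <- function(stack, params = n3Params()) {
  sp <- pixelSpacingMm(stack)
  fields <- lapply(stack@slices, estimateBiasField, params = params,
                   pixelSpacingMm = sp)
  corrected <- mapply(applyCorrection, stack@slices, fields,
                      SIMPLIFY = FALSE)
  list(corrected = axialImageStack(corrected, stack@geometry),
       fields = fields)
}
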