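#' @rdname AxialImageStack-class
#' @param x an object.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname AxialImageStack-class
#' @param i slice index.
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @rdname AxialImageStack-class
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Pixel spacing in millimetres
#'
#' The in-plane pixel spacing \code{fovMm / matrixPx}. An error is raised
#' if the two axes disagree beyond rounding, since isotropic pixels are
#' assumed by all area computations.
#'
#' @param x an \linkS4class{AcquisitionGeometry} or an object carrying one.
#' @return Pixel spacing in mm (scalar).
#' @export
setGeneric("pixelSpacingMm", function(x) standardGeneric("pixelSpacingMm"))

#' @rdname pixelSpacingMm
#' @export
setGeneric("pixelAreaCm2", function(x) standardGeneric("pixelAreaCm2"))

#' @rdname TissueLabelMap-class
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))

setMethod("nSlices", "AxialImageStack", function(x) length(x@slices))
setMethod("nSlices", "TissueLabelMap", function(x) length(x@slices))
setMethod("getSlice", "AxialImageStack", function(x, i) x@slices[[i]])
setMethod("getSlice", "TissueLabelMap", function(x, i) x@slices[[i]])
setMethod("geometry", "AxialImageStack", function(x) x@geometry)
setMethod("geometry", "TissueLabelMap", function(x) x@geometry)
setMethod("labelLegend", "TissueLabelMap", function(x) x@legend)

setMethod("pixelSpacingMm", "AcquisitionGeometry", function(x) {
  sp <- x@fovMm / x@matrixPx
  if (abs(sp[1] - sp[2]) > 1e-9 * sp[1])
    stop("anisotropic pixel spacing: ", sp[1], " x ", sp[2], " mm")
  sp[1]
})
setMethod("pixelSpacingMm", "AxialImageStack", function(x) pixelSpacingMm(x@geometry))
setMethod("pixelAreaCm2", "AcquisitionGeometry",
          function(x) (pixelSpacingMm(x) / 10)^2)
setMethod("pixelAreaCm2", "AxialImageStack", function(x) pixelAreaCm2(x@geometry))

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry:", paste(object@fovMm, collapse = " x "),
      "mm FOV,", paste(object@matrixPx, collapse = " x "), "px,",
      object@sliceThicknessMm, "mm slices,",
      object@intersliceGapMm, "mm gap,",
      object@sliceSpacingMm, "mm spacing\n")
})

setMethod("show", "AxialImageStack", function(object) {
  d <- dim(object@slices[[1]])
  cat("AxialImageStack:", length(object@slices), "slice(s) of",
      d[1], "x", d[2], "px;",
      sprintf("pixel spacing %.5f mm\n", pixelSpacingMm(object)))
})

setMethod("show", "TissueLabelMap", function(object) {
  cat("TissueLabelMap:", length(object@slices), "slice(s);",
      length(object@legend), "label classes\n")
})

setMethod("show", "BiasField", function(object) {
  cat(sprintf("BiasField: %d x %d px, range [%.4f, %.4f], %d iteration(s), %s\n",
              nrow(object@field), ncol(object@field),
              min(object@field), max(object@field), object@iterations,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: %.4g (mean of %s)\n", object@threshold,
              paste(sprintf("%.4g", object@thresholds), collapse = ", ")))
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", length(object@muscles), "muscle(s),",
      object@nSlices, "slice(s),",
      sprintf("intensities %g/%g (muscle/fat), noise sd %g, seed %d\n",
              object@intensityModel$muscleMean, object@intensityModel$fatMean,
              object@intensityModel$noiseSd, object@seed))
})
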