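#' @import methods
NULL

#' Names of the thirteen thigh muscles
#'
#' Standard abbreviations for the muscles traced on each axial slice:
#' rectus femoris (RF), vastus lateralis (VL), vastus intermedius (VI),
#' vastus medialis (VM), biceps femoris short and long heads (BFs, BFl),
#' semitendinosus (ST), semimembranosus (SM), adductor longus (AL),
#' adductor magnus (AM), adductor brevis (AB), sartorius (Sar) and
#' gracilis (Gr).
#'
#' @return Character vector of length 13.
#' @export
#' @examples
#' thighMuscles()
thighMuscles <- function() {
  c("RF", "VL", "VI", "VM", "BFs", "BFl", "ST", "SM",
    "AL", "AM", "AB", "Sar", "Gr")
}

#' Functional muscle groups of the thigh
#'
#' Quadriceps femoris (QF = RF + VL + VI + VM), hamstrings
#' (HM = BFs + BFl + ST + SM) and hip adductors
#' (AD = AL + AM + AB + Sar + Gr). The whole thigh is the union of the
#' three groups.
#'
#' @return Named list of character vectors of member muscle names.
#' @export
muscleGroups <- function() {
  list(QF = c("RF", "VL", "VI", "VM"),
       HM = c("BFs", "BFl", "ST", "SM"),
       AD = c("AL", "AM", "AB", "Sar", "Gr"))
}

## non-muscle outline names accepted in a SliceOutlineSet
.outlineExtras <- c("fascia", "femur")

## integer label codes used in TissueLabelMap slices
.labelLegend <- function() {
  m <- thighMuscles()
  c(structure(0L, names = "background"),
    structure(seq_along(m), names = m),
    structure(100L + seq_along(m), names = paste0("IntraMAT:", m)),
    structure(200L, names = "InterMAT"),
    structure(201L, names = "SAT"),
    structure(202L, names = "femur"),
    structure(203L, names = "unassigned"))
}

#' Acquisition geometry of an axial image stack
#'
#' Holds the field of view, reconstruction matrix, slice thickness and
#' interslice gap of an axial acquisition. The pixel spacing is
#' \code{fovMm / matrixPx} and must be identical on both axes for area
#' computations; the slice spacing used for volume integration is the
#' centre-to-centre distance \code{sliceThicknessMm + intersliceGapMm}
#' unless overridden.
#'
#' @slot fovMm numeric(2), field of view in mm (rows, columns).
#' @slot matrixPx integer(2), image matrix in pixels (rows, columns).
#' @slot sliceThicknessMm slice thickness in mm.
#' @slot intersliceGapMm gap between slices in mm.
#' @slot sliceSpacingMm centre-to-centre slice distance in mm used when
#'   integrating cross-sectional areas to volumes.
#' @export
setClass("AcquisitionGeometry",
  representation(fovMm = "numeric", matrixPx = "integer",
                 sliceThicknessMm = "numeric", intersliceGapMm = "numeric",
                 sliceSpacingMm = "numeric"))

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (length(object@fovMm) != 2L || any(object@fovMm <= 0))
    msg <- c(msg, "fovMm must be two positive values")
  if (length(object@matrixPx) != 2L || any(object@matrixPx < 1L))
    msg <- c(msg, "matrixPx must be two positive integers")
  if (object@sliceThicknessMm <= 0) msg <- c(msg, "sliceThicknessMm must be > 0")
  if (object@intersliceGapMm < 0) msg <- c(msg, "intersliceGapMm must be >= 0")
  if (object@sliceSpacingMm <= 0) msg <- c(msg, "sliceSpacingMm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionGeometry
#'
#' Defaults reproduce a 450 x 270 mm field of view reconstructed to a
#' 320 x 192 matrix (pixel spacing 1.40625 mm on both axes), 12 mm slices
#' separated by a 12 mm gap, hence a 24 mm centre-to-centre spacing.
#'
#' @param fovMm field of view in mm, (rows, columns).
#' @param matrixPx matrix size in pixels, (rows, columns).
#' @param sliceThicknessMm slice thickness in mm.
#' @param intersliceGapMm interslice gap in mm.
#' @param sliceSpacingMm centre-to-centre slice spacing in mm; defaults to
#'   thickness + gap.
#' @return An \linkS4class{AcquisitionGeometry}.
#' @export
#' @examples
#' g <- acquisitionGeometry()
#' pixelSpacingMm(g)
acquisitionGeometry <- function(fovMm = c(450, 270), matrixPx = c(320L, 192L),
                                sliceThicknessMm = 12, intersliceGapMm = 12,
                                sliceSpacingMm = sliceThicknessMm + intersliceGapMm) {
  new("AcquisitionGeometry", fovMm = as.numeric(fovMm),
      matrixPx = as.integer(matrixPx),
      sliceThicknessMm = as.numeric(sliceThicknessMm),
      intersliceGapMm = as.numeric(intersliceGapMm),
      sliceSpacingMm = as.numeric(sliceSpacingMm))
}

#' A stack of axial grayscale slices
#'
#' The raw input of the pipeline: a list of equally sized numeric matrices
#' (one per axial slice, row = image row) plus the acquisition geometry.
#'
#' @slot slices list of numeric matrices with identical dimensions.
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @export
setClass("AxialImageStack",
  representation(slices = "list", geometry = "AcquisitionGeometry"))

setValidity("AxialImageStack", function(object) {
  if (length(object@slices) == 0L) return("stack must contain at least one slice")
  dims <- vapply(object@slices, dim, integer(2))
  if (!all(dims == dims[, 1L])) return("all slices must share dimensions")
  if (!all(dims[, 1L] == object@geometry@matrixPx))
    return("slice dimensions must equal geometry matrixPx")
  if (!all(vapply(object@slices, function(s) all(is.finite(s)), logical(1))))
    return("slices must be finite")
  TRUE
})

#' @export
axialImageStack <- function(slices, geometry) {
  if (is.matrix(slices)) slices <- list(slices)
  new("AxialImageStack", slices = slices, geometry = geometry)
}

#' Per-pixel tissue labels for a stack
#'
#' Integer-coded tissue class per pixel per slice. The legend maps class
#' names (background, the 13 muscles, their IntraMAT counterparts,
#' InterMAT, SAT, femur, unassigned) to integer codes. The classes
#' partition each slice.
#'
#' @slot slices list of integer matrices.
#' @slot legend named integer vector mapping class name to code.
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @export
setClass("TissueLabelMap",
  representation(slices = "list", legend = "integer",
                 geometry = "AcquisitionGeometry"))

setValidity("TissueLabelMap", function(object) {
  if (length(object@slices) == 0L) return("label map must contain slices")
  codes <- unique(unlist(lapply(object@slices, as.vector)))
  if (!all(codes %in% object@legend))
    return("slice codes not covered by legend")
  TRUE
})

#' Estimated multiplicative bias field for one slice
#'
#' @slot field numeric matrix, strictly positive, mean 1 over signal pixels.
#' @slot iterations number of sharpening/smoothing cycles performed.
#' @slot converged whether the convergence tolerance was met.
#' @slot mask logical matrix of the signal pixels used in fitting.
#' @export
setClass("BiasField",
  representation(field = "matrix", iterations = "integer",
                 converged = "logical", mask = "matrix"))

setValidity("BiasField", function(object) {
  if (any(!is.finite(object@field)) || any(object@field <= 0))
    return("field must be finite and strictly positive")
  if (object@iterations < 1L) return("iterations must be >= 1")
  TRUE
})

#' Muscle/adipose intensity threshold estimate
#'
#' Result of the repeated bimodal-histogram threshold determination: the
#' per-repetition thresholds, their arithmetic mean (the value used for
#' classification), and the smoothed histogram of the final repetition.
#'
#' @slot thresholds per-repetition threshold intensities.
#' @slot threshold arithmetic mean of the repetitions.
#' @slot histogram list with bin mids, raw counts and smoothed counts.
#' @export
setClass("ThresholdResult",
  representation(thresholds = "numeric", threshold = "numeric",
                 histogram = "list"))

setValidity("ThresholdResult", function(object) {
  if (abs(object@threshold - mean(object@thresholds)) >
      1e-8 * max(1, abs(object@threshold)))
    return("threshold must be the mean of the repetitions")
  TRUE
})

#' Named traced outlines for one slice
#'
#' Closed polygons (columns x, y in 0-based pixel units, vertices at pixel
#' centres) for each traced muscle, the deep fascia and the femur.
#' Containment is decided by the even-odd rule evaluated at pixel centres.
#'
#' @slot sliceIndex 1-based index of the slice the outlines belong to.
#' @slot polygons named list of two-column vertex matrices.
#' @export
setClass("SliceOutlineSet",
  representation(sliceIndex = "integer", polygons = "list"))

setValidity("SliceOutlineSet", function(object) {
  nm <- names(object@polygons)
  ok <- c(thighMuscles(), .outlineExtras)
  bad <- setdiff(nm, ok)
  if (length(bad))
    return(sprintf("unknown structure name(s) %s; valid names are: %s",
                   paste(bad, collapse = ", "), paste(ok, collapse = ", ")))
  if (anyDuplicated(nm)) return("duplicated structure names")
  for (p in object@polygons) {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      return("each polygon must be a matrix with >= 3 vertex rows and 2 columns")
    if (any(!is.finite(p))) return("polygon vertices must be finite")
  }
  TRUE
})

#' @export
sliceOutlineSet <- function(polygons, sliceIndex = 1L) {
  new("SliceOutlineSet", sliceIndex = as.integer(sliceIndex),
      polygons = polygons)
}

#' Specification of a synthetic thigh phantom
#'
#' Describes the geometry (fascia ellipse, subcutaneous ring, femur disk,
#' muscle polygons), tissue fractions, intensity model and bias-field
#' model from which \code{\link{generatePhantom}} renders an image stack
#' with exact ground truth.
#'
#' @slot geometry an \linkS4class{AcquisitionGeometry}.
#' @slot nSlices number of axial slices to render.
#' @slot fascia list(center = c(x, y), semiAxes = c(ax, ay)) in pixels.
#' @slot skin list(semiAxes) of the outer skin ellipse (same centre).
#' @slot femur list(center, radius) in pixels.
#' @slot muscles named list of muscle polygons (x, y columns, 0-based).
#' @slot intramatFractions named per-muscle IntraMAT area fraction in [0, 1).
#' @slot intermatFraction fraction of the residual fascial area rendered as
#'   intermuscular adipose tissue, in [0, 1).
#' @slot intensityModel list(muscleMean, fatMean, noiseSd, femurMean,
#'   noiseModel) in arbitrary units.
#' @slot biasModel list(coefficients, amplitude, clampRange) of the
#'   second-order polynomial multiplicative field.
#' @slot seed integer seed controlling speckle and noise.
#' @export
setClass("PhantomSpec",
  representation(geometry = "AcquisitionGeometry", nSlices = "integer",
                 fascia = "list", skin = "list", femur = "list",
                 muscles = "list", intramatFractions = "numeric",
                 intermatFraction = "numeric", intensityModel = "list",
                 biasModel = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  im <- object@intensityModel
  if (im$fatMean <= im$muscleMean)
    msg <- c(msg, "fat mean must exceed muscle mean")
  if (im$noiseSd < 0) msg <- c(msg, "noise sd must be >= 0")
  fr <- object@intramatFractions
  if (any(fr < 0 | fr >= 1)) msg <- c(msg, "IntraMAT fractions must lie in [0, 1)")
  if (object@intermatFraction < 0 || object@intermatFraction >= 1)
    msg <- c(msg, "InterMAT fraction must lie in [0, 1)")
  if (!all(names(object@muscles) %in% thighMuscles()))
    msg <- c(msg, "muscle names must be thigh muscle abbreviations")
  if (is.null(names(fr)) || !all(names(object@muscles) %in% names(fr)))
    msg <- c(msg, "intramatFractions must be named for every muscle")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  ## femur disk inside fascia ellipse
  fa <- object@fascia; fe <- object@femur
  d <- fe$center - fa$center
  if (sum((abs(d) + fe$radius)^2 / fa$semiAxes^2) > 1)
    msg <- c(msg, "femur disk must lie inside the fascia ellipse")
  if (length(msg)) msg else TRUE
})

#' Ground truth accompanying a rendered phantom
#'
#' @slot labels the true \linkS4class{TissueLabelMap}.
#' @slot csa data.frame of true per-slice cross-sectional areas (cm^2).
#' @slot volumes data.frame of true per-structure volumes (cm^3).
#' @slot biasField the true multiplicative field (one matrix, shared by
#'   all slices of the phantom).
#' @export
setClass("GroundTruth",
  representation(labels = "TissueLabelMap", csa = "data.frame",
                 volumes = "data.frame", biasField = "matrix"))

#' Design of a synthetic longitudinal cohort
#'
#' @slot nPerGroup named integer vector of subjects per group
#'   (e.g. c(TR = 13, CTR = 7)).
#' @slot effectModel data.frame with columns structure, group,
#'   baselineMean, baselineSd, changeMean, changeSd (all volumes in cm^3):
#'   per-structure true before-volume distribution and before-to-after
#'   change distribution.
#' @slot seed integer seed.
#' @export
setClass("CohortDesign",
  representation(nPerGroup = "integer", effectModel = "data.frame",
                 seed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (any(object@nPerGroup < 2L))
    msg <- c(msg, "need at least 2 subjects per group")
  em <- object@effectModel
  need <- c("structure", "group", "baselineMean", "baselineSd",
            "changeMean", "changeSd")
  if (!all(need %in% names(em)))
    msg <- c(msg, paste("effectModel must have columns",
                        paste(need, collapse = ", ")))
  else if (any(em$changeSd < 0) || any(em$baselineSd < 0))
    msg <- c(msg, "effect-model sds must be >= 0")
  if (is.null(names(object@nPerGroup)))
    msg <- c(msg, "nPerGroup must be named by group")
  if (length(msg)) msg else TRUE
})

#' @export
cohortDesign <- function(nPerGroup, effectModel, seed = 1L) {
  new("CohortDesign", nPerGroup = structure(as.integer(nPerGroup),
                                            names = names(nPerGroup)),
      effectModel = effectModel, seed = as.integer(seed))
}
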