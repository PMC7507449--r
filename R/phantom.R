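#' Construct a phantom specification
#'
#' Low-level constructor; most users want \code{\link{defaultPhantomSpec}}.
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param nSlices number of axial slices.
#' @param fascia list(center, semiAxes) of the deep-fascia ellipse (pixels).
#' @param skin list(semiAxes) of the outer skin ellipse (same centre as the
#'   fascia); the ring between the two is rendered as subcutaneous adipose
#'   tissue.
#' @param femur list(center, radius) of the femur disk (pixels).
#' @param muscles named list of muscle polygons.
#' @param intramatFractions named per-muscle IntraMAT area fraction.
#' @param intermatFraction fraction of the residual fascial area (inside the
#'   fascia, outside all muscles and the femur) rendered as InterMAT.
#' @param intensityModel list(muscleMean, fatMean, noiseSd, femurMean,
#'   noiseModel = "gaussian"|"rician").
#' @param biasModel list(coefficients (length 5: x, y, x^2, xy, y^2),
#'   amplitude, clampRange).
#' @param seed integer seed for speckle and noise.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(geometry, nSlices, fascia, skin, femur, muscles,
                        intramatFractions, intermatFraction,
                        intensityModel, biasModel, seed = 1L) {
  if (is.null(intensityModel$femurMean))
    intensityModel$femurMean <- 0.45 * intensityModel$muscleMean
  if (is.null(intensityModel$noiseModel))
    intensityModel$noiseModel <- "gaussian"
  if (length(intramatFractions) == 1L && is.null(names(intramatFractions)))
    intramatFractions <- structure(rep(intramatFractions, length(muscles)),
                                   names = names(muscles))
  new("PhantomSpec", geometry = geometry, nSlices = as.integer(nSlices),
      fascia = fascia, skin = skin, femur = femur, muscles = muscles,
      intramatFractions = intramatFractions,
      intermatFraction = intermatFraction,
      intensityModel = intensityModel, biasModel = biasModel,
      seed = as.integer(seed))
}

#' Default thigh phantom specification
#'
#' A stylized mid-thigh cross-section on the default acquisition geometry
#' (450 x 270 mm field of view, 320 x 192 matrix, 12 mm slices with a
#' 12 mm gap): an elliptical deep fascia containing a central femur disk
#' and the requested muscles laid out as non-overlapping annular sectors,
#' surrounded by a subcutaneous fat ring out to the skin ellipse.
#' Muscle tissue and fat are rendered as a bimodal intensity distribution
#' (means 100 and 200 a.u.); the default noise sd of 5 puts the
#' muscle-signal-to-noise ratio at 20, and the default bias-field
#' amplitude of 0.2 gives a 20 percent smooth multiplicative
#' nonuniformity. IntraMAT is uniform random speckle within each muscle
#' at the requested area fraction.
#'
#' @param nSlices number of slices (default 15, covering a 36 cm thigh
#'   segment at the 24 mm slice spacing).
#' @param muscles which muscles to lay out (default all 13).
#' @param intramatFraction scalar or named per-muscle IntraMAT fraction.
#' @param intermatFraction InterMAT fraction of the residual fascial area.
#' @param muscleMean,fatMean,noiseSd intensity model (arbitrary units).
#' @param biasAmplitude peak deviation of the multiplicative field from 1;
#'   0 renders a unit field.
#' @param noiseModel "gaussian" (default) or "rician".
#' @param geometry acquisition geometry.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' spec <- defaultPhantomSpec(nSlices = 2, noiseSd = 0, biasAmplitude = 0)
#' ph <- generatePhantom(spec)
#' ph$stack
defaultPhantomSpec <- function(nSlices = 15L, muscles = thighMuscles(),
                               intramatFraction = 0.15,
                               intermatFraction = 0.5,
                               muscleMean = 100, fatMean = 200, noiseSd = 5,
                               biasAmplitude = 0.2,
                               noiseModel = c("gaussian", "rician"),
                               geometry = acquisitionGeometry(),
                               seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  H <- geometry@matrixPx[1]; W <- geometry@matrixPx[2]
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  ## anatomy scales with the matrix so reduced-resolution phantoms keep
  ## the same proportions (defaults give 55/60 px axes at 320 x 192)
  fascia <- list(center = ctr,
                 semiAxes = c(round(0.2865 * W), round(0.1875 * H)))
  skin <- list(semiAxes = fascia$semiAxes + max(8, round(0.0625 * W)))
  femur <- list(center = ctr, radius = round(0.052 * W))
  rho0 <- (femur$radius + max(2, round(0.02 * W))) / min(fascia$semiAxes)
  rho1 <- 0.88
  nm <- length(muscles)
  ## the inter-sector gap is 15% of the pitch so that cohort rendering can
  ## scale sectors by a good +/-15% in volume without neighbour overlap
  gap <- 0.15 * 2 * pi / nm
  width <- (2 * pi - nm * gap) / nm
  polys <- vector("list", nm)
  for (i in seq_len(nm)) {
    th0 <- (i - 1) * (width + gap)
    polys[[i]] <- sectorPolygon(fascia$center, fascia$semiAxes,
                                rho0, rho1, th0, th0 + width)
  }
  names(polys) <- muscles
  if (length(intramatFraction) == 1L)
    intramatFraction <- structure(rep(intramatFraction, nm), names = muscles)
  phantomSpec(geometry = geometry, nSlices = nSlices, fascia = fascia,
              skin = skin, femur = femur, muscles = polys,
              intramatFractions = intramatFraction,
              intermatFraction = intermatFraction,
              intensityModel = list(muscleMean = muscleMean,
                                    fatMean = fatMean, noiseSd = noiseSd,
                                    femurMean = 0.45 * muscleMean,
                                    noiseModel = noiseModel),
              biasModel = list(coefficients = c(0.8, 0.5, 0.6, -0.4, -0.5),
                               amplitude = biasAmplitude,
                               clampRange = c(0.8, 1.25)),
              seed = seed)
}

## evaluate the clamped second-order polynomial multiplicative field
evaluateBiasModel <- function(biasModel, dim) {
  H <- dim[1]; W <- dim[2]
  X <- matrix(0:(W - 1L), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1L), H, W)
  u <- (X - (W - 1) / 2) / ((W - 1) / 2)
  v <- (Y - (H - 1) / 2) / ((H - 1) / 2)
  cf <- biasModel$coefficients
  raw <- cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * u * v + cf[5] * v^2
  mx <- max(abs(raw))
  if (mx > 0) raw <- raw / mx
  cl <- biasModel$clampRange
  pmin(pmax(1 + biasModel$amplitude * raw, cl[1]), cl[2])
}

#' Render a thigh phantom with exact ground truth
#'
#' Renders each slice as \code{tissue template x bias field + noise}.
#' Within every muscle polygon, a seeded uniform random subset of pixels
#' of size \code{round(fraction x polygon pixel count)} is rendered as
#' IntraMAT speckle at the fat intensity; likewise for the InterMAT
#' fraction of the residual fascial area. The returned ground truth holds
#' the true per-pixel label map (whose class counts times the pixel area
#' are the true CSAs, exactly), the true CSA and volume tables, and the
#' true multiplicative field.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return List with elements \code{stack} (an
#'   \linkS4class{AxialImageStack}), \code{truth} (a
#'   \linkS4class{GroundTruth}) and \code{outlines} (list of
#'   \linkS4class{SliceOutlineSet}, the manual-segmentation stand-in).
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  geom <- spec@geometry
  dimHW <- geom@matrixPx
  im <- spec@intensityModel
  if (im$fatMean <= im$muscleMean)
    stop("intensity model error: fat mean must exceed muscle mean")

  ## the fascia and femur regions are defined by the same polygons that are
  ## returned as outlines, so that downstream classification of a noiseless
  ## phantom reproduces the ground-truth labels pixel for pixel
  fasciaPoly <- circleishEllipsePolygon(spec@fascia$center, spec@fascia$semiAxes)
  femurPoly <- circlePolygon(spec@femur$center, spec@femur$radius, 36L)
  fasciaM <- polygonMask(fasciaPoly, dimHW)
  skinM <- ellipseMask(spec@fascia$center, spec@skin$semiAxes, dimHW)
  femurM <- polygonMask(femurPoly, dimHW)
  muscleM <- lapply(spec@muscles, polygonMask, dim = dimHW)

  ## geometry sanity: pairwise non-overlap, containment in fascia
  occ <- matrix(0L, dimHW[1], dimHW[2])
  for (m in muscleM) occ <- occ + m
  if (any(occ > 1L)) stop("geometry error: overlapping muscle polygons")
  if (any(occ == 1L & !fasciaM))
    stop("geometry error: muscle polygon outside the fascia ellipse")
  if (any((occ == 1L) & femurM))
    stop("geometry error: muscle polygon overlaps the femur")

  legend <- .labelLegend()
  satM <- skinM & !fasciaM
  interRegion <- fasciaM & !femurM & occ == 0L
  field <- evaluateBiasModel(spec@biasModel, dimHW)
  mnames <- names(spec@muscles)
  codes <- legend[mnames]
  icodes <- legend[paste0("IntraMAT:", mnames)]

  slices <- vector("list", spec@nSlices)
  labels <- vector("list", spec@nSlices)
  withSeed(spec@seed, {
    for (s in seq_len(spec@nSlices)) {
      lab <- matrix(legend[["background"]], dimHW[1], dimHW[2])
      tmpl <- matrix(0, dimHW[1], dimHW[2])
      tmpl[satM] <- im$fatMean
      lab[satM] <- legend[["SAT"]]
      ## residual fascial area: InterMAT speckle at the requested fraction,
      ## remainder left as unassigned muscle-like tissue
      ridx <- which(interRegion)
      nInter <- round(spec@intermatFraction * length(ridx))
      inter <- if (nInter > 0) sample(ridx, nInter) else integer()
      tmpl[ridx] <- im$muscleMean
      lab[ridx] <- legend[["unassigned"]]
      tmpl[inter] <- im$fatMean
      lab[inter] <- legend[["InterMAT"]]
      for (i in seq_along(muscleM)) {
        idx <- which(muscleM[[i]] & !femurM)
        if (!length(idx)) stop("geometry error: empty muscle polygon: ",
                               mnames[i])
        tmpl[idx] <- im$muscleMean
        lab[idx] <- codes[i]
        nIntra <- round(spec@intramatFractions[[mnames[i]]] * length(idx))
        if (nIntra > 0) {
          sp <- sample(idx, nIntra)
          tmpl[sp] <- im$fatMean
          lab[sp] <- icodes[i]
        }
      }
      tmpl[femurM] <- im$femurMean
      lab[femurM] <- legend[["femur"]]
      img <- tmpl * field
      if (im$noiseSd > 0) {
        if (im$noiseModel == "rician") {
          img <- sqrt((img + rnorm(length(img), 0, im$noiseSd))^2 +
                        rnorm(length(img), 0, im$noiseSd)^2)
        } else {
          img <- img + rnorm(length(img), 0, im$noiseSd)
        }
        img[img < 0] <- 0
      }
      slices[[s]] <- img
      labels[[s]] <- lab
    }
  })

  labelMap <- new("TissueLabelMap", slices = labels, legend = legend,
                  geometry = geom)
  csa <- labelCSATable(labelMap)
  vols <- volumeTableFromCSA(csa, geom)
  truth <- new("GroundTruth", labels = labelMap, csa = csa,
               volumes = vols, biasField = field)
  outl <- lapply(seq_len(spec@nSlices), function(s) {
    polys <- spec@muscles
    polys$fascia <- fasciaPoly
    polys$femur <- femurPoly
    sliceOutlineSet(polys, s)
  })
  list(stack = axialImageStack(slices, geom), truth = truth,
       outlines = outl)
}

## dense polygonal approximation of an ellipse boundary
circleishEllipsePolygon <- function(center, semiAxes, nVertices = 90L) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
  cbind(center[1] + semiAxes[1] * cos(th),
        center[2] + semiAxes[2] * sin(th))
}
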