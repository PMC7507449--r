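# Shared fixture builders. Fixtures are generated in code at test time;
# reduced-resolution geometry keeps the suite fast while preserving the
# default pixel spacing (225/160 = 135/96 = 1.40625 mm).

smallGeometry <- function()
  acquisitionGeometry(fovMm = c(225, 135), matrixPx = c(160L, 96L))

smallPhantomSpec <- function(nSlices = 2L, muscles = c("RF", "VL", "VI", "VM"),
                             ...) {
  defaultPhantomSpec(nSlices = nSlices, muscles = muscles,
                     geometry = smallGeometry(), ...)
}

# a phantom spec holding one square muscle of an exact pixel count
squareMusclePhantom <- function(sidePx = 10L, intramatFraction = 0.1,
                                noiseSd = 0, seed = 1L) {
  g <- smallGeometry()
  ctr <- c((96 - 1) / 2, (160 - 1) / 2)
  x0 <- ctr[1] + 4; y0 <- ctr[2] - sidePx / 2
  sq <- cbind(c(x0 - 0.5, x0 + sidePx - 0.5, x0 + sidePx - 0.5, x0 - 0.5),
              c(y0 - 0.5, y0 - 0.5, y0 + sidePx - 0.5, y0 + sidePx - 0.5))
  phantomSpec(geometry = g, nSlices = 1L,
              fascia = list(center = ctr, semiAxes = c(27, 30)),
              skin = list(semiAxes = c(33, 36)),
              femur = list(center = ctr - c(15, 0), radius = 5),
              muscles = list(RF = sq),
              intramatFractions = c(RF = intramatFraction),
              intermatFraction = 0,
              intensityModel = list(muscleMean = 100, fatMean = 200,
                                    noiseSd = noiseSd),
              biasModel = list(coefficients = rep(0, 5), amplitude = 0,
                               clampRange = c(0.8, 1.25)),
              seed = seed)
}

# two-Gaussian mixture sample and brute-force minimum of its density
mixtureSample <- function(n, mu1, sd1, mu2, sd2) {
  k <- rbinom(1, n, 0.5)
  c(rnorm(k, mu1, sd1), rnorm(n - k, mu2, sd2))
}

mixtureDensityMin <- function(mu1, sd1, mu2, sd2) {
  x <- seq(mu1, mu2, by = 0.01)
  d <- 0.5 * dnorm(x, mu1, sd1) + 0.5 * dnorm(x, mu2, sd2)
  x[which.min(d)]
}

circlePolygonForTest <- function(center, radius, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# pixel counts per label class of one label-map slice
labelCounts <- function(labelMap, slice = 1L) {
  lab <- labelMap@slices[[slice]]
  leg <- labelMap@legend
  vapply(leg, function(code) sum(lab == code), numeric(1))
}
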