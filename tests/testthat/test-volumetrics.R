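test_that("CSA conversion matches the hand-computed pixel area", {
  g <- acquisitionGeometry()
  expect_equal(csaFromPixels(0, g), 0)
  expect_equal(csaFromPixels(1, g), (45 / 320)^2)
  expect_equal(csaFromPixels(1, g), 0.019775390625)
  expect_equal(csaFromPixels(1000, g), 19.775390625)
  expect_error(csaFromPixels(-1, g), "negative")
})

test_that("volume integration is the rectangle rule over slice spacing", {
  expect_equal(integrateVolume(rep(10, 5), 2.4), 120)
  expect_equal(integrateVolume(7, 2.4), 16.8)
  g <- acquisitionGeometry()   # 24 mm spacing -> e = 2.4 cm
  expect_equal(integrateVolume(rep(10, 5), g), 120)
  expect_error(integrateVolume(numeric(0), 2.4), "no slices")
})

test_that("a rasterized cylinder integrates to its analytic volume", {
  g <- smallGeometry()
  ctr <- c(47.5, 79.5)
  r <- 20
  poly <- circlePolygonForTest(ctr, r)
  n <- sum(polygonMask(poly, g@matrixPx))
  csa <- csaFromPixels(n, g)
  vol <- integrateVolume(rep(csa, 6), g)
  analytic <- pi * (r * pixelSpacingMm(g) / 10)^2 * 6 * (g@sliceSpacingMm / 10)
  expect_lt(abs(vol - analytic) / analytic, 0.03)
})

test_that("IntraMAT content and percentage change follow their definitions", {
  expect_equal(intramatContent(90, 10), 10)
  expect_equal(intramatContent(50, 0), 0)
  expect_equal(intramatContent(3780.0, 795.5), 17.39, tolerance = 1e-3)
  expect_error(intramatContent(0, 0), "undefined-content")
  expect_equal(percentChange(100, 100), 0)
  expect_equal(percentChange(100, 90), -10)
  expect_equal(percentChange(719.9, 574.6), -20.18, tolerance = 1e-3)
  expect_error(percentChange(0, 10), "positive")
})

test_that("group aggregation sums members and flags missing ones", {
  tab <- data.frame(slice = 1L,
                    structure = c("RF", "VL", "VI", "VM"),
                    tissueCSA = rep(10, 4), intramatCSA = rep(1, 4))
  out <- aggregateStructures(tab)
  expect_equal(out$tissueCSA[out$structure == "QF"], 40)
  expect_equal(out$intramatCSA[out$structure == "QF"], 4)
  expect_true(all(c("RF", "VL", "VI", "VM") %in% out$structure))
  full <- data.frame(slice = 1L, structure = thighMuscles(),
                     tissueCSA = c(rep(10, 4), rep(7.5, 4), rep(6, 5)),
                     intramatCSA = 0)
  outf <- aggregateStructures(full)
  expect_equal(outf$tissueCSA[outf$structure == "whole thigh"],
               40 + 30 + 30)
  expect_error(aggregateStructures(
    data.frame(slice = 1L, structure = c("RF", "VL"), tissueCSA = 1,
               intramatCSA = 0)), "missing member muscle")
})

test_that("CSA and volume are additive and scale with the pixel spacing", {
  spec <- smallPhantomSpec(nSlices = 2)
  ph <- generatePhantom(spec)
  vols <- ph$truth@volumes
  mus <- vols[vols$structure %in% c("RF", "VL", "VI", "VM"), ]
  qf <- vols[vols$structure == "QF", ]
  expect_equal(sum(mus$tissueVolume), qf$tissueVolume)
  expect_equal(sum(mus$intramatVolume), qf$intramatVolume)
  g1 <- acquisitionGeometry()
  g2 <- acquisitionGeometry(fovMm = 2 * g1@fovMm)   # double the spacing
  expect_equal(csaFromPixels(500, g2), 4 * csaFromPixels(500, g1))
})

test_that("pipeline volumes equal ground truth exactly on a noiseless phantom", {
  spec <- smallPhantomSpec(nSlices = 2, noiseSd = 0, biasAmplitude = 0,
                           seed = 6)
  ph <- generatePhantom(spec)
  seg <- classifyStack(ph$stack, ph$outlines, seed = 4)
  est <- volumeTableFromCSA(labelCSATable(seg$labels), spec@geometry)
  tru <- ph$truth@volumes
  m <- merge(est, tru, by = "structure")
  expect_equal(m$tissueVolume.x, m$tissueVolume.y)
  expect_equal(m$intramatVolume.x, m$intramatVolume.y)
})

test_that("volume table derives content per structure row", {
  spec <- smallPhantomSpec(nSlices = 2, intramatFraction = 0.2)
  ph <- generatePhantom(spec)
  v <- ph$truth@volumes
  rf <- v[v$structure == "RF", ]
  expect_equal(rf$intramatContent,
               intramatContent(rf$tissueVolume, rf$intramatVolume))
  expect_true(all(v$intramatContent >= 0 & v$intramatContent <= 100,
                  na.rm = TRUE))
})
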