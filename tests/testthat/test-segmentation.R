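test_that("threshold lands at the mixture-density minimum", {
  set.seed(11)
  s <- mixtureSample(2e4, 100, 5, 200, 5)
  ht <- histogramThreshold(s)
  expect_gt(ht$threshold, 140)
  expect_lt(ht$threshold, 160)
  expect_lt(abs(ht$threshold - mixtureDensityMin(100, 5, 200, 5)), 2)
  ## overlapping modes: unique interior minimum
  s2 <- mixtureSample(2e5, 100, 15, 200, 15)
  ht2 <- histogramThreshold(s2)
  expect_lt(abs(ht2$threshold - mixtureDensityMin(100, 15, 200, 15)), 2)
})

test_that("fully separated degenerate sample thresholds strictly between modes", {
  s <- c(rep(100, 500), rep(200, 500))
  ht <- histogramThreshold(s)
  expect_gt(ht$threshold, 100)
  expect_lt(ht$threshold, 200)
})

test_that("unimodal samples raise a bimodality error", {
  set.seed(2)
  expect_error(histogramThreshold(rnorm(5000, 100, 5)), "bimodality")
  expect_error(histogramThreshold(rep(1, 100)), "bimodality")
})

test_that("computeThreshold averages seeded jittered repetitions", {
  spec <- smallPhantomSpec(nSlices = 1, noiseSd = 5, biasAmplitude = 0)
  ph <- generatePhantom(spec)
  sl <- getSlice(ph$stack, 1)
  rois <- autoRoiSample(sl, ph$outlines[[1]])
  tr <- computeThreshold(sl, rois, nRepetitions = 3, seed = 7)
  expect_length(tr@thresholds, 3)
  expect_equal(tr@threshold, mean(tr@thresholds))
  ## reproducibility: same seed, identical result
  tr2 <- computeThreshold(sl, rois, nRepetitions = 3, seed = 7)
  expect_identical(tr@thresholds, tr2@thresholds)
  ## threshold separates the two phantom intensity modes
  expect_gt(tr@threshold, 100)
  expect_lt(tr@threshold, 200)
  ## out-of-image ROI
  bad <- roiSample(muscle = list(c(2, 2, 5), c(30, 30, 3), c(40, 40, 3)),
                   sat = rois$sat)
  expect_error(computeThreshold(sl, bad), "geometry error")
})

test_that("muscle pixel counts are conserved and ties go to muscle", {
  sl <- matrix(0, 40, 40)
  sq <- cbind(c(9.5, 19.5, 19.5, 9.5), c(9.5, 9.5, 19.5, 19.5))
  inside <- polygonMask(sq, c(40, 40))
  expect_equal(sum(inside), 100)
  vals <- rep(80, 100); vals[1:10] <- 180
  sl[inside] <- vals
  ct <- classifyMusclePixels(sl, sq, threshold = 150)
  expect_equal(unname(ct), c(100, 90, 10))
  expect_equal(ct[["total"]], ct[["muscle"]] + ct[["intramat"]])
  ## all pixels below the threshold
  ct2 <- classifyMusclePixels(sl, sq, threshold = 500)
  expect_equal(ct2[["intramat"]], 0)
  ## tie rule: equality counts as muscle
  sl[inside] <- 150
  ct3 <- classifyMusclePixels(sl, sq, threshold = 150)
  expect_equal(ct3[["muscle"]], 100)
  expect_error(classifyMusclePixels(sl, sq + 1000, 150), "empty polygon")
})

test_that("raising the threshold is monotone in the counts", {
  spec <- smallPhantomSpec(nSlices = 1, noiseSd = 10, biasAmplitude = 0.2)
  ph <- generatePhantom(spec)
  sl <- getSlice(ph$stack, 1)
  poly <- ph$outlines[[1]]@polygons$RF
  thr <- seq(80, 220, by = 10)
  cts <- t(vapply(thr, function(t) classifyMusclePixels(sl, poly, t),
                  numeric(3)))
  expect_true(all(diff(cts[, "muscle"]) >= 0))
  expect_true(all(diff(cts[, "intramat"]) <= 0))
  expect_true(all(cts[, "total"] == cts[1, "total"]))
})

test_that("slice classification partitions the image and SAT matches the subtraction equation", {
  spec <- smallPhantomSpec(nSlices = 1, noiseSd = 5, biasAmplitude = 0)
  ph <- generatePhantom(spec)
  sl <- getSlice(ph$stack, 1)
  lm1 <- classifySlice(sl, ph$outlines[[1]], threshold = 150,
                       geom = spec@geometry)
  cnt <- labelCounts(lm1)
  expect_equal(sum(cnt), prod(dim(sl)))
  ## SAT by direct labelling vs total-minus-parts over the partition
  muscleCnt <- sum(cnt[thighMuscles()])
  intraCnt <- sum(cnt[paste0("IntraMAT:", thighMuscles())])
  total <- sum(cnt) - cnt[["background"]]
  satSubtraction <- total - (muscleCnt + intraCnt + cnt[["InterMAT"]] +
                               cnt[["femur"]] + cnt[["unassigned"]])
  expect_equal(cnt[["SAT"]], satSubtraction)
  expect_error(classifySlice(sl, sliceOutlineSet(
    ph$outlines[[1]]@polygons["RF"]), 150), "fascia")
})

test_that("zero-InterMAT phantoms classify no InterMAT", {
  spec <- smallPhantomSpec(nSlices = 1, intermatFraction = 0, noiseSd = 0,
                           biasAmplitude = 0)
  ph <- generatePhantom(spec)
  lm1 <- classifySlice(getSlice(ph$stack, 1), ph$outlines[[1]], 150,
                       geom = spec@geometry)
  expect_equal(labelCounts(lm1)[["InterMAT"]], 0)
})

test_that("noiseless classification reproduces ground-truth labels exactly", {
  spec <- smallPhantomSpec(nSlices = 1, noiseSd = 0, biasAmplitude = 0)
  ph <- generatePhantom(spec)
  lm1 <- classifySlice(getSlice(ph$stack, 1), ph$outlines[[1]], 150,
                       geom = spec@geometry)
  expect_identical(lm1@slices[[1]], ph$truth@labels@slices[[1]])
})

test_that("IntraMAT fraction is recovered within 0.03 at SNR 20", {
  spec <- smallPhantomSpec(nSlices = 2, intramatFraction = 0.15,
                           noiseSd = 5, biasAmplitude = 0.2, seed = 21)
  ph <- generatePhantom(spec)
  co <- correctStack(ph$stack)
  seg <- classifyStack(co$corrected, ph$outlines, seed = 3)
  est <- volumeTableFromCSA(labelCSATable(seg$labels), spec@geometry)
  tru <- ph$truth@volumes
  for (m in c("RF", "VL", "VI", "VM")) {
    fe <- est$intramatContent[est$structure == m] / 100
    ft <- tru$intramatContent[tru$structure == m] / 100
    expect_lt(abs(fe - ft), 0.03)
  }
})
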