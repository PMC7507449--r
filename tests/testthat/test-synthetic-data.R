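test_that("zero IntraMAT fraction renders pure muscle", {
  spec <- smallPhantomSpec(nSlices = 1, intramatFraction = 0,
                           intermatFraction = 0, noiseSd = 0,
                           biasAmplitude = 0)
  ph <- generatePhantom(spec)
  cnt <- labelCounts(ph$truth@labels)
  expect_true(all(cnt[paste0("IntraMAT:", c("RF", "VL", "VI", "VM"))] == 0))
  expect_equal(cnt[["InterMAT"]], 0)
  csa <- ph$truth@csa
  expect_true(all(csa$intramatCSA[csa$structure %in% thighMuscles()] == 0))
})

test_that("IntraMAT speckle count is the rounded fraction of the polygon", {
  ph <- generatePhantom(squareMusclePhantom(sidePx = 10L,
                                            intramatFraction = 0.1))
  cnt <- labelCounts(ph$truth@labels)
  expect_equal(cnt[["IntraMAT:RF"]], 10)
  expect_equal(cnt[["RF"]], 90)
})

test_that("ground-truth CSA equals pixel count times squared pixel spacing", {
  g <- acquisitionGeometry()   # 450 x 270 mm -> 320 x 192 px
  expect_equal(pixelSpacingMm(g), 1.40625)
  expect_equal(csaFromPixels(1000, g), 1000 * (45 / 320)^2)
  expect_equal(csaFromPixels(1000, g), 19.775, tolerance = 1e-4)
  ph <- generatePhantom(squareMusclePhantom(intramatFraction = 0))
  csa <- ph$truth@csa
  rf <- csa[csa$structure == "RF", ]
  expect_equal(rf$tissueCSA, 100 * pixelAreaCm2(smallGeometry()))
})

test_that("identical spec and seed give bit-identical phantoms", {
  spec <- smallPhantomSpec(seed = 42)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(a$stack@slices, b$stack@slices)
  expect_identical(a$truth@labels@slices, b$truth@labels@slices)
})

test_that("label classes partition every slice exactly", {
  spec <- smallPhantomSpec(nSlices = 2, muscles = thighMuscles())
  ph <- generatePhantom(spec)
  for (s in 1:2) {
    cnt <- labelCounts(ph$truth@labels, s)
    expect_equal(sum(cnt), prod(smallGeometry()@matrixPx))
  }
  ## CSA bookkeeping: total thigh + background area = image area
  cnt <- labelCounts(ph$truth@labels, 1)
  csa <- ph$truth@csa
  tt <- csa$tissueCSA[csa$structure == "total thigh" & csa$slice == 1]
  pa <- pixelAreaCm2(smallGeometry())
  expect_equal(tt + cnt[["background"]] * pa,
               prod(smallGeometry()@matrixPx) * pa)
})

test_that("within-fascia histogram is bimodal up to noise sd (fat-muscle)/4", {
  spec <- smallPhantomSpec(nSlices = 1, noiseSd = 25, biasAmplitude = 0)
  ph <- generatePhantom(spec)
  sl <- getSlice(ph$stack, 1)
  lab <- ph$truth@labels@slices[[1]]
  inside <- lab != 0 & lab != ph$truth@labels@legend[["SAT"]] &
    lab != ph$truth@labels@legend[["femur"]]
  ht <- histogramThreshold(sl[inside])   # errors if unimodal
  expect_length(ht$modes, 2)
  expect_gt(ht$modes[2], ht$modes[1])
})

test_that("cohort truth reproduces a degenerate effect model exactly", {
  em <- data.frame(structure = "QF", group = c("TR", "CTR"),
                   baselineMean = c(1993.9, 2111.6), baselineSd = 0,
                   changeMean = c(0, -342.2), changeSd = 0)
  co <- generateCohort(cohortDesign(c(TR = 3, CTR = 3), em, seed = 9))
  v <- co$volumes
  for (su in unique(v$subject)) {
    b <- v$volume[v$subject == su & v$session == "before"]
    a <- v$volume[v$subject == su & v$session == "after"]
    expected <- if (grepl("^CTR", su)) -342.2 else 0
    expect_equal(a - b, expected)
  }
})

test_that("all-zero effect model gives identical sessions", {
  em <- data.frame(structure = c("RF", "VL"), group = "TR",
                   baselineMean = c(283.1, 684.6), baselineSd = c(50, 160),
                   changeMean = 0, changeSd = 0)
  co <- generateCohort(cohortDesign(c(TR = 4), em, seed = 2))
  v <- co$volumes
  wide <- merge(v[v$session == "before", c("subject", "structure", "volume")],
                v[v$session == "after", c("subject", "structure", "volume")],
                by = c("subject", "structure"))
  expect_equal(wide$volume.x, wide$volume.y)
})

test_that("sampled mean change concentrates near the model mean", {
  em <- defaultEffectModel(structures = "QF")
  co <- generateCohort(cohortDesign(c(TR = 8, CTR = 8), em, seed = 123))
  v <- co$volumes
  for (g in c("TR", "CTR")) {
    emg <- em[em$group == g, ]
    b <- v$volume[v$group == g & v$session == "before"]
    a <- v$volume[v$group == g & v$session == "after"]
    expect_lt(abs(mean(a - b) - emg$changeMean),
              2 * emg$changeSd / sqrt(8) + 1e-9)
  }
})

test_that("rendered cohort phantoms track the drawn relative volumes", {
  em <- data.frame(structure = "QF", group = c("TR", "CTR"),
                   baselineMean = 40, baselineSd = 2,
                   changeMean = c(0, -6), changeSd = 1)
  tmpl <- smallPhantomSpec(nSlices = 2, noiseSd = 0, biasAmplitude = 0)
  tmplQF <- generatePhantom(tmpl)$truth@volumes
  tmplQF <- tmplQF$tissueVolume[tmplQF$structure == "QF"]
  co <- generateCohort(cohortDesign(c(TR = 2, CTR = 2), em, seed = 5),
                       template = tmpl, render = TRUE)
  expect_length(co$phantoms, 8)
  for (p in co$phantoms) {
    target <- co$volumes$volume[co$volumes$subject == p$subject &
                                  co$volumes$session == p$session]
    got <- sum(p$truth@volumes$tissueVolume[
      p$truth@volumes$structure %in% c("RF", "VL", "VI", "VM")])
    ## rendered volume relative to the template equals the drawn volume
    ## relative to the group baseline mean, up to rasterization
    expect_lt(abs(got / tmplQF - target / 40), 0.06)
  }
})

test_that("invalid specs are rejected", {
  spec <- smallPhantomSpec()
  spec@intensityModel$fatMean <- 50
  expect_error(generatePhantom(spec), "fat mean")
  spec2 <- smallPhantomSpec()
  spec2@muscles[[2]] <- spec2@muscles[[1]]   # duplicate -> overlap
  expect_error(generatePhantom(spec2), "overlap")
  em <- data.frame(structure = "QF", group = "TR", baselineMean = 100,
                   baselineSd = 0, changeMean = 0, changeSd = 0)
  expect_error(cohortDesign(c(TR = 1), em), "2 subjects")
})
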