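test_that("intensity gate thresholds at a fraction of the image maximum", {
  img <- matrix(0, 10, 10)
  img[1, 1] <- 1000; img[2, 1] <- 99; img[3, 1] <- 150; img[4, 1] <- 100
  m <- intensityMask(img, 0.10)
  expect_equal(m[1, 1], 1)
  expect_equal(m[2, 1], 0)   # below 10 % of max
  expect_equal(m[3, 1], 1)
  expect_equal(m[4, 1], 1)   # exactly at threshold counts as foreground
  expect_equal(sum(m), 3)

  expect_equal(sum(intensityMask(matrix(7, 5, 5))), 25)  # uniform image
  expect_error(intensityMask(matrix(0, 3, 3)), "no positive")
})

test_that("lifetime masking keeps exactly the gated pixels as valid", {
  tau <- matrix(seq(0.1, 1.6, length.out = 16), 4, 4)
  ones <- matrix(1, 4, 4)
  expect_equal(maskLifetimes(tau, ones), tau)
  allMasked <- maskLifetimes(tau, matrix(0, 4, 4))
  expect_true(all(is.na(allMasked)))
  chk <- matrix(rep(c(1, 0), 8), 4, 4)
  out <- maskLifetimes(tau, chk)
  expect_equal(out[chk == 1], tau[chk == 1])
  expect_true(all(is.na(out[chk == 0])))
  expect_error(maskLifetimes(tau, matrix(1, 3, 3)), "shape")
})

test_that("range extraction uses closed intervals and skips invalid pixels", {
  rng <- calibrationRanges()$HDPE  # [2.89, 4.15]
  tau <- matrix(c(3.52, 1.40, 2.89, 4.15, 2.8899, 4.1501, NA, 3.0, 0),
                3, 3)
  out <- extractRange(tau, rng)
  expect_equal(as.vector(out), c(1, 0, 1, 1, 0, 0, 0, 1, 0))
})

test_that("morphology matches the brute-force oracle on random images", {
  set.seed(21)
  kernels <- list(matrix(1, 3, 3), matrix(1, 1, 3), matrix(1, 5, 5),
                  EBImage::makeBrush(5, "disc"))
  for (rep in 1:12) {
    img <- matrix(rbinom(16 * 16, 1, runif(1, 0.2, 0.7)), 16, 16)
    for (k in kernels) {
      expect_equal(binaryErode(img, k), bruteErode(img, k))
      expect_equal(binaryDilate(img, k), bruteDilate(img, k))
      expect_equal(binaryClosing(img, k), bruteClosing(img, k))
    }
  }
})

test_that("cleanup removes speckle, keeps solids, fills holes", {
  # single isolated pixel is noise: eliminated by the first erosion
  lone <- matrix(0, 31, 31); lone[16, 16] <- 1
  expect_equal(sum(morphologicalCleanup(lone)), 0)

  # a solid square survives with nearly its original area
  sq <- matrix(0, 80, 80); sq[16:65, 21:70] <- 1
  cleaned <- morphologicalCleanup(sq)
  expect_lt(abs(sum(cleaned) - 2500) / 2500, 0.05)

  # an interior hole is filled by the closing step
  holed <- matrix(0, 20, 20); holed[5:15, 5:15] <- 1; holed[10, 10] <- 0
  cleaned <- morphologicalCleanup(holed)
  expect_equal(cleaned[10, 10], 1)

  # cleanup never reaches beyond the dilation + closing envelope
  set.seed(8)
  img <- matrix(rbinom(60 * 60, 1, 0.3), 60, 60)
  p <- morphologyParams()
  envelope <- binaryDilate(img, EBImage::makeBrush(
    2 * (p$dilateRadius + p$closeRadius) + 1, "disc"))
  expect_true(all(morphologicalCleanup(img, p) <= envelope))

  expect_error(morphologicalCleanup(matrix(1, 2, 2)), "larger than")
  expect_error(morphologyParams(erode1 = 4), "odd")
})

test_that("relative share divides by the full pixel count", {
  expect_equal(relativeShare(matrix(1, 10, 10)), 100)
  expect_equal(relativeShare(matrix(0, 10, 10)), 0)
  m <- matrix(0, 1004, 1008); m[1:25, 1:25] <- 1
  expect_equal(relativeShare(m), 100 * 625 / (1004 * 1008))
  expect_equal(round(relativeShare(m), 2), 0.06)
})

test_that("projected pixel size follows sensor pixel / magnification", {
  expect_equal(pixelSizeUm(20), 0.28)
  expect_equal(pixelSizeUm(10), 0.56)
  expect_equal(pixelSizeUm(2), 2.8)
  expect_equal(pixelSizeUm(2, sensorPixelUm = 11.2), 5.6)
  expect_error(pixelSizeUm(0), "positive")
})

test_that("particle measurement sizes connected components physically", {
  m <- matrix(0, 200, 200)
  m[50:74, 60:94] <- 1  # 25 x 35 px
  p <- measureParticles(m, pixelSizeUm(2))
  expect_equal(nrow(p), 1)
  expect_equal(p$height_um, 25 * 2.8)  # 70 um
  expect_equal(p$width_um, 35 * 2.8)   # 98 um
  expect_equal(p$area_px, 25 * 35)

  expect_equal(nrow(measureParticles(matrix(0, 5, 5), 2.8)), 0)

  two <- matrix(0, 40, 40)
  two[2:7, 2:7] <- 1; two[20:29, 20:34] <- 1
  p <- measureParticles(two, 0.56)
  expect_equal(nrow(p), 2)
  expect_equal(p$area_px, c(150, 36))  # sorted by decreasing area

  # diagonal touch: one particle 8-connected, two when 4-connected
  diagm <- matrix(0, 10, 10)
  diagm[2:4, 2:4] <- 1; diagm[5:7, 5:7] <- 1
  expect_equal(nrow(measureParticles(diagm, 1, connectivity = 8)), 1)
  expect_equal(nrow(measureParticles(diagm, 1, connectivity = 4)), 2)
})

test_that("classification recovers a synthetic two-material scene", {
  r <- renderStack(smallScene(), seed = 31)
  res <- classifyStack(r$stack, calibrationRanges())

  truthH <- trueShare(r$labels, 1)
  truthS <- trueShare(r$labels, 2)
  expect_lt(abs(shares(res)[["HDPE"]] - truthH), 2)
  expect_lt(abs(shares(res)[["Spruce"]] - truthS), 2)

  fH <- materialFit(res, "HDPE")
  fS <- materialFit(res, "Spruce")
  expect_lt(abs(fitMu(fH) - 3.52), 3 * 0.21 / sqrt(fitN(fH)))
  expect_lt(abs(fitMu(fS) - 1.40), 3 * 0.12 / sqrt(fitN(fS)))

  # disjoint windows give disjoint raw masks
  expect_equal(sum(rawMask(res, "HDPE") * rawMask(res, "Spruce")), 0)
  expect_equal(res@params$ambiguous_pixels, 0)

  s <- summary(res)
  expect_equal(s$material, c("HDPE", "Spruce"))
  expect_equal(s$share_percent, unname(shares(res)))
})

test_that("a background-only scene classifies to zero shares", {
  spec <- sceneSpec(dims = c(120, 120), regions = list(
    sceneRegion("rect", "HDPE", 50, 50, 11, 11)))
  r <- renderStack(spec, seed = 13)
  # hide the only bright object: background alone stays below the gate
  stk <- r$stack
  blank <- intensityLayer(stk)
  blank[r$labels == 1] <- 0
  stk2 <- FLIMStack(blank, phaseLayer(stk), modIndexLayer(stk),
                    tauPhaseLayer(stk), tauModLayer(stk), modFreq(stk),
                    magnification = magnification(stk))
  res <- classifyStack(stk2, calibrationRanges())
  expect_lt(shares(res)[["HDPE"]], 0.5)
  expect_equal(shares(res)[["Spruce"]], 0)
})

test_that("single-material scene share matches its area after cleanup", {
  spec <- sceneSpec(dims = c(150, 150), regions = list(
    sceneRegion("rect", "HDPE", 30, 30, 70, 90)))
  r <- renderStack(spec, seed = 17)
  res <- classifyStack(r$stack, calibrationRanges()["HDPE"])
  truth <- trueShare(r$labels, 1)
  expect_lt(abs(shares(res)[["HDPE"]] - truth) / truth, 0.05)
})

test_that("classification is deterministic given identical inputs", {
  r <- renderStack(smallScene(c(100, 110)), seed = 4)
  res1 <- classifyStack(r$stack, calibrationRanges())
  res2 <- classifyStack(r$stack, calibrationRanges())
  expect_identical(shares(res1), shares(res2))
  expect_identical(summary(res1), summary(res2))
})
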