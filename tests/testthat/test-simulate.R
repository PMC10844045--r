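test_that("label rendering rasterizes regions deterministically", {
  empty <- sceneSpec(dims = c(50, 60))
  expect_equal(sum(renderLabels(empty)), 0)

  full <- sceneSpec(dims = c(40, 40), regions = list(
    sceneRegion("rect", "HDPE", 1, 1, 40, 40)))
  expect_true(all(renderLabels(full) == 1))

  two <- sceneSpec(dims = c(60, 60), regions = list(
    sceneRegion("rect", "HDPE", 2, 2, 10, 12),
    sceneRegion("rect", "Spruce", 30, 30, 8, 9)))
  lab <- two |> renderLabels()
  expect_equal(sum(lab == 1), 120)
  expect_equal(sum(lab == 2), 72)
  expect_equal(attr(lab, "materials"), c("HDPE", "Spruce"))

  # later regions overwrite earlier ones
  overlap <- sceneSpec(dims = c(30, 30), regions = list(
    sceneRegion("rect", "HDPE", 1, 1, 20, 20),
    sceneRegion("rect", "Spruce", 10, 10, 20, 20)))
  lab <- renderLabels(overlap)
  expect_equal(sum(lab == 1), 400 - 121)
  expect_equal(sum(lab == 2), 400)

  expect_error(sceneSpec(dims = c(20, 20), regions = list(
    sceneRegion("rect", "HDPE", 15, 15, 10, 10))), "out of bounds")
})

test_that("rendered stacks are physically self-consistent", {
  r <- renderStack(smallScene(c(120, 130)), seed = 2)
  stk <- r$stack
  f <- modFreq(stk)
  fg <- r$labels > 0
  # tau layers re-derived from the raw phase/modulation layers match
  expect_equal(tauPhaseLayer(stk)[fg],
               phaseLifetime(phaseLayer(stk)[fg], f), tolerance = 1e-12)
  expect_equal(tauPhaseLayer(stk)[fg],
               modulationLifetime(modIndexLayer(stk)[fg], f),
               tolerance = 1e-9)
  # round trip through deriveLifetimeLayers reproduces the tau layers
  stk2 <- deriveLifetimeLayers(intensityLayer(stk), phaseLayer(stk),
                               modIndexLayer(stk), f)
  expect_equal(tauPhaseLayer(stk2), tauPhaseLayer(stk), tolerance = 1e-12)
  expect_equal(tauModLayer(stk2), tauModLayer(stk), tolerance = 1e-9)
})

test_that("per-material draws recover the generating parameters", {
  spec <- sceneSpec(dims = c(300, 300), regions = list(
    sceneRegion("rect", "HDPE", 11, 11, 280, 280)))
  r <- renderStack(spec, seed = 6)
  vals <- tauPhaseLayer(r$stack)[r$labels == 1]
  f <- gaussianFit(vals)
  se <- 0.21 / sqrt(length(vals))
  expect_lt(abs(fitMu(f) - 3.52), 3 * se)
  expect_lt(abs(fitSigma(f) - 0.21), 5 * se)

  # sigma = 0 material renders an exactly constant lifetime patch
  const <- list(Flat = materialModel("Flat", 2.5, 0, 500))
  spec0 <- sceneSpec(dims = c(40, 40), regions = list(
    sceneRegion("rect", "Flat", 5, 5, 20, 20)))
  r0 <- renderStack(spec0, materials = const, seed = 1)
  expect_equal(unique(tauPhaseLayer(r0$stack)[r0$labels == 1]), 2.5,
               tolerance = 1e-12)

  expect_error(renderStack(sceneSpec(dims = c(20, 20), regions = list(
    sceneRegion("rect", "Unobtainium", 1, 1, 5, 5))), seed = 1),
    "unknown material")
})

test_that("same seed reproduces the same scene bit for bit", {
  a <- renderStack(smallScene(c(90, 90)), seed = 123)
  b <- renderStack(smallScene(c(90, 90)), seed = 123)
  expect_identical(intensityLayer(a$stack), intensityLayer(b$stack))
  expect_identical(phaseLayer(a$stack), phaseLayer(b$stack))
  expect_identical(tauPhaseLayer(a$stack), tauPhaseLayer(b$stack))
  c <- renderStack(smallScene(c(90, 90)), seed = 124)
  expect_false(identical(intensityLayer(a$stack), intensityLayer(c$stack)))
})

test_that("foreground/background separation drives the intensity gate", {
  r <- renderStack(smallScene(c(160, 170)), seed = 9)
  gate <- intensityMask(r$stack, 0.10)
  fg <- r$labels > 0
  recall <- sum(gate[fg] == 1) / sum(fg)
  expect_gt(recall, 0.99)
  # background (soil) stays below the gate
  expect_equal(sum(gate[!fg]), 0)
})

test_that("synthetic spectra reproduce the material emission structure", {
  mats <- materialPresets("BP")
  pk <- findPeaks(renderSpectrum(mats$HDPE))
  expect_equal(pk$wavelength_nm, c(528, 594))
  expect_equal(pk$stokes_shift_nm, c(40, 106))

  grassBP <- applyFilter(renderSpectrum(mats$Grass), bandPass(495, 550))
  expect_equal(max(intensities(grassBP)), 0)

  dark <- materialModel("Dark", 1, 0.1, 10,
                        cbind(c(600), c(10), c(0)))
  expect_equal(max(intensities(renderSpectrum(dark))), 0)

  # seeded noise is reproducible
  s1 <- renderSpectrum(mats$Spruce, noiseSd = 0.02, seed = 77)
  s2 <- renderSpectrum(mats$Spruce, noiseSd = 0.02, seed = 77)
  expect_identical(intensities(s1), intensities(s2))
})

test_that("presets reference defined materials and stay in bounds", {
  for (nm in c("experiment3", "experiment4")) {
    spec <- scenePreset(nm)
    expect_s4_class(spec, "SceneSpec")
    expect_true(validObject(spec))
    expect_true(all(sceneMaterials(spec) %in%
                      names(materialPresets("BP"))))
  }
  expect_setequal(sceneMaterials(scenePreset("experiment3")),
                  c("HDPE", "Spruce", "Grass"))
})
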