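gaussPeak <- function(grid, center, width, amp = 1)
  amp * exp(-0.5 * ((grid - center) / width)^2)

test_that("background subtraction is pointwise with clamping at zero", {
  wl <- 400:700
  s <- Spectrum(wl, gaussPeak(wl, 550, 10) + 0.2)
  bg <- Spectrum(wl, rep(0.2, length(wl)))
  out <- subtractBackground(s, bg)
  expect_equal(intensities(out), gaussPeak(wl, 550, 10), tolerance = 1e-12)

  expect_equal(intensities(subtractBackground(s, s)),
               rep(0, length(wl)))
  # background exceeding the sample clamps to zero, not negative
  big <- Spectrum(wl, rep(10, length(wl)))
  expect_equal(intensities(subtractBackground(s, big)),
               rep(0, length(wl)))
  expect_error(subtractBackground(s, Spectrum(401:701, rep(0, 301))),
               "grid")
})

test_that("replicate averaging preserves peaks and reduces noise ~5x", {
  wl <- 450:650
  s0 <- Spectrum(wl, rep(0, length(wl)))
  s1 <- Spectrum(wl, rep(1, length(wl)))
  expect_equal(intensities(averageSpectra(list(s0, s1))),
               rep(0.5, length(wl)))
  expect_equal(intensities(averageSpectra(list(s1, s1, s1, s1, s1))),
               rep(1, length(wl)))
  expect_error(averageSpectra(list()), "at least one")

  set.seed(11)
  pure <- gaussPeak(wl, 563, 20)
  reps <- lapply(1:5, function(i)
    Spectrum(wl, pure + rnorm(length(wl), 0, 0.05)))
  avg <- averageSpectra(reps)
  # residual noise can move the 1 nm-grid argmax by a sample or two
  expect_lt(abs(wl[which.max(intensities(avg))] - 563), 3)
  residVar <- var(intensities(avg) - pure)
  expect_lt(residVar, 0.05^2 / 5 * 2)  # ~ sigma^2/5, generous factor 2
})

test_that("interpolation reproduces sample points and locates fine maxima", {
  ramp <- Spectrum(c(500, 510, 520), c(0, 1, 2))
  fine <- interpolateSpectrum(ramp, 0.01)
  expect_equal(wavelengths(fine)[1], 500)
  expect_equal(max(wavelengths(fine)), 520)
  expect_equal(intensities(fine),
               (wavelengths(fine) - 500) / 10, tolerance = 1e-9)
  # original sample points exact
  at510 <- which(abs(wavelengths(fine) - 510) < 1e-9)
  expect_equal(intensities(fine)[at510], 1)

  tri <- Spectrum(500:560, pmax(0, 1 - abs(500:560 - 528) / 10))
  fineTri <- interpolateSpectrum(tri, 0.01)
  peakWl <- wavelengths(fineTri)[which.max(intensities(fineTri))]
  expect_lt(abs(peakWl - 528), 0.011)
  expect_error(interpolateSpectrum(tri, -1), "positive")
  expect_error(interpolateSpectrum(Spectrum(500, 1), 0.01), "2 samples")
})

test_that("ideal filters apply boxcar transmission", {
  wl <- 200:1000
  grass <- Spectrum(wl, gaussPeak(wl, 700, 20))
  blocked <- applyFilter(grass, bandPass(495, 550))
  expect_equal(max(intensities(blocked)), 0)

  above <- Spectrum(550:800, gaussPeak(550:800, 650, 30))
  expect_equal(intensities(applyFilter(above, longPass(500))),
               intensities(above))

  hdpe <- Spectrum(wl, gaussPeak(wl, 528, 12, 0.8) +
                         gaussPeak(wl, 594, 18, 1.0))
  bp <- applyFilter(hdpe, bandPass(495, 550))
  pk <- findPeaks(bp)
  expect_equal(pk$wavelength_nm, 528)

  # a filter never increases intensity anywhere
  for (f in list(longPass(500), bandPass(495, 550), bandPass(600, 900))) {
    out <- applyFilter(hdpe, f)
    expect_true(all(intensities(out) <= intensities(hdpe) + 1e-15))
  }
  expect_error(bandPass(550, 495), "cuton")
})

test_that("peak finding resolves known maxima with Stokes shifts", {
  wl <- 200:1000
  spruce <- Spectrum(wl, gaussPeak(wl, 563, 25))
  pk <- findPeaks(spruce)
  expect_equal(pk$wavelength_nm, 563)
  expect_equal(pk$stokes_shift_nm, 75)

  expect_equal(nrow(findPeaks(Spectrum(wl, rep(1, length(wl))))), 0)
  expect_equal(nrow(findPeaks(Spectrum(wl, rep(0, length(wl))))), 0)

  grass <- Spectrum(wl, gaussPeak(wl, 691, 6, 1.0) +
                          gaussPeak(wl, 719, 6, 0.8) +
                          gaussPeak(wl, 741, 6, 0.6))
  pk <- findPeaks(grass)
  expect_equal(pk$wavelength_nm, c(691, 719, 741))
  expect_equal(pk$stokes_shift_nm, c(203, 231, 253))

  # BP-filtered peaks are a passband-restricted subset of the originals
  hdpe <- Spectrum(wl, gaussPeak(wl, 528, 12, 0.8) +
                         gaussPeak(wl, 594, 18))
  pkAll <- findPeaks(hdpe)$wavelength_nm
  pkBP <- findPeaks(applyFilter(hdpe, bandPass(495, 550)))$wavelength_nm
  expect_true(all(pkBP %in% pkAll))
  expect_true(all(pkBP >= 495 & pkBP <= 550))
})

test_that("Stokes shift subtracts the 488 nm excitation", {
  expect_equal(stokesShift(528), 40)
  expect_equal(stokesShift(594), 106)
  expect_equal(stokesShift(488), 0)
  expect_equal(stokesShift(c(691, 719, 741)), c(203, 231, 253))
  expect_error(stokesShift(450), "anti-Stokes")
})

test_that("normalization scales the peak to exactly 1 and is idempotent", {
  wl <- 500:600
  s <- Spectrum(wl, 5 * gaussPeak(wl, 550, 10))
  n1 <- normalizeSpectrum(s)
  expect_equal(max(intensities(n1)), 1)
  expect_equal(intensities(normalizeSpectrum(n1)), intensities(n1))
  expect_error(normalizeSpectrum(Spectrum(wl, rep(0, length(wl)))),
               "normalize")
})
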