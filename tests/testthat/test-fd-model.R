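test_that("phase lifetime follows tan(phi)/omega", {
  expect_equal(phaseLifetime(0, 30e6), 0)
  # tan(pi/4) = 1 => tau = 1/omega = 1/(2*pi*30e6) s = 5.305 ns
  expect_equal(phaseLifetime(pi / 4, 30e6), 1e9 / (2 * pi * 30e6),
               tolerance = 1e-12)
  expect_equal(phaseLifetime(pi / 4, 30e6), 5.305, tolerance = 1e-4)
  # frozen from the analytic inverse: phi = arctan(2*pi*30e6 * 3.75e-9)
  expect_equal(phaseLifetime(0.61531406652049492, 30e6), 3.75,
               tolerance = 1e-9)
  expect_error(phaseLifetime(pi / 2, 30e6), "invalid phase")
  expect_error(phaseLifetime(-0.1, 30e6), "invalid phase")
  expect_error(phaseLifetime(0.3, 0), "positive")
})

test_that("modulation index is the ratio of relative modulation depths", {
  expect_equal(modulationIndex(1, 1, 0.5, 1), 0.5)
  expect_equal(modulationIndex(80, 100, 20, 50), 0.5)
  expect_equal(modulationIndex(1, 1, 1, 1), 1.0)
  expect_error(modulationIndex(0, 1, 1, 1), "positive")
  expect_error(modulationIndex(1, 1, -2, 1), "positive")
  # emission more modulated than excitation is unphysical
  expect_error(modulationIndex(0.5, 1, 0.9, 1), "M > 1")
})

test_that("modulation lifetime follows sqrt(1/M^2 - 1)/omega", {
  expect_equal(modulationLifetime(1, 30e6), 0)
  expect_equal(modulationLifetime(1 / sqrt(2), 30e6),
               1e9 / (2 * pi * 30e6), tolerance = 1e-12)
  # frozen from the forward model M = 1/sqrt(1 + (omega tau)^2) at 3.75 ns
  expect_equal(modulationLifetime(0.81659220326587856, 30e6), 3.75,
               tolerance = 1e-9)
  expect_error(modulationLifetime(1.2, 30e6), "\\(0, 1\\]")
  expect_error(modulationLifetime(0, 30e6), "\\(0, 1\\]")
})

test_that("forward models invert the lifetime equations exactly", {
  expect_equal(lifetimeToPhase(0, 30e6), 0)
  expect_equal(lifetimeToPhase(3.75, 30e6), 0.615314, tolerance = 1e-5)
  expect_equal(lifetimeToModIndex(0, 17e6), 1.0)
  expect_equal(lifetimeToModIndex(3.75, 30e6), 0.8166, tolerance = 1e-4)
  expect_error(lifetimeToPhase(-1, 30e6), "non-negative")
  expect_error(lifetimeToModIndex(-1, 30e6), "non-negative")
  for (tau in c(0.5, 1.4, 3.52, 3.75, 17)) {
    for (f in c(10e6, 30e6, 80e6)) {
      expect_equal(phaseLifetime(lifetimeToPhase(tau, f), f), tau,
                   tolerance = 1e-9)
      expect_equal(modulationLifetime(lifetimeToModIndex(tau, f), f), tau,
                   tolerance = 1e-9)
    }
  }
})

test_that("two-component mixtures give apparent tau_PH <= tau_M", {
  set.seed(42)
  for (i in 1:50) {
    taus <- sort(runif(2, 0.2, 8))
    if (diff(taus) < 0.05) next
    fr <- runif(1, 0.05, 0.95)
    r <- mixedEmissionResponse(taus, c(fr, 1 - fr), 30e6)
    tauPH <- phaseLifetime(r$phaseShift, 30e6)
    tauM <- modulationLifetime(r$modIndex, 30e6)
    expect_lt(tauPH, tauM)
    # apparent lifetimes fall between the component lifetimes
    expect_gt(tauPH, taus[1] - 1e-9)
    expect_lt(tauM, taus[2] + 1e-9)
  }
  # a pure component collapses back to the single-exponential answer
  r <- mixedEmissionResponse(2.5, 1, 30e6)
  expect_equal(phaseLifetime(r$phaseShift, 30e6), 2.5, tolerance = 1e-9)
  expect_equal(modulationLifetime(r$modIndex, 30e6), 2.5, tolerance = 1e-9)
})

test_that("deriveLifetimeLayers fills lifetimes pixelwise, NA for invalid", {
  z <- matrix(0, 3, 4)
  stk <- deriveLifetimeLayers(z + 1, z, z + 1, 30e6)
  expect_equal(tauPhaseLayer(stk), z)
  expect_equal(tauModLayer(stk), z)

  ph <- matrix(pi / 4, 3, 4)
  stk <- deriveLifetimeLayers(z + 1, ph, z + 0.5, 30e6)
  expect_equal(tauPhaseLayer(stk),
               matrix(1e9 / (2 * pi * 30e6), 3, 4), tolerance = 1e-12)

  # non-physical phase / modulation become the NA sentinel, not clipped
  ph[1, 1] <- pi / 2 + 0.1
  M <- z + 0.5
  M[2, 2] <- 1.5
  stk <- deriveLifetimeLayers(z + 1, ph, M, 30e6)
  expect_true(is.na(tauPhaseLayer(stk)[1, 1]))
  expect_true(is.na(tauModLayer(stk)[2, 2]))
  expect_equal(sum(is.na(tauPhaseLayer(stk))), 1)

  expect_error(deriveLifetimeLayers(matrix(1, 2, 2), ph, M, 30e6),
               "share one shape")
})

test_that("FLIMStack validity rejects inconsistent layers", {
  z <- matrix(0.5, 2, 2)
  expect_error(FLIMStack(z, z, z, z, matrix(0, 3, 3), 30e6),
               "share one shape")
  expect_error(FLIMStack(z, matrix(2, 2, 2), z, z, z, 30e6), "phase")
  expect_error(FLIMStack(z, z, matrix(1.5, 2, 2), z, z, 30e6),
               "modulation index")
  expect_error(FLIMStack(z, z, z, z, z, -1), "modFreqHz")
  stk <- FLIMStack(z, z, z, z, z, 30e6, magnification = 20)
  expect_equal(dim(stk), c(2L, 2L))
  expect_equal(pixelSizeUm(stk), 0.28)
})
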