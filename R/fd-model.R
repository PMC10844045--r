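#' @include AllGenerics.R
NULL

## Angular modulation frequency from ordinary frequency in Hz.
.omega <- function(modFreqHz) 2 * pi * modFreqHz

.checkFreq <- function(modFreqHz) {
  if (length(modFreqHz) != 1 || !is.finite(modFreqHz) || modFreqHz <= 0)
    stop("modFreqHz must be a single positive frequency in Hz")
}

#' Phase-dependent fluorescence lifetime
#'
#' In frequency-domain fluorimetry a single-exponential emitter excited
#' with light modulated at angular frequency \eqn{\omega = 2\pi f}
#' emits fluorescence phase-shifted by \eqn{\varphi}, from which the
#' phase-dependent lifetime follows as
#' \deqn{\tau_{PH} = \tan(\varphi) / \omega.}
#'
#' @param phaseShift phase shift \eqn{\varphi} in radians; each value
#'   must lie in \eqn{[0, \pi/2)} (or be \code{NA}, which propagates).
#' @param modFreqHz modulation frequency \eqn{f} in Hz (scalar).
#' @return lifetime(s) in nanoseconds, same shape as \code{phaseShift}.
#' @examples
#' phaseLifetime(pi / 4, 30e6)               # 1/omega = 5.305 ns
#' phaseLifetime(lifetimeToPhase(3.75, 30e6), 30e6)  # round trip
#' @seealso [lifetimeToPhase()] for the inverse,
#'   [modulationLifetime()] for the demodulation route.
#' @export
phaseLifetime <- function(phaseShift, modFreqHz) {
  .checkFreq(modFreqHz)
  if (any(phaseShift < 0 | phaseShift >= pi / 2, na.rm = TRUE))
    stop("invalid phase: phase shift must lie in [0, pi/2) for a ",
         "single-exponential decay")
  tan(phaseShift) / .omega(modFreqHz) * 1e9
}

#' Modulation index of a frequency-domain signal
#'
#' The emission of a modulated excitation \eqn{B\sin(\omega t) + A} is
#' amplitude-damped to \eqn{b} around its own offset \eqn{a}; the
#' modulation index is the ratio of the relative modulation depths,
#' \deqn{M = (b/a) / (B/A).}
#'
#' @param excAmplitude,excOffset excitation amplitude \eqn{B} and
#'   offset \eqn{A} (a.u., positive).
#' @param emAmplitude,emOffset emission amplitude \eqn{b} and offset
#'   \eqn{a} (a.u., positive).
#' @return modulation index in \eqn{(0, 1]} for physical signals.
#' @examples
#' modulationIndex(1, 1, 0.5, 1)     # 0.5
#' modulationIndex(80, 100, 20, 50)  # 0.5
#' @export
modulationIndex <- function(excAmplitude, excOffset, emAmplitude, emOffset) {
  vals <- c(excAmplitude, excOffset, emAmplitude, emOffset)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all four signal components must be strictly positive")
  M <- (emAmplitude / emOffset) / (excAmplitude / excOffset)
  if (any(M > 1 + 1e-12))
    stop("emission cannot be more modulated than the excitation (M > 1)")
  pmin(M, 1)
}

#' Modulation-dependent fluorescence lifetime
#'
#' From the modulation index \eqn{M} of a single-exponential emitter
#' the lifetime follows as
#' \deqn{\tau_M = \sqrt{1/M^2 - 1} / \omega.}
#'
#' @param modIndex modulation index in \eqn{(0, 1]} (or \code{NA},
#'   which propagates).
#' @param modFreqHz modulation frequency \eqn{f} in Hz (scalar).
#' @return lifetime(s) in nanoseconds.
#' @examples
#' modulationLifetime(1 / sqrt(2), 30e6)  # 5.305 ns
#' modulationLifetime(1, 30e6)            # 0: undamped signal
#' @export
modulationLifetime <- function(modIndex, modFreqHz) {
  .checkFreq(modFreqHz)
  if (any(modIndex <= 0 | modIndex > 1, na.rm = TRUE))
    stop("modulation index must lie in (0, 1]")
  sqrt(pmax(1 / modIndex^2 - 1, 0)) / .omega(modFreqHz) * 1e9
}

#' Phase shift of a single-exponential emitter (inverse model)
#'
#' Analytic inverse of [phaseLifetime()]:
#' \eqn{\varphi = \arctan(\omega\tau)}. Used by the scene simulator to
#' build self-consistent raw layers from a drawn lifetime map.
#'
#' @param lifetimeNs lifetime(s) in ns, non-negative.
#' @param modFreqHz modulation frequency in Hz (scalar).
#' @return phase shift(s) in radians, in \eqn{[0, \pi/2)}.
#' @examples
#' lifetimeToPhase(3.75, 30e6)  # 0.61548 rad
#' @export
lifetimeToPhase <- function(lifetimeNs, modFreqHz) {
  .checkFreq(modFreqHz)
  if (any(lifetimeNs < 0, na.rm = TRUE))
    stop("lifetime must be non-negative")
  atan(.omega(modFreqHz) * lifetimeNs * 1e-9)
}

#' Modulation index of a single-exponential emitter (forward model)
#'
#' Single-exponential forward model consistent with
#' [modulationLifetime()]: \eqn{M = 1/\sqrt{1 + (\omega\tau)^2}}.
#'
#' @inheritParams lifetimeToPhase
#' @return modulation index(es) in \eqn{(0, 1]}.
#' @examples
#' lifetimeToModIndex(0, 30e6)     # 1
#' lifetimeToModIndex(3.75, 30e6)  # 0.8166
#' @export
lifetimeToModIndex <- function(lifetimeNs, modFreqHz) {
  .checkFreq(modFreqHz)
  if (any(lifetimeNs < 0, na.rm = TRUE))
    stop("lifetime must be non-negative")
  1 / sqrt(1 + (.omega(modFreqHz) * lifetimeNs * 1e-9)^2)
}

#' Apparent phase and modulation of a multi-component emitter
#'
#' For a pixel whose signal mixes several single-exponential components
#' with lifetimes \eqn{\tau_i} and fractional steady-state intensities
#' \eqn{f_i}, the components add as phasors:
#' \eqn{g = \sum f_i / (1 + (\omega\tau_i)^2)},
#' \eqn{s = \sum f_i \omega\tau_i / (1 + (\omega\tau_i)^2)},
#' giving the apparent \eqn{\varphi = \arctan(s/g)} and
#' \eqn{M = \sqrt{g^2 + s^2}}. For heterogeneous mixtures the apparent
#' phase lifetime is systematically below the apparent modulation
#' lifetime.
#'
#' @param lifetimesNs component lifetimes in ns.
#' @param fractions fractional intensities, summing to 1 (normalized if
#'   not).
#' @param modFreqHz modulation frequency in Hz.
#' @return list with elements \code{phaseShift} (rad) and
#'   \code{modIndex}.
#' @examples
#' r <- mixedEmissionResponse(c(1.4, 3.52), c(0.5, 0.5), 30e6)
#' phaseLifetime(r$phaseShift, 30e6) <= modulationLifetime(r$modIndex, 30e6)
#' @export
mixedEmissionResponse <- function(lifetimesNs, fractions, modFreqHz) {
  .checkFreq(modFreqHz)
  if (length(lifetimesNs) != length(fractions) || length(fractions) < 1)
    stop("lifetimesNs and fractions must be equal-length, non-empty")
  if (any(lifetimesNs < 0) || any(fractions < 0) || sum(fractions) <= 0)
    stop("lifetimes and fractions must be non-negative, fractions not all zero")
  f <- fractions / sum(fractions)
  wt <- .omega(modFreqHz) * lifetimesNs * 1e-9
  g <- sum(f / (1 + wt^2))
  s <- sum(f * wt / (1 + wt^2))
  list(phaseShift = atan2(s, g), modIndex = sqrt(g^2 + s^2))
}

#' Construct a FLIMStack from its five layers
#'
#' Low-level constructor; layers are validated against the class
#' invariants. Use [deriveLifetimeLayers()] to build the lifetime
#' layers from raw measured layers.
#'
#' @param intensity,phase,modIndex,tauPhase,tauMod the five layers as
#'   equal-shape numeric matrices (phase in radians, lifetimes in ns).
#' @param modFreqHz modulation frequency in Hz.
#' @param magnification objective magnification factor.
#' @param sensorPixelUm detector pixel edge in micrometres.
#' @param exposureMs exposure time in ms (optional).
#' @param emissionFilter emission-filter descriptor string.
#' @return a validated [FLIMStack-class] object.
#' @export
FLIMStack <- function(intensity, phase, modIndex, tauPhase, tauMod,
                      modFreqHz, magnification = 10, sensorPixelUm = 5.6,
                      exposureMs = NA_real_, emissionFilter = "none") {
  new("FLIMStack", intensity = intensity, phase = phase,
      modIndex = modIndex, tauPhase = tauPhase, tauMod = tauMod,
      modFreqHz = as.numeric(modFreqHz),
      magnification = as.numeric(magnification),
      sensorPixelUm = as.numeric(sensorPixelUm),
      exposureMs = as.numeric(exposureMs),
      emissionFilter = emissionFilter)
}

#' Derive the lifetime layers of a stack from raw measured layers
#'
#' Applies the phase and modulation lifetime equations pixelwise to the
#' measured phase-shift and modulation-index layers. Pixels with a
#' non-physical phase (outside \eqn{[0, \pi/2)}) or modulation index
#' (outside \eqn{(0, 1]}) are set to the \code{NA} invalid-pixel
#' sentinel in all affected layers rather than clipped.
#'
#' @param intensity,phase,modIndex raw layers (equal-shape numeric
#'   matrices; phase in radians).
#' @inheritParams FLIMStack
#' @return a [FLIMStack-class] with \code{tauPhase} and \code{tauMod}
#'   filled in.
#' @examples
#' ph <- matrix(pi / 4, 2, 2)
#' stk <- deriveLifetimeLayers(matrix(1, 2, 2), ph, matrix(0.7, 2, 2), 30e6)
#' tauPhaseLayer(stk)  # uniform 5.305 ns
#' @export
deriveLifetimeLayers <- function(intensity, phase, modIndex, modFreqHz,
                                 magnification = 10, sensorPixelUm = 5.6,
                                 exposureMs = NA_real_,
                                 emissionFilter = "none") {
  if (!identical(dim(intensity), dim(phase)) ||
      !identical(dim(intensity), dim(modIndex)))
    stop("intensity, phase and modIndex layers must share one shape")
  .checkFreq(modFreqHz)
  ph <- phase
  ph[!is.na(ph) & (ph < 0 | ph >= pi / 2)] <- NA_real_
  M <- modIndex
  M[!is.na(M) & (M <= 0 | M > 1)] <- NA_real_
  tauP <- tan(ph) / .omega(modFreqHz) * 1e9
  tauM <- sqrt(pmax(1 / M^2 - 1, 0)) / .omega(modFreqHz) * 1e9
  FLIMStack(intensity = intensity, phase = ph, modIndex = M,
            tauPhase = tauP, tauMod = tauM, modFreqHz = modFreqHz,
            magnification = magnification, sensorPixelUm = sensorPixelUm,
            exposureMs = exposureMs, emissionFilter = emissionFilter)
}

## ---- methods -------------------------------------------------------

#' @rdname FLIMStack-accessors
setMethod("intensityLayer", "FLIMStack", function(x) x@intensity)
#' @rdname FLIMStack-accessors
setMethod("phaseLayer", "FLIMStack", function(x) x@phase)
#' @rdname FLIMStack-accessors
setMethod("modIndexLayer", "FLIMStack", function(x) x@modIndex)
#' @rdname FLIMStack-accessors
setMethod("tauPhaseLayer", "FLIMStack", function(x) x@tauPhase)
#' @rdname FLIMStack-accessors
setMethod("tauModLayer", "FLIMStack", function(x) x@tauMod)
#' @rdname FLIMStack-accessors
setMethod("modFreq", "FLIMStack", function(x) x@modFreqHz)
#' @rdname FLIMStack-accessors
setMethod("magnification", "FLIMStack", function(x) x@magnification)
#' @rdname FLIMStack-accessors
setMethod("emissionFilter", "FLIMStack", function(x) x@emissionFilter)

#' @describeIn FLIMStack-class image dimensions \code{c(rows, cols)}.
#' @param x a \code{FLIMStack}.
#' @export
setMethod("dim", "FLIMStack", function(x) dim(x@intensity))

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "numeric", function(x, ...) {
  args <- list(...)
  sensorPixelUm <- if (is.null(args$sensorPixelUm)) 5.6 else args$sensorPixelUm
  if (any(x <= 0)) stop("magnification must be positive")
  sensorPixelUm / x
})

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "FLIMStack", function(x, ...) {
  x@sensorPixelUm / x@magnification
})

setMethod("show", "FLIMStack", function(object) {
  d <- dim(object)
  cat(sprintf("FLIMStack: %d x %d pixels, 5 layers\n", d[1], d[2]))
  cat(sprintf("  modulation frequency: %.3g MHz\n", object@modFreqHz / 1e6))
  cat(sprintf("  magnification: %gx (pixel %.3g um)\n",
              object@magnification, pixelSizeUm(object)))
  cat(sprintf("  emission filter: %s\n", object@emissionFilter))
  tp <- object@tauPhase
  nValid <- sum(!is.na(tp))
  cat(sprintf("  tau_phase: %d valid pixels", nValid))
  if (nValid)
    cat(sprintf(", range %.3g-%.3g ns", min(tp, na.rm = TRUE),
                max(tp, na.rm = TRUE)))
  cat("\n")
})
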