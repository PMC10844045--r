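#' @include flimsort-package.R
NULL

## Canonical layer names, in the order the instrument writes them.
.LAYER_ORDER <- c("intensity", "phase", "mod_index", "tau_phase", "tau_mod")

.checkLayer <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    return(sprintf("layer '%s' must be a numeric matrix", name))
  NULL
}

#' FLIMStack: a five-layer frequency-domain FLIM image
#'
#' The central data container of the package. A frequency-domain FLIM
#' camera measurement yields, per pixel, the fluorescence intensity
#' \eqn{I}, the phase shift \eqn{\varphi} of the harmonic emission
#' relative to the modulated excitation, the modulation index \eqn{M},
#' and the two derived lifetimes: the phase-dependent lifetime
#' \eqn{\tau_{PH} = \tan(\varphi)/\omega} and the modulation-dependent
#' lifetime \eqn{\tau_M = \sqrt{1/M^2 - 1}/\omega}, with
#' \eqn{\omega = 2\pi f} the angular modulation frequency.
#'
#' Pixels where no physical lifetime exists (phase outside
#' \eqn{[0, \pi/2)}, modulation index outside \eqn{(0, 1]}) carry
#' \code{NA}, the package-wide invalid-pixel sentinel, and are excluded
#' from all downstream statistics.
#'
#' @slot intensity numeric matrix, photon-count-proportional intensity
#'   (arbitrary units, non-negative).
#' @slot phase numeric matrix, phase shift in radians, in
#'   \eqn{[0, \pi/2)} where valid.
#' @slot modIndex numeric matrix, modulation index in \eqn{[0, 1]}
#'   where valid.
#' @slot tauPhase,tauMod numeric matrices, lifetimes in nanoseconds,
#'   non-negative where valid.
#' @slot modFreqHz modulation frequency \eqn{f} in Hz.
#' @slot magnification optical magnification factor of the objective.
#' @slot sensorPixelUm physical edge length of a detector pixel in
#'   micrometres.
#' @slot exposureMs exposure time in milliseconds (\code{NA} if unknown).
#' @slot emissionFilter free-text descriptor of the emission filter in
#'   place during acquisition (e.g. \code{"BP495-550"}, \code{"LP500"},
#'   \code{"none"}).
#'
#' @seealso [FLIMStack()] for construction, [deriveLifetimeLayers()] to
#'   build a stack from raw measured layers, [readStack()] /
#'   [writeStack()] for TIFF I/O.
#' @name FLIMStack-class
#' @aliases FLIMStack-class
#' @exportClass FLIMStack
setClass("FLIMStack",
  slots = c(
    intensity      = "matrix",
    phase          = "matrix",
    modIndex       = "matrix",
    tauPhase       = "matrix",
    tauMod         = "matrix",
    modFreqHz      = "numeric",
    magnification  = "numeric",
    sensorPixelUm  = "numeric",
    exposureMs     = "numeric",
    emissionFilter = "character"
  ),
  prototype = prototype(
    modFreqHz = 30e6, magnification = 10, sensorPixelUm = 5.6,
    exposureMs = NA_real_, emissionFilter = "none"
  )
)

setValidity("FLIMStack", function(object) {
  msgs <- character()
  layers <- list(intensity = object@intensity, phase = object@phase,
                 mod_index = object@modIndex, tau_phase = object@tauPhase,
                 tau_mod = object@tauMod)
  for (nm in names(layers)) {
    m <- .checkLayer(layers[[nm]], nm)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (length(msgs) == 0) {
    dims <- vapply(layers, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      msgs <- c(msgs, "all five layers must share one shape")
    if (any(object@intensity < 0, na.rm = TRUE))
      msgs <- c(msgs, "intensity must be non-negative")
    ph <- object@phase
    if (any(ph < 0 | ph >= pi / 2, na.rm = TRUE))
      msgs <- c(msgs, "phase must lie in [0, pi/2) or be NA")
    M <- object@modIndex
    if (any(M < 0 | M > 1, na.rm = TRUE))
      msgs <- c(msgs, "modulation index must lie in [0, 1] or be NA")
    if (any(object@tauPhase < 0, na.rm = TRUE) ||
        any(object@tauMod < 0, na.rm = TRUE))
      msgs <- c(msgs, "lifetimes must be non-negative or NA")
  }
  if (length(object@modFreqHz) != 1 || !is.finite(object@modFreqHz) ||
      object@modFreqHz <= 0)
    msgs <- c(msgs, "modFreqHz must be a single positive number")
  if (length(object@magnification) != 1 || object@magnification <= 0)
    msgs <- c(msgs, "magnification must be a single positive number")
  if (length(object@sensorPixelUm) != 1 || object@sensorPixelUm <= 0)
    msgs <- c(msgs, "sensorPixelUm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Spectrum: a fluorescence emission spectrum
#'
#' Wavelength/intensity series as produced by a CCD spectrometer, with a
#' record of any optical filter model already applied to it.
#'
#' @slot wavelengthNm strictly increasing wavelengths in nanometres.
#' @slot intensity intensities in arbitrary units, same length.
#' @slot filterApplied descriptor of the filter model applied
#'   (\code{"none"} for raw spectra).
#' @seealso [Spectrum()], [applyFilter()], [findPeaks()]
#' @name Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(wavelengthNm = "numeric", intensity = "numeric",
            filterApplied = "character"),
  prototype = prototype(filterApplied = "none")
)

setValidity("Spectrum", function(object) {
  msgs <- character()
  if (length(object@wavelengthNm) != length(object@intensity))
    msgs <- c(msgs, "wavelength and intensity must have equal length")
  if (length(object@wavelengthNm) >= 2 &&
      any(diff(object@wavelengthNm) <= 0))
    msgs <- c(msgs, "wavelengths must be strictly increasing")
  if (anyNA(object@wavelengthNm))
    msgs <- c(msgs, "wavelengths must not contain NA")
  if (length(object@filterApplied) != 1)
    msgs <- c(msgs, "filterApplied must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' OpticalFilter: ideal long-pass or band-pass emission filter
#'
#' Ideal boxcar transmission model: a long-pass (LP) filter transmits
#' everything at or above its cut-on wavelength; a band-pass (BP)
#' filter transmits only between cut-on and cut-off.
#'
#' @slot kind \code{"LP"} or \code{"BP"}.
#' @slot cutonNm cut-on wavelength in nm.
#' @slot cutoffNm cut-off wavelength in nm (\code{NA} for LP).
#' @seealso [longPass()], [bandPass()], [applyFilter()]
#' @name OpticalFilter-class
#' @exportClass OpticalFilter
setClass("OpticalFilter",
  slots = c(kind = "character", cutonNm = "numeric", cutoffNm = "numeric"))

setValidity("OpticalFilter", function(object) {
  msgs <- character()
  if (!object@kind %in% c("LP", "BP"))
    msgs <- c(msgs, "kind must be 'LP' or 'BP'")
  if (length(object@cutonNm) != 1 || !is.finite(object@cutonNm) ||
      object@cutonNm <= 0)
    msgs <- c(msgs, "cutonNm must be a single positive number")
  if (object@kind == "BP") {
    if (length(object@cutoffNm) != 1 || !is.finite(object@cutoffNm))
      msgs <- c(msgs, "BP filter requires a finite cutoffNm")
    else if (object@cutoffNm <= object@cutonNm)
      msgs <- c(msgs, "BP filter requires cutonNm < cutoffNm")
  }
  if (length(msgs)) msgs else TRUE
})

#' GaussianFit: Gaussian characterization of a lifetime population
#'
#' Expectation value and standard deviation of the per-pixel lifetimes
#' of one material, as estimated by [gaussianFit()].
#'
#' @slot mu expectation value in ns.
#' @slot sigma standard deviation in ns.
#' @slot n number of contributing (valid) pixels; may be \code{NA} for
#'   fits loaded from a material database.
#' @seealso [gaussianFit()], [materialRange()]
#' @name GaussianFit-class
#' @exportClass GaussianFit
setClass("GaussianFit",
  slots = c(mu = "numeric", sigma = "numeric", n = "numeric"))

setValidity("GaussianFit", function(object) {
  msgs <- character()
  if (length(object@mu) != 1 || !is.finite(object@mu))
    msgs <- c(msgs, "mu must be a single finite number")
  if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
      object@sigma < 0)
    msgs <- c(msgs, "sigma must be a single non-negative number")
  if (length(object@n) != 1 || (!is.na(object@n) && object@n < 1))
    msgs <- c(msgs, "n must be a single count >= 1 (or NA)")
  if (length(msgs)) msgs else TRUE
})

#' MaterialRange: a lifetime acceptance window for one material
#'
#' A named closed interval \eqn{[\mu - k\sigma, \mu + k\sigma]} of
#' phase-dependent lifetimes within which a pixel is attributed to the
#' material. The multiplier defaults to \eqn{k = 3}, the convention
#' used to define the HDPE and spruce windows from single-material
#' calibration measurements.
#'
#' @slot name material label (e.g. \code{"HDPE"}).
#' @slot lo,hi interval bounds in ns, \code{lo < hi}.
#' @slot k the sigma multiplier used to derive the bounds.
#' @slot fit the source [GaussianFit-class] object.
#' @seealso [materialRange()], [extractRange()], [classifyStack()]
#' @name MaterialRange-class
#' @exportClass MaterialRange
setClass("MaterialRange",
  slots = c(name = "character", lo = "numeric", hi = "numeric",
            k = "numeric", fit = "GaussianFit"))

setValidity("MaterialRange", function(object) {
  msgs <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  if (length(object@lo) != 1 || length(object@hi) != 1 ||
      !is.finite(object@lo) || !is.finite(object@hi))
    msgs <- c(msgs, "lo and hi must be single finite numbers")
  else if (object@lo >= object@hi)
    msgs <- c(msgs, "degenerate range: lo must be strictly below hi")
  if (length(msgs)) msgs else TRUE
})

#' MaterialModel: generative model of one material for the simulator
#'
#' Describes a material as the scene simulator sees it: a Gaussian
#' per-pixel lifetime distribution, a mean fluorescence intensity, and
#' a set of Gaussian emission peaks for spectrum synthesis.
#'
#' @slot name material label.
#' @slot tauMuNs,tauSigmaNs lifetime distribution parameters in ns.
#' @slot meanIntensity mean fluorescence intensity (arbitrary units).
#' @slot emissionPeaks numeric matrix with columns \code{center_nm},
#'   \code{width_nm}, \code{amplitude}; zero rows allowed (dark
#'   material).
#' @seealso [materialModel()], [materialPresets()], [renderStack()],
#'   [renderSpectrum()]
#' @name MaterialModel-class
#' @exportClass MaterialModel
setClass("MaterialModel",
  slots = c(name = "character", tauMuNs = "numeric",
            tauSigmaNs = "numeric", meanIntensity = "numeric",
            emissionPeaks = "matrix"))

setValidity("MaterialModel", function(object) {
  msgs <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  if (length(object@tauMuNs) != 1 || object@tauMuNs <= 0)
    msgs <- c(msgs, "tauMuNs must be a single positive number")
  if (length(object@tauSigmaNs) != 1 || object@tauSigmaNs < 0)
    msgs <- c(msgs, "tauSigmaNs must be a single non-negative number")
  if (length(object@meanIntensity) != 1 || object@meanIntensity <= 0)
    msgs <- c(msgs, "meanIntensity must be a single positive number")
  if (ncol(object@emissionPeaks) != 3)
    msgs <- c(msgs, "emissionPeaks must have 3 columns (center, width, amplitude)")
  if (length(msgs)) msgs else TRUE
})

#' SceneSpec: layout of a synthetic multi-material scene
#'
#' Defines the geometry of a simulated sample: image shape, a list of
#' placed material regions (rectangles or ellipses; later regions
#' overwrite earlier ones), and a soil-like background model with low
#' intensity and broadly distributed lifetimes.
#'
#' @slot dims integer vector \code{c(n_rows, n_cols)}.
#' @slot regions list of region descriptors as built by
#'   [sceneRegion()].
#' @slot background list with elements \code{intensity_fraction}
#'   (background intensity ceiling as a fraction of the maximum
#'   foreground mean intensity, in \eqn{[0, 1)}) and \code{tau_range_ns}
#'   (uniform lifetime range).
#' @slot seed default random seed used by [renderStack()] when none is
#'   given (\code{NA} = unseeded).
#' @seealso [sceneSpec()], [scenePreset()], [renderLabels()],
#'   [renderStack()]
#' @name SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec",
  slots = c(dims = "integer", regions = "list", background = "list",
            seed = "numeric"))

setValidity("SceneSpec", function(object) {
  msgs <- character()
  if (length(object@dims) != 2 || any(object@dims < 1))
    msgs <- c(msgs, "dims must be two positive integers")
  bf <- object@background$intensity_fraction
  if (is.null(bf) || length(bf) != 1 || bf < 0 || bf >= 1)
    msgs <- c(msgs, "background intensity_fraction must lie in [0, 1)")
  tr <- object@background$tau_range_ns
  if (is.null(tr) || length(tr) != 2 || tr[1] < 0 || tr[2] <= tr[1])
    msgs <- c(msgs, "background tau_range_ns must be an increasing pair >= 0")
  for (r in object@regions) {
    if (!all(c("shape", "material", "row", "col", "height", "width")
             %in% names(r))) {
      msgs <- c(msgs, "each region needs shape/material/row/col/height/width")
      next
    }
    if (r$row < 1 || r$col < 1 ||
        r$row + r$height - 1 > object@dims[1] ||
        r$col + r$width - 1 > object@dims[2])
      msgs <- c(msgs, sprintf("region '%s' extends out of bounds", r$material))
  }
  if (length(msgs)) msgs else TRUE
})

#' ClassificationResult: output of the multi-material pipeline
#'
#' Holds, per material, the raw lifetime-range mask, the
#' morphologically cleaned mask, the relative share of image pixels,
#' the Gaussian lifetime statistics of the classified pixels, and the
#' particle measurements; plus the intensity-gated lifetime image and
#' the parameters of the run.
#'
#' @slot ranges named list of [MaterialRange-class] objects.
#' @slot rawMasks,cleanMasks named lists of 0/1 matrices.
#' @slot shares named numeric vector, percent of all image pixels.
#' @slot fits named list of [GaussianFit-class] objects (\code{NULL}
#'   entries where no pixels were classified).
#' @slot particles named list of particle-measurement data frames.
#' @slot tauImage the intensity-gated phase-lifetime image (ns, with
#'   \code{NA} at gated-out pixels).
#' @slot params list of run parameters (threshold, morphology sizes,
#'   connectivity, pixel size).
#' @seealso [classifyStack()], [shares()], [particleTable()]
#' @name ClassificationResult-class
#' @exportClass ClassificationResult
setClass("ClassificationResult",
  slots = c(ranges = "list", rawMasks = "list", cleanMasks = "list",
            shares = "numeric", fits = "list", particles = "list",
            tauImage = "matrix", params = "list"))

setValidity("ClassificationResult", function(object) {
  msgs <- character()
  nm <- names(object@ranges)
  for (s in list(object@rawMasks, object@cleanMasks, object@fits,
                 object@particles)) {
    if (!identical(names(s), nm))
      msgs <- c(msgs, "per-material lists must share the material names")
  }
  if (any(object@shares < 0 | object@shares > 100))
    msgs <- c(msgs, "relative shares must lie in [0, 100]")
  if (length(msgs)) msgs else TRUE
})
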