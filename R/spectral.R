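#' @include AllGenerics.R
NULL

#' Construct a Spectrum
#'
#' @param wavelengthNm strictly increasing wavelengths in nm.
#' @param intensity intensities (a.u.), same length.
#' @param filterApplied filter descriptor; \code{"none"} for raw data.
#' @return a [Spectrum-class] object.
#' @examples
#' Spectrum(500:600, dnorm(500:600, 550, 10))
#' @export
Spectrum <- function(wavelengthNm, intensity, filterApplied = "none") {
  new("Spectrum", wavelengthNm = as.numeric(wavelengthNm),
      intensity = as.numeric(intensity), filterApplied = filterApplied)
}

#' @describeIn Spectrum-class wavelengths in nm.
#' @param x a \code{Spectrum}.
#' @export
wavelengths <- function(x) x@wavelengthNm

#' @describeIn Spectrum-class intensities (a.u.).
#' @export
intensities <- function(x) x@intensity

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelengthNm)
  cat(sprintf("Spectrum: %d samples, %.4g-%.4g nm, filter: %s\n", n,
              if (n) min(object@wavelengthNm) else NA,
              if (n) max(object@wavelengthNm) else NA,
              object@filterApplied))
})

#' @describeIn Spectrum-class number of samples.
#' @export
setMethod("length", "Spectrum", function(x) length(x@wavelengthNm))

#' Ideal long-pass emission filter
#'
#' @param cutonNm cut-on wavelength in nm; all light at or above it is
#'   transmitted, everything below is blocked.
#' @return an [OpticalFilter-class] object.
#' @examples
#' longPass(500)
#' @export
longPass <- function(cutonNm) {
  new("OpticalFilter", kind = "LP", cutonNm = as.numeric(cutonNm),
      cutoffNm = NA_real_)
}

#' Ideal band-pass emission filter
#'
#' @param cutonNm,cutoffNm passband limits in nm; light is transmitted
#'   only on the closed interval between them.
#' @return an [OpticalFilter-class] object.
#' @examples
#' bandPass(495, 550)
#' @export
bandPass <- function(cutonNm, cutoffNm) {
  new("OpticalFilter", kind = "BP", cutonNm = as.numeric(cutonNm),
      cutoffNm = as.numeric(cutoffNm))
}

setMethod("show", "OpticalFilter", function(object) {
  if (object@kind == "LP")
    cat(sprintf("Ideal LP filter, cut-on %g nm\n", object@cutonNm))
  else
    cat(sprintf("Ideal BP filter, %g-%g nm\n", object@cutonNm,
                object@cutoffNm))
})

.filterLabel <- function(f) {
  if (f@kind == "LP") sprintf("LP%g", f@cutonNm)
  else sprintf("BP%g-%g", f@cutonNm, f@cutoffNm)
}

.sameGrid <- function(a, b) {
  length(a@wavelengthNm) == length(b@wavelengthNm) &&
    all(a@wavelengthNm == b@wavelengthNm)
}

#' Subtract a background spectrum
#'
#' Pointwise subtraction of a background (e.g. dark/air) measurement
#' from a sample spectrum, on an identical wavelength grid. Negative
#' differences are clamped to zero, since negative fluorescence
#' intensities are unphysical.
#'
#' @param sample,background [Spectrum-class] objects on the same grid.
#' @return the background-corrected [Spectrum-class].
#' @export
subtractBackground <- function(sample, background) {
  if (!.sameGrid(sample, background))
    stop("sample and background must share an identical wavelength grid")
  Spectrum(sample@wavelengthNm,
           pmax(sample@intensity - background@intensity, 0),
           filterApplied = sample@filterApplied)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate measurements on a common
#' wavelength grid (the acquisition protocol measures five sites per
#' material).
#'
#' @param replicates non-empty list of [Spectrum-class] objects sharing
#'   one grid.
#' @return the mean [Spectrum-class].
#' @export
averageSpectra <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0)
    stop("need at least one replicate spectrum")
  ref <- replicates[[1]]
  for (s in replicates)
    if (!.sameGrid(ref, s))
      stop("all replicates must share an identical wavelength grid")
  mats <- vapply(replicates, intensities, numeric(length(ref)))
  Spectrum(ref@wavelengthNm, rowMeans(as.matrix(mats)),
           filterApplied = ref@filterApplied)
}

#' Resample a spectrum on a fine uniform grid
#'
#' Interpolates onto a uniform grid of the given step covering the
#' original wavelength range. Piecewise-linear interpolation is the
#' default (monotone, no overshoot); natural cubic splines are
#' available via \code{method = "cubic"}. Original sample points are
#' reproduced exactly by both methods.
#'
#' @param s a [Spectrum-class] with at least 2 samples.
#' @param stepNm interpolation step in nm (default 0.01).
#' @param method \code{"linear"} (default) or \code{"cubic"}.
#' @return the interpolated [Spectrum-class].
#' @export
interpolateSpectrum <- function(s, stepNm = 0.01,
                                method = c("linear", "cubic")) {
  method <- match.arg(method)
  if (!is.numeric(stepNm) || length(stepNm) != 1 || stepNm <= 0)
    stop("stepNm must be a single positive number")
  wl <- s@wavelengthNm
  if (length(wl) < 2) stop("need at least 2 samples to interpolate")
  grid <- seq(wl[1], wl[length(wl)], by = stepNm)
  ## keep the true endpoint even when the range is not a multiple of step
  if (grid[length(grid)] < wl[length(wl)])
    grid <- c(grid, wl[length(wl)])
  y <- if (method == "linear")
    approx(wl, s@intensity, xout = grid)$y
  else
    spline(wl, s@intensity, xout = grid, method = "natural")$y
  Spectrum(grid, y, filterApplied = s@filterApplied)
}

#' Apply an ideal optical filter to a spectrum
#'
#' Boxcar transmission: an LP filter zeroes all intensity below its
#' cut-on; a BP filter zeroes everything outside the closed
#' \code{[cuton, cutoff]} passband. Intensities inside the passband are
#' unchanged.
#'
#' @param s a [Spectrum-class].
#' @param f an [OpticalFilter-class].
#' @return the filtered [Spectrum-class], with \code{filterApplied} set
#'   to the filter descriptor.
#' @examples
#' s <- Spectrum(400:800, dnorm(400:800, 700, 10))
#' max(intensities(applyFilter(s, bandPass(495, 550))))  # 0: blocked
#' @export
applyFilter <- function(s, f) {
  validObject(f)
  keep <- if (f@kind == "LP") s@wavelengthNm >= f@cutonNm
          else s@wavelengthNm >= f@cutonNm & s@wavelengthNm <= f@cutoffNm
  Spectrum(s@wavelengthNm, ifelse(keep, s@intensity, 0),
           filterApplied = .filterLabel(f))
}

#' Stokes shift of an emission maximum
#'
#' Difference between an emission-peak wavelength and the excitation
#' wavelength (488 nm laser by default). Anti-Stokes emission is not
#' modelled; peaks below the excitation wavelength are rejected.
#'
#' @param peakNm emission-maximum wavelength(s) in nm.
#' @param excitationNm excitation wavelength in nm (default 488).
#' @return Stokes shift(s) in nm.
#' @examples
#' stokesShift(528)  # 40
#' stokesShift(594)  # 106
#' @export
stokesShift <- function(peakNm, excitationNm = 488) {
  if (any(peakNm < excitationNm))
    stop("emission maximum below the excitation wavelength ",
         "(anti-Stokes emission is not modelled)")
  peakNm - excitationNm
}

#' Locate emission maxima in a spectrum
#'
#' Finds local maxima whose topographic prominence is at least
#' \code{prominenceFraction} of the global maximum intensity. The
#' prominence of a peak is its height above the higher of the two
#' minima separating it from taller terrain on either side (or the
#' spectrum edge). Each reported peak carries its Stokes shift
#' relative to the excitation wavelength (\code{NA} for peaks below
#' it).
#'
#' @param s a [Spectrum-class] (raw or normalized).
#' @param prominenceFraction minimum relative prominence (default
#'   0.05).
#' @param excitationNm excitation wavelength for Stokes shifts.
#' @return data frame with columns \code{wavelength_nm},
#'   \code{intensity}, \code{stokes_shift_nm}, sorted by wavelength;
#'   zero rows if no peaks.
#' @export
findPeaks <- function(s, prominenceFraction = 0.05, excitationNm = 488) {
  y <- s@intensity
  wl <- s@wavelengthNm
  n <- length(y)
  empty <- data.frame(wavelength_nm = numeric(0), intensity = numeric(0),
                      stokes_shift_nm = numeric(0))
  if (n < 3 || max(y) <= 0) return(empty)
  ## local maxima; plateaus contribute their midpoint
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[j]) j <- j + 1  # walk plateau
      if (j < n && y[j + 1] < y[j]) idx <- c(idx, (i + j) %/% 2)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(idx) == 0) return(empty)
  globalMax <- max(y)
  prom <- vapply(idx, function(p) {
    h <- y[p]
    leftHigher <- which(y[seq_len(p - 1)] > h)
    lo <- if (length(leftHigher)) max(leftHigher) + 1 else 1
    leftMin <- min(y[lo:p])
    rightHigher <- which(y[(p + 1):n] > h)
    hi <- if (length(rightHigher)) p + min(rightHigher) - 1 else n
    rightMin <- min(y[p:hi])
    h - max(leftMin, rightMin)
  }, numeric(1))
  keep <- prom >= prominenceFraction * globalMax
  idx <- idx[keep]
  if (length(idx) == 0) return(empty)
  shift <- ifelse(wl[idx] >= excitationNm, wl[idx] - excitationNm, NA_real_)
  data.frame(wavelength_nm = wl[idx], intensity = y[idx],
             stokes_shift_nm = shift)[order(wl[idx]), , drop = FALSE]
}

#' Normalize a spectrum to unit peak intensity
#'
#' @param s a [Spectrum-class] with positive maximum intensity.
#' @return the [Spectrum-class] divided by its maximum (peak value
#'   exactly 1). Idempotent.
#' @export
normalizeSpectrum <- function(s) {
  m <- max(s@intensity)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize a spectrum with non-positive maximum")
  Spectrum(s@wavelengthNm, s@intensity / m,
           filterApplied = s@filterApplied)
}
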