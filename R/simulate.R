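#' @include classify.R
NULL

#' Construct a material model for the simulator
#'
#' @param name material label.
#' @param tauMuNs,tauSigmaNs per-pixel lifetime distribution (Gaussian,
#'   ns).
#' @param meanIntensity mean fluorescence intensity (a.u.).
#' @param emissionPeaks matrix (or NULL) with columns center nm,
#'   width nm, relative amplitude, one row per Gaussian emission peak.
#' @return a [MaterialModel-class].
#' @export
materialModel <- function(name, tauMuNs, tauSigmaNs, meanIntensity,
                          emissionPeaks = NULL) {
  if (is.null(emissionPeaks))
    emissionPeaks <- matrix(numeric(0), 0, 3)
  emissionPeaks <- as.matrix(emissionPeaks)
  colnames(emissionPeaks) <- c("center_nm", "width_nm", "amplitude")
  new("MaterialModel", name = name, tauMuNs = as.numeric(tauMuNs),
      tauSigmaNs = as.numeric(tauSigmaNs),
      meanIntensity = as.numeric(meanIntensity),
      emissionPeaks = emissionPeaks)
}

setMethod("show", "MaterialModel", function(object) {
  cat(sprintf("MaterialModel '%s': tau %.3g +/- %.3g ns, I = %g a.u., %d emission peak(s)\n",
              object@name, object@tauMuNs, object@tauSigmaNs,
              object@meanIntensity, nrow(object@emissionPeaks)))
})

#' Calibration-based material presets
#'
#' Material models parameterized by the single-material FD-FLIM
#' calibration: with the BP 495-550 nm emission filter, HDPE has
#' 3.52 +/- 0.21 ns and spruce 1.40 +/- 0.12 ns, while grass emission
#' (chlorophyll, 680-770 nm) is blocked and contributes only residual
#' intensity; with the LP 500 nm filter, HDPE is 1.68 +/- 0.07 ns,
#' spruce 1.54 +/- 0.07 ns and grass 1.15 +/- 0.08 ns. Emission-peak
#' positions mirror the measured spectra: HDPE at 528 nm (polymer) and
#' 594 nm (red dye, the taller peak), spruce at 563 nm (lignin), grass
#' at 691/719/741 nm (chlorophyll a).
#'
#' Mean intensities are relative working values (foreground materials
#' at 800-1000 a.u.; BP-filtered grass at 50 a.u., i.e. 5\% of the
#' brightest foreground, so it falls below the 10\% intensity gate and
#' appears as noise).
#'
#' @param filter \code{"BP"} (default) or \code{"LP"} emission filter
#'   the lifetimes were calibrated with.
#' @return named list of [MaterialModel-class] objects (\code{HDPE},
#'   \code{Spruce}, \code{Grass}).
#' @export
materialPresets <- function(filter = c("BP", "LP")) {
  filter <- match.arg(filter)
  hdpePeaks <- rbind(c(528, 12, 0.8), c(594, 18, 1.0))
  sprucePeaks <- rbind(c(563, 25, 1.0))
  grassPeaks <- rbind(c(691, 6, 1.0), c(719, 6, 0.8), c(741, 6, 0.6))
  if (filter == "BP") {
    list(
      HDPE = materialModel("HDPE", 3.52, 0.21, 1000, hdpePeaks),
      Spruce = materialModel("Spruce", 1.40, 0.12, 800, sprucePeaks),
      ## chlorophyll emission is outside the BP passband: residual
      ## intensity only, broad noise-like lifetimes
      Grass = materialModel("Grass", 1.15, 0.60, 50, grassPeaks))
  } else {
    list(
      HDPE = materialModel("HDPE", 1.68, 0.07, 1000, hdpePeaks),
      Spruce = materialModel("Spruce", 1.54, 0.07, 800, sprucePeaks),
      Grass = materialModel("Grass", 1.15, 0.08, 900, grassPeaks))
  }
}

#' Describe one placed region of a synthetic scene
#'
#' @param shape \code{"rect"} or \code{"ellipse"}.
#' @param material material name (must exist in the model list given
#'   to [renderStack()]).
#' @param row,col top-left corner (1-based pixel indices).
#' @param height,width extents in pixels (for an ellipse, the bounding
#'   box of the inscribed ellipse).
#' @return a region descriptor list.
#' @export
sceneRegion <- function(shape = c("rect", "ellipse"), material, row, col,
                        height, width) {
  shape <- match.arg(shape)
  list(shape = shape, material = material, row = as.integer(row),
       col = as.integer(col), height = as.integer(height),
       width = as.integer(width))
}

#' Construct a synthetic scene specification
#'
#' @param dims image shape \code{c(rows, cols)}; default the sensor
#'   resolution 1004 x 1008.
#' @param regions list of [sceneRegion()] descriptors; later regions
#'   overwrite earlier ones.
#' @param backgroundIntensityFraction soil background intensity
#'   ceiling, as a fraction of the maximum foreground mean intensity
#'   (default 0.08, safely below the 0.10 gate).
#' @param backgroundTauRangeNs uniform lifetime range of background
#'   pixels in ns (default 0.2-5).
#' @param seed default seed used by [renderStack()] (optional).
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(dims = c(1004L, 1008L), regions = list(),
                      backgroundIntensityFraction = 0.08,
                      backgroundTauRangeNs = c(0.2, 5),
                      seed = NA_real_) {
  new("SceneSpec", dims = as.integer(dims), regions = regions,
      background = list(
        intensity_fraction = as.numeric(backgroundIntensityFraction),
        tau_range_ns = as.numeric(backgroundTauRangeNs)),
      seed = as.numeric(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px, %d region(s), background <= %g%% of foreground\n",
              object@dims[1], object@dims[2], length(object@regions),
              100 * object@background$intensity_fraction))
})

#' Material names referenced by a scene
#'
#' @param spec a [SceneSpec-class].
#' @return character vector of unique material names in region order.
#' @export
sceneMaterials <- function(spec) {
  unique(vapply(spec@regions, `[[`, character(1), "material"))
}

#' Preset scenes mirroring the two sample arrangements
#'
#' \code{"experiment3"}: three large abutting regions — spruce across
#' the top, HDPE lower left, grass lower right — filling most of the
#' frame, as when large pieces of the three materials are laid next to
#' each other and imaged at 10x.
#' \code{"experiment4"}: small material chips scattered on soil at 2x
#' magnification — several spruce splinters (elongated rectangles) and
#' small HDPE chips down to 25 x 35 px, the minimum detectable
#' particle footprint.
#'
#' @param name preset name.
#' @param seed default seed recorded in the spec.
#' @return a [SceneSpec-class].
#' @export
scenePreset <- function(name = c("experiment3", "experiment4"),
                        seed = NA_real_) {
  name <- match.arg(name)
  if (name == "experiment3") {
    regions <- list(
      sceneRegion("rect", "Spruce", row = 1, col = 1,
                  height = 400, width = 1008),
      sceneRegion("rect", "HDPE", row = 421, col = 1,
                  height = 584, width = 500),
      sceneRegion("rect", "Grass", row = 421, col = 521,
                  height = 584, width = 488))
    sceneSpec(regions = regions, seed = seed)
  } else {
    regions <- list(
      ## spruce splinters: elongated, ~5 mm x 1 mm at 2.8 um/px scale
      ## is larger than the frame, so splinter-shaped cut-outs
      sceneRegion("rect", "Spruce", row = 80, col = 100,
                  height = 120, width = 700),
      sceneRegion("rect", "Spruce", row = 320, col = 250,
                  height = 90, width = 620),
      sceneRegion("rect", "Spruce", row = 650, col = 60,
                  height = 110, width = 560),
      ## HDPE chips, 1-2 mm scale down to the 25 x 35 px minimum
      sceneRegion("rect", "HDPE", row = 520, col = 760,
                  height = 120, width = 140),
      sceneRegion("ellipse", "HDPE", row = 250, col = 40,
                  height = 80, width = 110),
      sceneRegion("rect", "HDPE", row = 850, col = 420,
                  height = 60, width = 90),
      sceneRegion("rect", "HDPE", row = 900, col = 800,
                  height = 25, width = 35))
    sceneSpec(regions = regions, seed = seed)
  }
}

#' Rasterize a scene into a ground-truth label image
#'
#' Deterministic: background is 0, each material gets the 1-based index
#' of its name in \code{sceneMaterials(spec)}; later regions overwrite
#' earlier ones.
#'
#' @param spec a [SceneSpec-class].
#' @return integer label matrix with attribute \code{materials} (the
#'   name vector the ids index into).
#' @export
renderLabels <- function(spec) {
  validObject(spec)
  mats <- sceneMaterials(spec)
  lab <- matrix(0L, spec@dims[1], spec@dims[2])
  for (r in spec@regions) {
    id <- match(r$material, mats)
    rows <- r$row:(r$row + r$height - 1)
    cols <- r$col:(r$col + r$width - 1)
    if (r$shape == "rect") {
      lab[rows, cols] <- id
    } else {
      cy <- r$row + (r$height - 1) / 2
      cx <- r$col + (r$width - 1) / 2
      ry <- r$height / 2
      rx <- r$width / 2
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      inside <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
      sub <- lab[rows, cols]
      sub[inside] <- id
      lab[rows, cols] <- sub
    }
  }
  attr(lab, "materials") <- mats
  lab
}

## Gaussian draw truncated at zero (lifetimes cannot be negative).
.rnormTrunc0 <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  x <- rnorm(n, mu, sigma)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mu, sigma)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Render a synthetic five-layer FLIM stack with ground truth
#'
#' Simulates an acquisition of the scene: each foreground pixel draws
#' a lifetime from its material's Gaussian distribution (truncated at
#' zero) and an intensity from the material mean with multiplicative
#' Gaussian noise; background (soil) pixels get uniform low intensity
#' and broadly distributed uniform lifetimes, so that under the 10\%
#' intensity gate they vanish or appear as noise. The phase-shift and
#' modulation-index layers are then computed from the drawn lifetime
#' map through the single-exponential forward model, making the stack
#' self-consistent: re-deriving the lifetime layers from the raw
#' layers reproduces the drawn map.
#'
#' @param spec a [SceneSpec-class].
#' @param materials named list of [MaterialModel-class] objects
#'   covering every material the scene references (default: BP-filter
#'   presets).
#' @param modFreqHz modulation frequency in Hz (default 30 MHz).
#' @param magnification objective magnification recorded in the stack
#'   metadata (default 2).
#' @param intensityCV coefficient of variation of the multiplicative
#'   intensity noise (default 0.10).
#' @param seed random seed; defaults to the spec's own seed. Same seed,
#'   same scene: outputs are reproducible bit for bit.
#' @return list with elements \code{stack} ([FLIMStack-class]) and
#'   \code{labels} (the [renderLabels()] ground truth).
#' @export
renderStack <- function(spec, materials = materialPresets("BP"),
                        modFreqHz = 30e6, magnification = 2,
                        intensityCV = 0.10, seed = NULL) {
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  if (!is.null(seed) && !is.na(seed)) set.seed(seed)
  mats <- sceneMaterials(spec)
  missingMats <- setdiff(mats, names(materials))
  if (length(missingMats))
    stop("unknown material(s) in scene: ",
         paste(missingMats, collapse = ", "))
  lab <- renderLabels(spec)
  nr <- spec@dims[1]; nc <- spec@dims[2]
  tau <- matrix(NA_real_, nr, nc)
  intensity <- matrix(NA_real_, nr, nc)
  for (i in seq_along(mats)) {
    m <- materials[[mats[i]]]
    sel <- which(lab == i)
    tau[sel] <- .rnormTrunc0(length(sel), m@tauMuNs, m@tauSigmaNs)
    intensity[sel] <- m@meanIntensity *
      pmax(1 + rnorm(length(sel), 0, intensityCV), 0.01)
  }
  bg <- which(lab == 0)
  maxMean <- max(vapply(materials[mats], function(m) m@meanIntensity,
                        numeric(1)))
  intensity[bg] <- runif(length(bg), 0,
                         spec@background$intensity_fraction * maxMean)
  tr <- spec@background$tau_range_ns
  tau[bg] <- runif(length(bg), tr[1], tr[2])
  phase <- lifetimeToPhase(tau, modFreqHz)
  M <- lifetimeToModIndex(tau, modFreqHz)
  stk <- deriveLifetimeLayers(intensity, phase, M, modFreqHz,
                              magnification = magnification,
                              emissionFilter = "BP495-550")
  list(stack = stk, labels = lab)
}

#' Render a synthetic emission spectrum of a material
#'
#' Sum of the material's Gaussian emission peaks on a wavelength grid,
#' plus optional additive Gaussian noise, clamped to non-negative.
#'
#' @param material a [MaterialModel-class].
#' @param grid wavelength grid in nm (default 200-1000 nm at 1 nm, the
#'   spectrometer range).
#' @param noiseSd additive noise SD relative to the tallest peak
#'   amplitude (default 0).
#' @param seed optional random seed.
#' @return a [Spectrum-class].
#' @examples
#' s <- renderSpectrum(materialPresets("BP")$HDPE)
#' findPeaks(s)$wavelength_nm  # 528 and 594
#' @export
renderSpectrum <- function(material, grid = seq(200, 1000, by = 1),
                           noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  pk <- material@emissionPeaks
  y <- numeric(length(grid))
  for (i in seq_len(nrow(pk)))
    y <- y + pk[i, 3] * exp(-0.5 * ((grid - pk[i, 1]) / pk[i, 2])^2)
  if (noiseSd > 0 && nrow(pk) > 0)
    y <- y + rnorm(length(grid), 0, noiseSd * max(pk[, 3]))
  Spectrum(grid, pmax(y, 0))
}
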