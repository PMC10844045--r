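#' @include gaussian.R
#' @importFrom EBImage erode dilate makeBrush bwlabel
#' @importFrom igraph graph_from_edgelist components
NULL

.asBinary <- function(x) {
  m <- matrix(as.numeric(as.vector(x) != 0), nrow(x), ncol(x))
  m[is.na(m)] <- 0
  m
}

#' Intensity gate: binary mask of prominent pixels
#'
#' Rescales a fluorescence intensity image to a binary image: pixels at
#' or above \code{thresholdFraction} of the maximum intensity present
#' in the image become 1, everything below becomes 0. The default 10\%
#' gate suppresses background (soil) and blocked-fluorescence pixels
#' before any lifetime is interpreted. Pixels exactly at the threshold
#' are foreground.
#'
#' @param intensity intensity layer (numeric matrix) or a
#'   [FLIMStack-class].
#' @param thresholdFraction fraction of the image maximum (default
#'   0.10).
#' @return a 0/1 matrix.
#' @export
intensityMask <- function(intensity, thresholdFraction = 0.10) {
  if (is(intensity, "FLIMStack")) intensity <- intensityLayer(intensity)
  if (thresholdFraction < 0 || thresholdFraction > 1)
    stop("thresholdFraction must lie in [0, 1]")
  m <- max(intensity, na.rm = TRUE)
  if (!is.finite(m) || m <= 0)
    stop("intensity image has no positive values to threshold against")
  out <- matrix(0, nrow(intensity), ncol(intensity))
  out[!is.na(intensity) & intensity >= thresholdFraction * m] <- 1
  out
}

#' Gate a lifetime image with a binary mask
#'
#' Pixelwise product of the lifetime layer with a 0/1 mask, mirroring
#' the multiplication of the intensity-derived binary image with the
#' phase-lifetime image. Gated-out pixels become \code{NA}, the
#' invalid-pixel sentinel, so they are excluded from every downstream
#' statistic (a stored-file representation writes them as 0).
#'
#' @param tau lifetime layer (numeric matrix, ns) or [FLIMStack-class].
#' @param mask 0/1 matrix of the same shape.
#' @return the gated lifetime matrix with \code{NA} outside the mask.
#' @export
maskLifetimes <- function(tau, mask) {
  if (is(tau, "FLIMStack")) tau <- tauPhaseLayer(tau)
  if (!identical(dim(tau), dim(mask)))
    stop("lifetime image and mask must share one shape")
  out <- tau
  out[.asBinary(mask) == 0] <- NA_real_
  out
}

#' Extract the pixels falling in a material's lifetime window
#'
#' Binary image of all valid pixels whose lifetime lies inside the
#' closed interval of a [MaterialRange-class].
#'
#' @param tau lifetime image (ns) with \code{NA} marking invalid
#'   pixels.
#' @param range a [MaterialRange-class].
#' @return a 0/1 matrix.
#' @export
extractRange <- function(tau, range) {
  validObject(range)
  if (is(tau, "FLIMStack")) tau <- tauPhaseLayer(tau)
  out <- matrix(0, nrow(tau), ncol(tau))
  out[!is.na(tau) & tau >= range@lo & tau <= range@hi] <- 1
  out
}

#' Morphology parameters for mask cleanup
#'
#' Structuring-element sizes for the four-step cleanup: an initial
#' erosion with a rectangular element (removes isolated noise pixels),
#' dilation and closing with disk elements (restores region interiors
#' and fills holes), and a final rectangular erosion for edge
#' smoothing. Rectangle edges must be odd so elements are centred.
#'
#' @param erode1 integer pair, edge lengths (rows, cols) of the first
#'   erosion rectangle; a single value is square.
#' @param dilateRadius disk radius in px for dilation.
#' @param closeRadius disk radius in px for closing.
#' @param erode2 edge lengths of the final erosion rectangle.
#' @return a named list of validated sizes.
#' @export
morphologyParams <- function(erode1 = c(3, 3), dilateRadius = 2,
                             closeRadius = 2, erode2 = c(3, 3)) {
  fix <- function(e, what) {
    if (length(e) == 1) e <- c(e, e)
    e <- as.integer(e)
    if (length(e) != 2 || any(e < 1) || any(e %% 2 == 0))
      stop(what, " must be one or two odd positive integers")
    e
  }
  if (dilateRadius < 1 || closeRadius < 1)
    stop("disk radii must be >= 1")
  list(erode1 = fix(erode1, "erode1"),
       dilateRadius = as.integer(dilateRadius),
       closeRadius = as.integer(closeRadius),
       erode2 = fix(erode2, "erode2"))
}

.rectKernel <- function(edges) matrix(1, edges[1], edges[2])
.diskKernel <- function(radius) makeBrush(2L * radius + 1L, shape = "disc")

## One morphology step with the image border treated as background:
## the image is padded with background wide enough for the element,
## operated on, and cropped back to the original domain.
.morphOp <- function(mask, kernel, op) {
  mask <- .asBinary(mask)
  if (nrow(kernel) > nrow(mask) || ncol(kernel) > ncol(mask))
    stop("structuring element larger than the image")
  pad <- max(dim(kernel))
  big <- matrix(0, nrow(mask) + 2 * pad, ncol(mask) + 2 * pad)
  rows <- pad + seq_len(nrow(mask))
  cols <- pad + seq_len(ncol(mask))
  big[rows, cols] <- mask
  r <- op(big, kernel)
  out <- matrix(as.numeric(as.vector(r) != 0), nrow(big), ncol(big))
  out[rows, cols, drop = FALSE]
}

#' Elementary binary morphology with background borders
#'
#' Standard binary erosion, dilation and closing (dilation followed by
#' erosion) with an arbitrary flat structuring element, treating
#' everything outside the image as background — foreground touching
#' the border erodes there.
#'
#' @param mask a 0/1 matrix.
#' @param kernel binary structuring element matrix with odd dimensions
#'   (e.g. \code{matrix(1, 3, 3)}).
#' @return the transformed 0/1 matrix.
#' @seealso [morphologicalCleanup()] for the four-step pipeline.
#' @export
binaryErode <- function(mask, kernel) .morphOp(mask, kernel, erode)

#' @rdname binaryErode
#' @export
binaryDilate <- function(mask, kernel) .morphOp(mask, kernel, dilate)

#' @rdname binaryErode
#' @export
binaryClosing <- function(mask, kernel)
  binaryErode(binaryDilate(mask, kernel), kernel)

#' Four-step morphological cleanup of a material mask
#'
#' Applies, in order: erosion with a rectangular element (eliminates
#' isolated noise pixels wrongly counted into the range), dilation with
#' a disk, closing with a disk (recovers pixels inside the material
#' boundary whose lifetime fell outside the window), and a final
#' rectangular erosion for edge smoothing. Pixels outside the image
#' are treated as background, so foreground touching the border erodes
#' there.
#'
#' @param mask a 0/1 matrix.
#' @param params a list from [morphologyParams()].
#' @return the cleaned 0/1 matrix.
#' @export
morphologicalCleanup <- function(mask, params = morphologyParams()) {
  mask <- .asBinary(mask)
  out <- binaryErode(mask, .rectKernel(params$erode1))
  out <- binaryDilate(out, .diskKernel(params$dilateRadius))
  out <- binaryClosing(out, .diskKernel(params$closeRadius))
  binaryErode(out, .rectKernel(params$erode2))
}

#' Relative share of an image covered by a mask
#'
#' Percentage of all image pixels (the full sensor area, not only the
#' gated foreground) equal to 1.
#'
#' @param mask a 0/1 matrix.
#' @return percent in \eqn{[0, 100]}.
#' @examples
#' relativeShare(matrix(c(1, 0, 0, 0), 2, 2))  # 25
#' @export
relativeShare <- function(mask) {
  mask <- .asBinary(mask)
  100 * sum(mask) / length(mask)
}

## Connected-component labelling. EBImage's bwlabel is 4-connected;
## for 8-connectivity, labels touching diagonally are merged.
.labelComponents <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop("connectivity must be 4 or 8")
  lab <- bwlabel(mask)
  lab <- matrix(as.integer(round(as.vector(lab))), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
    keep1 <- a1 > 0 & b1 > 0 & a1 != b1
    keep2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(edges) > 0) {
      g <- graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                               directed = FALSE)
      comp <- components(g)
      remap <- seq_len(nlab)
      ids <- as.integer(igraph::V(g)$name)
      remap[ids] <- nlab + comp$membership  # merge groups above old ids
      lab2 <- lab
      lab2[lab > 0] <- remap[lab[lab > 0]]
      lab <- matrix(match(lab2, sort(unique(as.vector(lab2[lab2 > 0])))),
                    nr, nc)
      lab[is.na(lab)] <- 0L
    }
  }
  lab
}

#' Measure particles in a binary mask
#'
#' Labels connected components (8-connected by default) and reports,
#' per particle, the pixel area, bounding box, centroid, and the
#' physical extents obtained by multiplying bounding-box edges with
#' the projected pixel size. A 25 x 35 px particle at 2x magnification
#' (2.8 um pixels) therefore measures 70 um x 100 um.
#'
#' @param mask a 0/1 matrix.
#' @param pixelSizeUm projected pixel edge in micrometres (see
#'   [pixelSizeUm()]).
#' @param connectivity 8 (default) or 4.
#' @return data frame sorted by decreasing area with columns
#'   \code{area_px}, \code{bbox_rows_px}, \code{bbox_cols_px},
#'   \code{height_um}, \code{width_um}, \code{centroid_row},
#'   \code{centroid_col}; zero rows for an empty mask.
#' @export
measureParticles <- function(mask, pixelSizeUm, connectivity = 8) {
  mask <- .asBinary(mask)
  lab <- .labelComponents(mask, connectivity)
  empty <- data.frame(area_px = numeric(0), bbox_rows_px = numeric(0),
                      bbox_cols_px = numeric(0), height_um = numeric(0),
                      width_um = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0))
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  pos <- which(lab > 0)
  ids <- lab[pos]
  rows <- (pos - 1) %% nrow(lab) + 1
  cols <- (pos - 1) %/% nrow(lab) + 1
  area <- tabulate(ids, nlab)
  rmin <- tapply(rows, ids, min); rmax <- tapply(rows, ids, max)
  cmin <- tapply(cols, ids, min); cmax <- tapply(cols, ids, max)
  out <- data.frame(
    area_px = area,
    bbox_rows_px = as.numeric(rmax - rmin + 1),
    bbox_cols_px = as.numeric(cmax - cmin + 1),
    centroid_row = as.numeric(tapply(rows, ids, mean)),
    centroid_col = as.numeric(tapply(cols, ids, mean)))
  out$height_um <- out$bbox_rows_px * pixelSizeUm
  out$width_um <- out$bbox_cols_px * pixelSizeUm
  out <- out[order(-out$area_px), c("area_px", "bbox_rows_px",
                                    "bbox_cols_px", "height_um",
                                    "width_um", "centroid_row",
                                    "centroid_col")]
  rownames(out) <- NULL
  out
}

#' Multi-material lifetime classification pipeline
#'
#' Runs the full evaluation chain on a five-layer FLIM stack: (1) the
#' intensity image is gated at \code{thresholdFraction} of its maximum
#' ([intensityMask()]); (2) the phase-lifetime image is masked with the
#' gate ([maskLifetimes()]); (3) for each material, pixels inside its
#' lifetime window are extracted into a raw binary image
#' ([extractRange()]); (4) each raw image is cleaned by
#' erosion-dilation-closing-erosion ([morphologicalCleanup()]); (5)
#' per material, the relative share of image pixels, the Gaussian
#' lifetime statistics of the classified pixels, and the particle
#' measurements are computed.
#'
#' Gaussian statistics are taken over the gated lifetime image
#' restricted to the cleaned mask by default (pixels re-included by
#' closing contribute their actual lifetimes); set
#' \code{statsAfterCleanup = FALSE} to use the raw range mask instead.
#' Material windows may overlap, in which case a pixel can enter
#' several raw masks; the count of such ambiguous pixels is recorded in
#' the result parameters.
#'
#' @param stack a [FLIMStack-class].
#' @param ranges list of [MaterialRange-class] objects (at least one).
#' @param thresholdFraction intensity gate fraction (default 0.10).
#' @param morphology list from [morphologyParams()].
#' @param connectivity particle connectivity, 8 (default) or 4.
#' @param statsAfterCleanup logical; compute lifetime statistics on the
#'   cleaned (default) or raw masks.
#' @return a [ClassificationResult-class].
#' @seealso [shares()], [materialFit()], [particleTable()],
#'   [writeClassification()]
#' @export
classifyStack <- function(stack, ranges, thresholdFraction = 0.10,
                          morphology = morphologyParams(),
                          connectivity = 8, statsAfterCleanup = TRUE) {
  if (!is(stack, "FLIMStack")) stop("stack must be a FLIMStack")
  if (is(ranges, "MaterialRange")) ranges <- list(ranges)
  if (length(ranges) == 0) stop("at least one material range is required")
  nms <- vapply(ranges, materialName, character(1))
  if (anyDuplicated(nms)) stop("material names must be unique")
  names(ranges) <- nms

  gate <- tryCatch(intensityMask(stack, thresholdFraction),
                   error = function(e) stop("intensity_mask: ",
                                            conditionMessage(e)))
  tauGated <- maskLifetimes(stack, gate)
  pxUm <- pixelSizeUm(stack)

  rawMasks <- cleanMasks <- fits <- particles <-
    stats::setNames(vector("list", length(ranges)), nms)
  sharesV <- stats::setNames(numeric(length(ranges)), nms)
  for (nm in nms) {
    raw <- tryCatch(extractRange(tauGated, ranges[[nm]]),
                    error = function(e) stop("extract_range[", nm, "]: ",
                                             conditionMessage(e)))
    cleaned <- tryCatch(morphologicalCleanup(raw, morphology),
                        error = function(e) stop("morphology[", nm, "]: ",
                                                 conditionMessage(e)))
    rawMasks[[nm]] <- raw
    cleanMasks[[nm]] <- cleaned
    sharesV[nm] <- relativeShare(cleaned)
    statsMask <- if (statsAfterCleanup) cleaned else raw
    vals <- tauGated[statsMask == 1]
    vals <- vals[is.finite(vals)]
    fits[nm] <- list(if (length(vals) >= 2) gaussianFit(vals) else NULL)
    particles[[nm]] <- measureParticles(cleaned, pxUm, connectivity)
  }

  ambiguous <- 0
  if (length(ranges) > 1) {
    tot <- Reduce(`+`, rawMasks)
    ambiguous <- sum(tot > 1)
  }
  new("ClassificationResult", ranges = ranges, rawMasks = rawMasks,
      cleanMasks = cleanMasks, shares = sharesV, fits = fits,
      particles = particles, tauImage = tauGated,
      params = list(threshold_fraction = thresholdFraction,
                    morphology = morphology,
                    connectivity = connectivity,
                    stats_after_cleanup = statsAfterCleanup,
                    pixel_size_um = pxUm,
                    mod_freq_hz = modFreq(stack),
                    magnification = magnification(stack),
                    ambiguous_pixels = ambiguous))
}

#' @rdname ClassificationResult-accessors
setMethod("shares", "ClassificationResult", function(x) x@shares)

.pickMaterial <- function(x, material, slotList) {
  if (missing(material)) return(slotList)
  if (!material %in% names(slotList))
    stop("unknown material: ", material)
  slotList[[material]]
}

#' @rdname ClassificationResult-accessors
setMethod("materialFit", "ClassificationResult", function(x, material)
  .pickMaterial(x, material, x@fits))
#' @rdname ClassificationResult-accessors
setMethod("cleanedMask", "ClassificationResult", function(x, material)
  .pickMaterial(x, material, x@cleanMasks))
#' @rdname ClassificationResult-accessors
setMethod("rawMask", "ClassificationResult", function(x, material)
  .pickMaterial(x, material, x@rawMasks))
#' @rdname ClassificationResult-accessors
setMethod("particleTable", "ClassificationResult", function(x, material)
  .pickMaterial(x, material, x@particles))

#' Summary table of a classification result
#'
#' @param object a [ClassificationResult-class].
#' @param ... unused.
#' @return data frame with one row per material: \code{material},
#'   \code{tau_mu_ns}, \code{tau_sigma_ns}, \code{n_pixels},
#'   \code{share_percent}, \code{n_particles}.
#' @export
setMethod("summary", "ClassificationResult", function(object, ...) {
  nms <- names(object@ranges)
  data.frame(
    material = nms,
    tau_mu_ns = vapply(nms, function(n) {
      f <- object@fits[[n]]; if (is.null(f)) NA_real_ else f@mu
    }, numeric(1)),
    tau_sigma_ns = vapply(nms, function(n) {
      f <- object@fits[[n]]; if (is.null(f)) NA_real_ else f@sigma
    }, numeric(1)),
    n_pixels = vapply(nms, function(n) {
      f <- object@fits[[n]]; if (is.null(f)) 0 else f@n
    }, numeric(1)),
    share_percent = as.numeric(object@shares),
    n_particles = vapply(nms, function(n) nrow(object@particles[[n]]),
                         integer(1)),
    row.names = NULL)
})

setMethod("show", "ClassificationResult", function(object) {
  cat("ClassificationResult\n")
  s <- summary(object)
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s share %6.2f %%", s$material[i],
                s$share_percent[i]))
    if (!is.na(s$tau_mu_ns[i]))
      cat(sprintf(", tau %.3g +/- %.3g ns (n = %d)", s$tau_mu_ns[i],
                  s$tau_sigma_ns[i], as.integer(s$n_pixels[i])))
    cat(sprintf(", %d particle(s)\n", s$n_particles[i]))
  }
  if (object@params$ambiguous_pixels > 0)
    cat(sprintf("  note: %d pixel(s) fell in more than one material range\n",
                object@params$ambiguous_pixels))
})
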