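#' @include simulate.R
#' @importFrom tiff readTIFF writeTIFF
#' @importFrom jsonlite toJSON fromJSON write_json read_json
NULL

## --------------------------------------------------------------------
## Five-layer stack TIFF + sidecar metadata.
##
## Pages are 32-bit float, single channel, no compression. The TIFF
## writer available here stores samples in [0, 1], so every layer is
## written under a per-layer scale declared in the sidecar
## (value = stored * scale) with ~2% headroom, and the invalid-pixel
## sentinel NA is encoded as the reserved stored value 1.0 (valid data
## never reaches it). The sidecar is plain "key = value" text: units,
## scales, layer order and acquisition metadata.
## --------------------------------------------------------------------

.NA_STORED <- 1.0
## stored values are quantized by the writer (~2^-32 steps), so the
## sentinel is recognized by threshold; valid data never exceeds ~0.981
## because every scale carries 2% headroom
.NA_THRESHOLD <- 0.999

.defaultMetaPath <- function(path) paste0(path, ".meta")

.writeKV <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    if (is.numeric(v)) v <- paste(sprintf("%.17g", v), collapse = ",")
    sprintf("%s = %s", k, v)
  }, character(1))
  writeLines(lines, path)
}

.readKV <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("malformed metadata line: ", ln)
    key <- trimws(parts[1])
    kv[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}

.encodeLayer <- function(values, scale) {
  stored <- values / scale
  bad <- !is.na(stored) & stored >= .NA_THRESHOLD
  if (any(bad))
    stop("layer values exceed the declared scale headroom")
  stored[is.na(stored)] <- .NA_STORED
  stored
}

#' Write a five-layer FLIM stack to TIFF with sidecar metadata
#'
#' Writes a 5-page 32-bit float grayscale TIFF (layer order: intensity,
#' phase, modulation index, phase lifetime, modulation lifetime) and a
#' human-readable key/value sidecar carrying the acquisition metadata,
#' the per-layer value scales and units (phase in radians, lifetimes in
#' ns). Invalid (\code{NA}) pixels are stored under a reserved sentinel
#' value declared in the sidecar. [readStack()] inverts the encoding;
#' the round trip is exact to the 32-bit sample quantization of the
#' writer (better than 1e-6 of each layer's full scale).
#'
#' @param stack a valid [FLIMStack-class].
#' @param path output TIFF path.
#' @param metadataPath sidecar path (default \code{<path>.meta}).
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(stack, path, metadataPath = .defaultMetaPath(path)) {
  validObject(stack)
  layers <- list(intensity = stack@intensity, phase = stack@phase,
                 mod_index = stack@modIndex, tau_phase = stack@tauPhase,
                 tau_mod = stack@tauMod)
  maxOr1 <- function(x) {
    m <- suppressWarnings(max(x, na.rm = TRUE))
    if (!is.finite(m) || m <= 0) 1 else m
  }
  scales <- c(
    intensity = maxOr1(layers$intensity) * 1.02,
    phase = pi / 2 * 1.02,
    mod_index = 1.02,
    tau_phase = maxOr1(layers$tau_phase) * 1.02,
    tau_mod = maxOr1(layers$tau_mod) * 1.02)
  pages <- lapply(names(layers), function(nm)
    .encodeLayer(layers[[nm]], scales[[nm]]))
  writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
            reduce = FALSE)
  kv <- list(
    format = "flim-stack-v1",
    layer_order = paste(names(layers), collapse = ","),
    n_rows = nrow(stack@intensity),
    n_cols = ncol(stack@intensity),
    mod_freq_hz = stack@modFreqHz,
    magnification = stack@magnification,
    sensor_pixel_um = stack@sensorPixelUm,
    exposure_ms = stack@exposureMs,
    emission_filter = stack@emissionFilter,
    phase_unit = "radian",
    lifetime_unit = "ns",
    na_stored_value = .NA_STORED)
  for (nm in names(layers)) kv[[paste0("scale_", nm)]] <- scales[[nm]]
  .writeKV(kv, metadataPath)
  invisible(metadataPath)
}

.numMeta <- function(kv, key, default = NULL) {
  if (is.null(kv[[key]])) {
    if (is.null(default)) stop("metadata key missing: ", key)
    return(default)
  }
  suppressWarnings(as.numeric(kv[[key]]))
}

#' Read a five-layer FLIM stack from TIFF + sidecar metadata
#'
#' Expects a 5-page single-channel TIFF and the sidecar written by
#' [writeStack()] (or hand-written with the same keys). Layer
#' assignment follows the sidecar's \code{layer_order}; per-layer
#' scales and the invalid-value sentinel are applied; phase declared
#' in degrees (\code{phase_unit = degree}) is converted to radians.
#'
#' @param path TIFF path.
#' @param metadataPath sidecar path (default \code{<path>.meta}).
#' @return a validated [FLIMStack-class].
#' @export
readStack <- function(path, metadataPath = .defaultMetaPath(path)) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  kv <- .readKV(metadataPath)
  pages <- readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 5)
    stop(sprintf("expected a 5-page TIFF stack, found %d page(s)",
                 length(pages)))
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, integer(1)) != 2))
    stop("stack pages must be single-channel (grayscale)")
  for (i in 2:5)
    if (!identical(dims[[i]], dims[[1]]))
      stop("stack pages differ in shape")
  order <- strsplit(kv$layer_order %||% paste(.LAYER_ORDER, collapse = ","),
                    ",")[[1]]
  order <- trimws(order)
  if (!setequal(order, .LAYER_ORDER) || length(order) != 5)
    stop("layer_order must be a permutation of: ",
         paste(.LAYER_ORDER, collapse = ", "))
  naStored <- .numMeta(kv, "na_stored_value", .NA_STORED)
  getLayer <- function(nm) {
    stored <- pages[[match(nm, order)]]
    scale <- .numMeta(kv, paste0("scale_", nm), 1)
    out <- stored * scale
    out[stored >= .NA_THRESHOLD * naStored] <- NA_real_
    out
  }
  phase <- getLayer("phase")
  if (identical(kv$phase_unit, "degree")) phase <- phase * pi / 180
  FLIMStack(
    intensity = getLayer("intensity"), phase = phase,
    modIndex = getLayer("mod_index"), tauPhase = getLayer("tau_phase"),
    tauMod = getLayer("tau_mod"),
    modFreqHz = .numMeta(kv, "mod_freq_hz"),
    magnification = .numMeta(kv, "magnification", 10),
    sensorPixelUm = .numMeta(kv, "sensor_pixel_um", 5.6),
    exposureMs = .numMeta(kv, "exposure_ms", NA_real_),
    emissionFilter = kv$emission_filter %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --------------------------------------------------------------------
## Spectra: two-column comma-separated text (wavelength nm, intensity).
## --------------------------------------------------------------------

#' Read a spectrum from a comma-separated file
#'
#' Two columns: wavelength in nm, intensity in a.u. A single header
#' line is tolerated; any other non-numeric row is a format error
#' reporting its line number. Wavelengths must be strictly increasing.
#'
#' @param path file path.
#' @return a [Spectrum-class].
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("spectrum file is empty: ", path)
  start <- 1
  firstFields <- strsplit(lines[1], ",")[[1]]
  if (anyNA(suppressWarnings(as.numeric(firstFields)))) start <- 2
  if (start > length(lines)) stop("spectrum file holds no data rows")
  wl <- numeric(0); y <- numeric(0)
  for (i in start:length(lines)) {
    fields <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
    if (length(fields) != 2 || anyNA(fields))
      stop(sprintf("non-numeric or malformed spectrum row at line %d", i))
    wl <- c(wl, fields[1]); y <- c(y, fields[2])
  }
  if (length(wl) >= 2 && any(diff(wl) <= 0))
    stop("wavelengths must be strictly increasing (duplicate or ",
         "non-monotone wavelength found)")
  Spectrum(wl, y)
}

#' Write a spectrum to a comma-separated file
#'
#' Full double precision, so [readSpectrum()] recovers the values
#' exactly.
#'
#' @param s a [Spectrum-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSpectrum <- function(s, path) {
  lines <- c("wavelength_nm,intensity",
             sprintf("%.17g,%.17g", s@wavelengthNm, s@intensity))
  writeLines(lines, path)
  invisible(path)
}

## --------------------------------------------------------------------
## Material database: CSV of (name, mu_ns, sigma_ns, k).
## --------------------------------------------------------------------

#' Read a material lifetime database
#'
#' CSV with header \code{name,mu_ns,sigma_ns,k}; each row becomes a
#' \eqn{\mu \pm k\sigma} [MaterialRange-class].
#'
#' @param path CSV path.
#' @return named list of [MaterialRange-class] objects.
#' @export
readMaterialDb <- function(path) {
  if (!file.exists(path)) stop("material database not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "mu_ns", "sigma_ns", "k")
  if (!all(need %in% names(df)))
    stop("material database needs columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("material database is empty")
  ranges <- lapply(seq_len(nrow(df)), function(i) {
    fit <- new("GaussianFit", mu = df$mu_ns[i], sigma = df$sigma_ns[i],
               n = NA_real_)
    materialRange(fit, k = df$k[i], name = df$name[i])
  })
  names(ranges) <- df$name
  ranges
}

#' Write a material lifetime database
#'
#' @param ranges list of [MaterialRange-class] objects (or a single
#'   one).
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeMaterialDb <- function(ranges, path) {
  if (is(ranges, "MaterialRange")) ranges <- list(ranges)
  df <- data.frame(
    name = vapply(ranges, materialName, character(1)),
    mu_ns = vapply(ranges, function(r) r@fit@mu, numeric(1)),
    sigma_ns = vapply(ranges, function(r) r@fit@sigma, numeric(1)),
    k = vapply(ranges, function(r) r@k, numeric(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## --------------------------------------------------------------------
## Binary masks and label images: 8-bit single-page TIFF (0 / 255).
## --------------------------------------------------------------------

#' Write a binary mask as an 8-bit TIFF
#'
#' Foreground (1) is stored as white (255), background as black.
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  writeTIFF(.asBinary(mask), path, bits.per.sample = 8L,
            compression = "none")
  invisible(path)
}

#' Read a binary mask written by [writeMask()]
#'
#' @param path TIFF path.
#' @return 0/1 matrix.
#' @export
readMask <- function(path) {
  m <- readTIFF(path)
  if (length(dim(m)) != 2) stop("mask must be a single-channel TIFF")
  .asBinary(m > 0.5)
}

## --------------------------------------------------------------------
## Scene specifications: JSON.
## --------------------------------------------------------------------

#' Write a scene specification to JSON
#'
#' @param spec a [SceneSpec-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSceneSpec <- function(spec, path) {
  validObject(spec)
  obj <- list(dims = spec@dims,
              background = spec@background,
              seed = if (is.na(spec@seed)) NULL else spec@seed,
              regions = lapply(spec@regions, function(r)
                r[c("shape", "material", "row", "col", "height", "width")]))
  write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a scene specification from JSON
#'
#' @param path JSON path.
#' @return a [SceneSpec-class].
#' @export
readSceneSpec <- function(path) {
  if (!file.exists(path)) stop("scene spec not found: ", path)
  obj <- read_json(path, simplifyVector = TRUE)
  regions <- obj$regions
  if (is.data.frame(regions))
    regions <- lapply(seq_len(nrow(regions)), function(i)
      as.list(regions[i, , drop = FALSE]))
  regions <- lapply(regions, function(r)
    sceneRegion(r$shape, r$material, r$row, r$col, r$height, r$width))
  sceneSpec(dims = obj$dims, regions = regions,
            backgroundIntensityFraction = obj$background$intensity_fraction,
            backgroundTauRangeNs = obj$background$tau_range_ns,
            seed = if (is.null(obj$seed) || !is.numeric(obj$seed))
              NA_real_ else obj$seed)
}

## --------------------------------------------------------------------
## Classification result writers.
## --------------------------------------------------------------------

#' Write all outputs of a classification run
#'
#' Writes, into \code{dir}: per-material cleaned-mask TIFFs
#' (\code{mask_<material>.tif}), a particle table CSV, a summary CSV
#' (material, mu, sigma, n, share), the lifetime histogram CSV of the
#' gated image, and a JSON log of the run parameters.
#'
#' @param result a [ClassificationResult-class].
#' @param dir output directory (created if missing).
#' @param binWidthNs bin width of the exported histogram (default
#'   0.05).
#' @return invisibly, the directory.
#' @export
writeClassification <- function(result, dir, binWidthNs = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result@cleanMasks))
    writeMask(result@cleanMasks[[nm]],
              file.path(dir, sprintf("mask_%s.tif", nm)))
  write.csv(summary(result), file.path(dir, "summary.csv"),
            row.names = FALSE)
  parts <- do.call(rbind, lapply(names(result@particles), function(nm) {
    p <- result@particles[[nm]]
    if (nrow(p) == 0) return(NULL)
    cbind(material = nm, p)
  }))
  if (is.null(parts))
    parts <- data.frame(material = character(0))
  write.csv(parts, file.path(dir, "particles.csv"), row.names = FALSE)
  if (any(is.finite(result@tauImage))) {
    h <- lifetimeHistogram(result@tauImage, binWidthNs)
    write.csv(data.frame(bin_mid_ns = h$mids, count = h$counts),
              file.path(dir, "lifetime_histogram.csv"), row.names = FALSE)
  }
  write_json(result@params, file.path(dir, "run_parameters.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
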