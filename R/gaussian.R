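#' @include AllGenerics.R
NULL

## Valid-pixel extraction shared by the single-material evaluation.
.validTaus <- function(tau) {
  if (is(tau, "FLIMStack")) tau <- tauPhaseLayer(tau)
  v <- as.numeric(tau)
  v[is.finite(v)]
}

#' Absolute-frequency histogram of a lifetime image
#'
#' Bins the valid (non-\code{NA}) pixels of a lifetime layer into
#' fixed-width bins. Bin edges start at the largest multiple of the
#' bin width not exceeding the smallest value, so bins are aligned to
#' the lifetime axis rather than to the data.
#'
#' @param tau a lifetime layer (numeric matrix, ns) or a
#'   [FLIMStack-class] (its phase-lifetime layer is used).
#' @param binWidthNs bin width in ns (default 0.05).
#' @return list with \code{breaks} (edges), \code{mids}, \code{counts};
#'   counts sum to the number of valid pixels.
#' @export
lifetimeHistogram <- function(tau, binWidthNs = 0.05) {
  if (!is.numeric(binWidthNs) || length(binWidthNs) != 1 || binWidthNs <= 0)
    stop("binWidthNs must be a single positive number")
  v <- .validTaus(tau)
  if (length(v) == 0) stop("no valid lifetime pixels to histogram")
  lo <- floor(min(v) / binWidthNs) * binWidthNs
  hi <- ceiling(max(v) / binWidthNs) * binWidthNs
  if (hi <= lo) hi <- lo + binWidthNs
  breaks <- seq(lo, hi, by = binWidthNs)
  if (breaks[length(breaks)] < max(v)) breaks <- c(breaks, hi + binWidthNs)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
       counts = counts)
}

#' Gaussian characterization of a lifetime population
#'
#' Estimates the expectation value and standard deviation of the
#' lifetime distribution of one material. The default estimator is the
#' method of moments on the valid pixels (sample mean and sample SD),
#' which for Gaussian data is the maximum-likelihood answer and is
#' independent of any histogram binning. A least-squares fit of a
#' scaled Gaussian to the lifetime histogram is available via
#' \code{method = "curve"} for comparison.
#'
#' @param tau lifetime values: numeric vector/matrix (ns) or a
#'   [FLIMStack-class]. \code{NA} pixels are excluded.
#' @param method \code{"moments"} (default) or \code{"curve"}.
#' @param binWidthNs histogram bin width for the curve method.
#' @return a [GaussianFit-class] object.
#' @examples
#' set.seed(1)
#' gaussianFit(rnorm(1e4, 3.52, 0.21))
#' @export
gaussianFit <- function(tau, method = c("moments", "curve"),
                        binWidthNs = 0.05) {
  method <- match.arg(method)
  v <- .validTaus(tau)
  if (length(v) < 2)
    stop("need at least 2 valid lifetime values to fit")
  if (method == "moments") {
    return(new("GaussianFit", mu = mean(v), sigma = sd(v),
               n = as.numeric(length(v))))
  }
  h <- lifetimeHistogram(v, binWidthNs)
  x <- h$mids
  y <- h$counts
  start <- c(mu = mean(v), sigma = max(sd(v), binWidthNs / 2),
             amp = max(y))
  obj <- function(p) {
    if (p[2] <= 0) return(Inf)
    sum((y - p[3] * exp(-0.5 * ((x - p[1]) / p[2])^2))^2)
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  new("GaussianFit", mu = unname(fit$par[1]),
      sigma = abs(unname(fit$par[2])), n = as.numeric(length(v)))
}

#' @rdname fit-accessors
setMethod("fitMu", "GaussianFit", function(x) x@mu)
#' @rdname fit-accessors
setMethod("fitSigma", "GaussianFit", function(x) x@sigma)
#' @rdname fit-accessors
setMethod("fitN", "GaussianFit", function(x) x@n)

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: %.3g +/- %.3g ns (n = %s)\n", object@mu,
              object@sigma,
              if (is.na(object@n)) "?" else format(object@n)))
})

#' Lifetime acceptance window of a material
#'
#' Builds the closed interval \eqn{[\mu - k\sigma, \mu + k\sigma]} from
#' a Gaussian fit. With the default \eqn{k = 3} and the single-material
#' calibration values 3.52 +/- 0.21 ns (HDPE) and 1.40 +/- 0.12 ns
#' (spruce), this yields the windows [2.89, 4.15] and [1.04, 1.76] ns
#' used by the classification pipeline.
#'
#' A fit with \eqn{\sigma = 0} (or \eqn{k = 0}) would give a degenerate
#' zero-width window and is rejected; supply an explicit
#' \code{halfWidthNs} to override.
#'
#' @param fit a [GaussianFit-class].
#' @param k sigma multiplier (default 3).
#' @param name material label; required.
#' @param halfWidthNs optional explicit half-width in ns, overriding
#'   \code{k * sigma}.
#' @return a [MaterialRange-class].
#' @examples
#' f <- new("GaussianFit", mu = 3.52, sigma = 0.21, n = NA_real_)
#' materialRange(f, k = 3, name = "HDPE")  # [2.89, 4.15] ns
#' @export
materialRange <- function(fit, k = 3, name, halfWidthNs = NULL) {
  if (missing(name)) stop("a material name is required")
  if (!is.null(halfWidthNs)) {
    if (halfWidthNs <= 0) stop("halfWidthNs must be positive")
    half <- halfWidthNs
  } else {
    if (fit@sigma <= 0)
      stop("degenerate range: sigma = 0; supply an explicit halfWidthNs")
    if (k <= 0)
      stop("degenerate range: k must be positive")
    half <- k * fit@sigma
  }
  new("MaterialRange", name = name, lo = fit@mu - half,
      hi = fit@mu + half, k = as.numeric(k), fit = fit)
}

#' @rdname fit-accessors
setMethod("materialName", "MaterialRange", function(x) x@name)
#' @rdname fit-accessors
setMethod("rangeLo", "MaterialRange", function(x) x@lo)
#' @rdname fit-accessors
setMethod("rangeHi", "MaterialRange", function(x) x@hi)

setMethod("show", "MaterialRange", function(object) {
  cat(sprintf("MaterialRange '%s': [%.3g, %.3g] ns (k = %g)\n",
              object@name, object@lo, object@hi, object@k))
})

#' Normalized Gaussian curve of a fit
#'
#' Gaussian density scaled to peak value 1, for graphical comparison
#' of material lifetime distributions.
#'
#' @param fit a [GaussianFit-class] with \eqn{\sigma > 0}.
#' @param grid lifetimes (ns) at which to evaluate; default
#'   \eqn{\mu \pm 4\sigma} at 401 points.
#' @return data frame with columns \code{tau_ns} and \code{density}
#'   (peak value exactly 1 at \eqn{\mu}).
#' @export
normalizedGaussianCurve <- function(fit, grid = NULL) {
  if (fit@sigma <= 0)
    stop("sigma must be positive for a Gaussian curve")
  if (is.null(grid))
    grid <- seq(fit@mu - 4 * fit@sigma, fit@mu + 4 * fit@sigma,
                length.out = 401)
  data.frame(tau_ns = grid,
             density = exp(-0.5 * ((grid - fit@mu) / fit@sigma)^2))
}
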