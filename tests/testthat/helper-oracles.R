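# Independent brute-force oracles and small fixture builders.

# Sliding-window morphology by explicit shifting with zero padding:
# an implementation route entirely separate from the package's.
shiftImage <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  srcR <- seq_len(nr) - dr
  srcC <- seq_len(nc) - dc
  okR <- srcR >= 1 & srcR <= nr
  okC <- srcC >= 1 & srcC <= nc
  out[okR, okC] <- img[srcR[okR], srcC[okC], drop = FALSE]
  out
}

bruteMorph <- function(img, kernel, op = c("erode", "dilate")) {
  op <- match.arg(op)
  cr <- (nrow(kernel) + 1) %/% 2
  cc <- (ncol(kernel) + 1) %/% 2
  acc <- NULL
  for (i in seq_len(nrow(kernel))) for (j in seq_len(ncol(kernel))) {
    if (kernel[i, j] == 0) next
    # erosion at p inspects p + offset; dilation deposits at p + offset
    s <- if (op == "erode") shiftImage(img, cr - i, cc - j)
         else shiftImage(img, i - cr, j - cc)
    acc <- if (is.null(acc)) s
           else if (op == "erode") pmin(acc, s) else pmax(acc, s)
  }
  acc
}

bruteErode <- function(img, kernel) bruteMorph(img, kernel, "erode")
bruteDilate <- function(img, kernel) bruteMorph(img, kernel, "dilate")
bruteClosing <- function(img, kernel)
  bruteErode(bruteDilate(img, kernel), kernel)

# Table-2 single-material calibration windows (BP filter), mu +/- 3 sigma.
calibrationRanges <- function() {
  list(
    HDPE = materialRange(new("GaussianFit", mu = 3.52, sigma = 0.21,
                             n = NA_real_), k = 3, name = "HDPE"),
    Spruce = materialRange(new("GaussianFit", mu = 1.40, sigma = 0.12,
                               n = NA_real_), k = 3, name = "Spruce"))
}

# Small two-material scene used by several tests; region geometry
# scales with the requested image shape.
smallScene <- function(dims = c(180, 200)) {
  nr <- dims[1]; nc <- dims[2]
  sceneSpec(dims = dims, regions = list(
    sceneRegion("rect", "HDPE",
                row = max(1, round(0.10 * nr)),
                col = max(1, round(0.10 * nc)),
                height = round(0.33 * nr), width = round(0.40 * nc)),
    sceneRegion("rect", "Spruce",
                row = round(0.60 * nr), col = round(0.45 * nc),
                height = round(0.28 * nr), width = round(0.45 * nc))))
}

trueShare <- function(labels, id) 100 * sum(labels == id) / length(labels)
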