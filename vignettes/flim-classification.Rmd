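---
title: "Lifetime-range classification of microplastics with flimsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lifetime-range classification of microplastics with flimsort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimsort)
```

## The measurement model

Frequency-domain FLIM excites the sample with light modulated at an
ordinary frequency $f$ (30 MHz throughout this package's defaults) and
observes, per camera pixel, a harmonic emission that is phase-shifted
by $\varphi$ and demodulated by the modulation index
$M = (b/a)/(B/A)$, where $B, A$ are the excitation amplitude and
offset and $b, a$ their emission counterparts. For a
single-exponential fluorophore both observables encode the lifetime:

$$\tau_{PH} = \frac{\tan\varphi}{\omega}, \qquad
  \tau_{M} = \frac{\sqrt{1/M^2 - 1}}{\omega}, \qquad \omega = 2\pi f.$$

Two conventions are fixed package-wide and deliberately:

* $\omega$ is the *angular* frequency $2\pi f$; configuration files
  and metadata store the ordinary frequency $f$ in Hz. This is the
  standard frequency-domain fluorimetry convention, and the 3.75 ns
  reference-slide round trip only closes under it.
* Lifetimes are nanoseconds everywhere in the API; seconds appear only
  inside the formulas. Phase is radians internally; file metadata may
  declare degrees (`phase_unit = degree`) and is converted on read.

A pixel with $\varphi \notin [0, \pi/2)$ or $M \notin (0, 1]$ has no
single-exponential interpretation. Such pixels are set to `NA`, the
package-wide invalid-pixel sentinel, and are excluded from every
statistic. They are never clipped into range: clipping would bias the
Gaussian moments that the whole classification rests on.

For mixed pixels (`mixedEmissionResponse()`) the components add as
phasors, and the apparent lifetimes obey
$\tau_{PH} \le \tau_M$ — a useful physical sanity check that the test
suite asserts on random mixtures.

## Single-material characterization

A calibration measurement of one material yields about $10^6$ pixel
lifetimes. `gaussianFit()` characterizes them by the *method of
moments*: $\mu$ = sample mean, $\sigma$ = sample standard deviation.
For Gaussian data this is the maximum-likelihood estimate and — unlike
least-squares fitting of a histogram — does not depend on a bin width.
A histogram curve fit (`method = "curve"`) is provided for comparison;
on simulated Gaussian populations the two agree to well within one
standard error. Histograms themselves (`lifetimeHistogram()`) default
to 0.05 ns bins, fine enough to resolve $\sigma \approx 0.1$ ns
populations while keeping counts per bin high; the bin width is a
parameter, not a modelling commitment.

`materialRange()` turns a fit into the closed acceptance window
$[\mu - k\sigma,\ \mu + k\sigma]$ with $k = 3$ by default, covering
99.7 % of a Gaussian population. With the shipped calibration values
(BP filter: HDPE $3.52 \pm 0.21$ ns, spruce $1.40 \pm 0.12$ ns) the
windows $[2.89, 4.15]$ and $[1.04, 1.76]$ ns are disjoint, which is
precisely why the band-pass filter is the default: under a long-pass
filter the HDPE and spruce populations ($1.68 \pm 0.07$ and
$1.54 \pm 0.07$ ns) overlap within one standard deviation and cannot
be separated this way. A $\sigma = 0$ fit is rejected as degenerate
rather than silently producing an empty window; an explicit
`halfWidthNs` override exists for synthetic material definitions.

Whether calibration images should be pre-masked before fitting is
left to the caller: `gaussianFit()` fits whatever pixels it is given.
Fitting a whole frame that includes substrate pixels biases $\mu$
slightly toward the substrate population; the command-layer
`cmdFit()` documents this and the tests quantify it on simulated
frames.

## The multi-material pipeline

`classifyStack()` runs, in order:

1. **Intensity gate** — `intensityMask()` binarizes the intensity
   layer at 10 % of the image maximum. Pixels exactly at the
   threshold are foreground (the boundary case is otherwise
   undefined; the choice is documented and tested). The gate is
   relative to the image maximum, not absolute, so it survives
   exposure changes.
2. **Lifetime masking** — `maskLifetimes()` multiplies the phase
   lifetime image by the gate. Gated-out pixels become `NA`
   downstream (files store them as 0, per the binary-image product
   convention).
3. **Range extraction** — `extractRange()` marks pixels inside each
   material's closed window. Windows are extracted independently; a
   pixel may satisfy several overlapping windows, and the count of
   such ambiguous pixels is recorded in the result parameters.
4. **Morphological cleanup** — erosion (3×3 rectangle) removes
   isolated noise pixels whose lifetime fell into a window by chance;
   dilation and closing (disk, radius 2) recover interior pixels
   whose lifetime fell *outside* the window though they belong to the
   material; a final 3×3 erosion smooths edges. The element sizes are
   not dictated by the method and default to the smallest symmetric
   choices that remove single-pixel noise and close single-pixel
   holes; they are configurable (`morphologyParams()`) and recorded
   in every result. Outside the image border counts as background, so
   foreground touching the border erodes — the conservative choice
   for area estimates.
5. **Statistics** — relative share = classified pixels / *all* image
   pixels (the full-sensor denominator makes shares comparable across
   runs and directly yields the 0.06 % minimum-detectable share of a
   25×25 px particle); Gaussian statistics of the classified pixels;
   particle measurements via connected components.

Statistics are computed on the cleaned masks by default
(`statsAfterCleanup = TRUE`): the cleaned mask is the method's final
answer for "these pixels are this material", and pixels re-included by
closing contribute their actual lifetimes symmetrically, so the mean
stays unbiased. The pre-cleanup option exists for diagnosing how much
the morphology moves the statistics.

Particles are 8-connected by default (a diagonal chain of pixels reads
as one physical particle); 4-connectivity is available. Physical
extents are bounding-box edges times the projected pixel size
(5.6 µm / magnification). Note one arithmetic subtlety: a 35 px
bounding box at 2× is 98 µm, which instrument software typically
reports rounded as 100 µm.

## The scene simulator

`renderStack()` emulates the acquisition, not the optics: each
foreground pixel draws its lifetime from the material's Gaussian
(truncated at zero) and its intensity from the material mean with 10 %
multiplicative Gaussian noise; the raw phase and modulation layers are
then computed *through the forward model*, so the stack is physically
self-consistent and `deriveLifetimeLayers()` reproduces the drawn
lifetime map exactly. Soil background gets uniform intensity in
[0, 8 %] of the maximum foreground mean — safely below the 10 % gate —
and uniform lifetimes on [0.2, 5] ns, so any background pixel that
does survive gating lands in a material window only as isolated
speckle, which the first erosion removes. This background model is an
engineered stand-in (no quantitative soil lifetime statistics exist to
copy); it reproduces the qualitative "soil appears as noise"
behaviour and is labelled synthetic throughout.

What the simulator deliberately does **not** model: the optical point
spread function, photobleaching, detector shot noise correlated with
intensity, lifetime gradients within a material, biofilms or
weathering on particle surfaces, and mixed-material edge pixels.
Passing recovery tests on simulation therefore demonstrates that the
*pipeline* is correct and unbiased under its own assumptions — not
that real environmental samples satisfy those assumptions. On real
multi-material measurements the per-material standard deviations are
several times larger than the single-material calibration values, an
effect of sample heterogeneity that this package measures but does
not attempt to generate.

Two presets mirror the study designs: `"experiment3"` (three large
abutting regions of spruce, HDPE and grass at 10×) and
`"experiment4"` (spruce splinters and HDPE chips down to the
25 × 35 px minimum footprint on soil at 2×).

## File formats and numerical choices

* **Stacks** are 5-page 32-bit float TIFFs (order: intensity, phase,
  modulation index, τ_PH, τ_M) with a human-readable key/value
  sidecar. The available TIFF writer stores samples in [0, 1] with
  ~2⁻³² quantization, so each layer is written under a declared
  per-layer scale with 2 % headroom, and `NA` is encoded as the
  reserved stored value 1.0, recognized on read by threshold. Round
  trips are exact to better than 10⁻⁶ of each layer's full scale;
  second-generation round trips are value-stable.
* **Spectra** are two-column CSV (nm, a.u.) written at full double
  precision, so write→read is bit-exact. Interpolation
  (`interpolateSpectrum()`, default 0.01 nm) is piecewise linear —
  monotone and overshoot-free, which matters when the next step is an
  argmax; natural cubic splines are available where smoothness is
  wanted.
* **Peak detection** uses topographic prominence (default 5 % of the
  global maximum) on the interpolated spectrum. This resolves the
  three chlorophyll maxima of grass (691/719/741 nm) while ignoring
  noise ripples; a plain local-maximum search would report every
  noise wiggle.
* **Filters** are ideal boxcars (LP: transmit ≥ cut-on; BP: transmit
  on the closed [cut-on, cut-off]); real transmission curves are out
  of scope.
* Background subtraction clamps negative differences to zero, since
  negative intensities are unphysical and would propagate into peak
  normalization.

## Problem sizes and determinism

The test suite validates morphology against an independent
sliding-window oracle exhaustively on all $2^{16}$ binary 4×4 images
(tiled into one frame with background gaps wide enough to keep tiles
independent) plus randomized 16×16 cases with 5×5 elements, and runs
end-to-end parameter recovery on full-sensor 1004 × 1008 scenes
across ten seeds — recovered means within three standard errors of
the generating values and shares within two percentage points of the
ground-truth areas. Smaller scenes (~100–300 px frames) are used
where the full sensor adds nothing. All randomness flows through
explicit seeds; the same seed yields byte-identical simulator files
and identical classification summaries.

## Known limitations

* Single-frequency, single-exponential model only: no multi-frequency
  fitting, no phasor-plot analysis, no lifetime unmixing of mixed
  pixels.
* Classification is purely lifetime-range-based; materials whose
  windows overlap (e.g. the long-pass calibration values) cannot be
  separated, and the package reports ambiguity rather than resolving
  it.
* The camera referencing procedure and instrument control are out of
  scope; stacks are consumed as produced.
* Absolute radiometry is not attempted; all intensity reasoning is
  relative to the image maximum.
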