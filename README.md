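# flimsort

Frequency-domain fluorescence lifetime imaging (FD-FLIM) analysis for
identifying microplastic particles among natural materials.

## The problem

Identifying microplastics in environmental samples normally requires
extracting the particles from the matrix before spectroscopic analysis
(FTIR, Raman) — a slow, error-prone process. The fluorescence
*lifetime* is a material characteristic on the nanosecond scale, and a
frequency-domain FLIM camera measures it per pixel over a whole field
of view in a single exposure. Dyed high-density polyethylene (HDPE)
measured through a 495–550 nm band-pass emission filter has a lifetime
of 3.52 ± 0.21 ns, clearly separated from spruce wood at
1.40 ± 0.12 ns, while grass (chlorophyll emission at 680–770 nm) is
blocked entirely by the filter and soil stays below the intensity
gate. Lifetime-range segmentation of the image therefore picks the
plastic out of the matrix directly.

`flimsort` implements the complete evaluation chain for such
measurements, for analysts working with five-layer FD-FLIM image
stacks (intensity *I*, phase shift *φ*, modulation index *M*, and the
two derived lifetime images), plus a ground-truth-labelled scene
simulator so every stage can be validated without instrument data.

## The model

With excitation modulated at angular frequency ω = 2π·f (f = 30 MHz
here), a single-exponential emitter responds with a phase-shifted,
demodulated harmonic signal, giving two independent lifetime
estimates per pixel:

- phase lifetime:  τ_PH = tan(φ) / ω
- modulation lifetime:  τ_M = √(1/M² − 1) / ω,  with
  M = (b/a)/(B/A) the ratio of emission to excitation modulation
  depth.

Single-material calibration images are characterized by Gaussian
analysis (expectation value μ and standard deviation σ of the pixel
lifetimes); each material then gets a closed acceptance window
R = [μ − 3σ, μ + 3σ]. A multi-material image is evaluated by: (1) a
10 % intensity gate against the image maximum; (2) masking the phase
lifetime image with the gate; (3) extracting each material's window
into a binary image; (4) morphological cleanup
(erosion → dilation → closing → erosion); (5) relative shares
(classified pixels / all 1004 × 1008 pixels), per-material Gaussian
statistics, and particle sizing via connected components and the
projected pixel size (5.6 µm sensor pixel / magnification: 0.28, 0.56
and 2.8 µm at 20×, 10× and 2×).

## Worked example

Simulate the small-chips-on-soil arrangement (HDPE chips and spruce
splinters on soil, 2× magnification, full 1004 × 1008 sensor), then
classify it against the calibration windows:

```r
library(flimsort)

sim <- renderStack(scenePreset("experiment4"), seed = 42)
sim$stack
#> FLIMStack: 1004 x 1008 pixels, 5 layers
#>   modulation frequency: 30 MHz
#>   magnification: 2x (pixel 2.8 um)
#>   emission filter: BP495-550
#>   tau_phase: 1012032 valid pixels, range 0.2-5 ns

db <- list(
  materialRange(new("GaussianFit", mu = 3.52, sigma = 0.21, n = NA_real_),
                k = 3, name = "HDPE"),
  materialRange(new("GaussianFit", mu = 1.40, sigma = 0.12, n = NA_real_),
                k = 3, name = "Spruce"))

res <- classifyStack(sim$stack, db)
res
#> ClassificationResult
#>   HDPE       share   2.95 %, tau 3.52 +/- 0.208 ns (n = 29863), 4 particle(s)
#>   Spruce     share  19.90 %, tau 1.4 +/- 0.12 ns (n = 201377), 3 particle(s)
```

The recovered expectation values match the generating calibration
parameters, and the shares match the ground-truth areas of the scene
(2.96 % HDPE, 19.90 % spruce from `sim$labels`). The smallest chip in
the preset is the 25 × 35 px minimum detectable footprint; at 2.8 µm
pixels its bounding box measures 70 µm × 98 µm:

```r
head(particleTable(res, "HDPE"), 3)
#>   area_px bbox_rows_px bbox_cols_px height_um width_um centroid_row centroid_col
#> 1   16796          120          140       336      392        579.5        829.5
#> 2    6800           80          110       224      308        289.5         94.5
#> 3    5396           60           90       168      252        879.5        464.5
```

Spectral pre-analysis uses the same package: `renderSpectrum()`,
`subtractBackground()`, `averageSpectra()`, `interpolateSpectrum()`
(0.01 nm step), ideal `longPass(500)` / `bandPass(495, 550)` filter
models, and `findPeaks()` with Stokes shifts against the 488 nm
excitation.

A thin command-line wrapper is installed at
`inst/scripts/flimsort` (`flimsort simulate|spectra|fit|classify`).

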