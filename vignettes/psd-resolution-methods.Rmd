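---
title: "Single-image resolution estimation for SFXM maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-image resolution estimation for SFXM maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfres)
```

## The problem

Scanning fluorescence X-ray microscopy (SFXM) raster-scans a focused
X-ray spot across a specimen and records, per pixel, the emission at
characteristic fluorescence lines. Spectrum-fitting software converts
the recorded spectra into per-element areal mass concentration maps
$C_Z(x, y)$ in µg cm⁻². The spatial resolution actually achieved in
such a map depends on the focal spot *and* on the photon statistics of
that element's signal: a weakly fluorescing element in a short-dwell
scan resolves less than a strong one in the same scan. Fourier ring
correlation would need two independent images; this package estimates
resolution from a single map via its power spectral density (PSD).

## The model

The analysis works on the signed square-root amplitude
$\psi(x, y) = \mathrm{sign}(C)\sqrt{|C|}$, since fluorescence is an
incoherent signal proportional to intensity. Background subtraction
against a high-statistics background model leaves element-free pixels
fluctuating on either side of zero; the signed extension of the square
root (`signedAmplitude()`) preserves that zero-mean character instead
of rectifying the noise.

The 2-D PSD is $S(u_x, u_y) = |\Psi(u_x, u_y)|^2$ with $\Psi$ the
discrete Fourier transform of $\psi$ (`psd2d()`). Azimuthal averaging
over rings of constant radial frequency
$u_r = \sqrt{u_x^2 + u_y^2}$ gives the 1-D spectrum $S(u_r)$
(`azimuthalAverage()`), which for natural images declines log-log
linearly,

$$ S(u_r) \approx P\, u_r^{\,a}, \qquad a < 0, $$

until it flattens at the noise floor $S_{nf}$: Poisson counting noise
is uncorrelated between pixels, hence spectrally flat. Fitting the
trend below the knee (`fitSignalTrend()`) and averaging the floor above
it (`estimateNoiseFloor()`) yields

$$ u_{knee} = \left(\frac{S_{nf}}{P}\right)^{1/a}, \qquad
   u_{res} = \left(\frac{\mathrm{SNR}_{res}\, S_{nf}}{P}\right)^{1/a},
   \qquad \delta_{res} = \frac{1}{2\,u_{res}}, $$

where $\mathrm{SNR}_{res} = 5$ by default (the Rose criterion for a
reliably detected feature; `snrRes` is configurable). The same
quantities define the Wiener filter
$W(u) = S(u)/(S(u) + S_{nf})$, which equals 1/2 exactly at the knee
(`wienerFilter()`); the package reports the curve but does not apply
it to images.

Directional resolutions use the same machinery restricted to azimuthal
sectors of ±30° (configurable up to ±45°) about the $u_x$ or $u_y$
axis (`sectorAverage()`): samples near the $u_x$ axis probe structure
along x, giving $\delta_{res,x}$, and likewise for y.

## Parameters that matter

* **`snrRes`** (dimensionless, default 5): the signal-to-noise
  threshold defining $u_{res}$. 1 reproduces the knee; larger values
  give coarser, more conservative resolutions. $\delta_{res}$ is
  strictly increasing in `snrRes`.
* **Signal and noise ranges** (1/µm): explicit user input, mirroring
  interactive cursor selection in PSD tools. The signal range must sit
  below the knee, the noise range above it. `suggestFitRanges()`
  offers a two-segment piecewise-linear heuristic (split minimizing
  total squared residual, right segment flat) as a labeled
  convenience, not a substitute for inspection. `sensitivityScan()`
  quantifies how much $\delta_{res}$ moves across alternative signal
  selections; slopes can differ by more than one unit while
  $\delta_{res}$ moves by only a few percent, because the knee is
  pinned by the floor crossing.
* **`nBins`** (default `min(64, floor(min(Nx, Ny)/2))`): number of
  linear radial bins over $(0, u_{max}]$; the bin value is the
  arithmetic mean of member samples and the bin center the interval
  midpoint — the simplest reproducible smoothing rule.
* **Pixel pitch `dx`, `dy`** (µm): may differ; $u_r$ and sector angles
  are always computed on the physical frequency grid, so anisotropic
  scans (e.g. 1 µm × 2 µm) are handled without resampling. Scan-stage
  tilt is *not* folded into the pitch: maps are analysed in stage
  coordinates, which is also how resolutions are reported.

## Numerical choices

* **Transform normalization.** The unnormalized forward DFT is used
  ($\sum |\Psi|^2 = N_{tot} \sum \psi^2$, asserted as a test).
  Resolution depends only on the ratio $S/S_{nf}$, which is
  normalization-invariant; rescaling the whole PSD by any $k > 0$
  leaves $u_{knee}$, $u_{res}$, $\delta_{res}$ unchanged (also
  asserted).
* **Odd dimensions.** Maps with an odd pixel count are padded with one
  row/column of the average low signal level before transforming. "Low
  signal level" is not uniquely defined by common practice; this
  package uses the mean of the lowest-decile pixel values (the decile
  and an explicit numeric fill are exposed), which approximates the
  local background without injecting a sharp edge.
* **DC sample.** Excluded from radial binning by default: it carries
  the squared image sum, dwarfing the trend. A flag restores it.
* **Fit estimator.** Unweighted OLS in log10–log10 space; weighting by
  bin occupancy is available behind `weighted = TRUE`. The noise floor
  is the unweighted mean of in-range bins, with a median option for
  outlier robustness. With slopes this steep, estimator choice moves
  $\delta_{res}$ far less than it moves $a$.
* **Degenerate inputs.** A non-negative fitted slope (pure-noise
  image) yields a fit flagged invalid rather than an error at fit
  time; knee/resolution computations on such fits raise a "no knee"
  error. A floor above the trend at the low end of the fit range
  triggers an extrapolation warning. Bins with no samples are flagged
  `n = 0` and excluded everywhere.

## Calibration computations

The beamline characterization helpers implement the standard
instrument equations: absolute flux
$\Phi = (V - V_{dark})\, g_s \cdot 10^6 \cdot K(E)$ from a calibrated
photodiode ($K$ is a supplied calibration constant, never derived);
oblique-mount beam broadening $W/\cos\theta$; the inverse-square
detector distance fit $I = \alpha/(d_{eff} + \Delta d)^2$ (linearized
OLS start, Levenberg–Marquardt refinement — identical on exact
three-point series); the planar solid angle
$\Omega_{eff} = N_d A_{act}/d_{eff}^2$ without per-element obliquity
corrections; the probe-area ellipse $A_{beam} = \pi \delta_x \delta_y$
(the reading consistent with published fluence rates for asymmetric
probes, reducing to $\pi\delta^2$ for a symmetric Airy probe); and the
fluence chain rate $= \Phi/A_{beam}$, fluence $=$ rate
$\times\, t_{dwell}$.

The empirical limit of detection compares low-concentration sample
pixels against a blank scan. Counting statistics scale with dwell
time, so the blank histogram is widened **about its mean** by
$(t_{blank}/t_{sample})^{1/2}$ — correcting the distribution's width,
as photon statistics demand, without shifting its center. The
threshold is the smallest concentration exceeded by at most
`fpTolerance` corrected blank pixels (default 0, i.e. the corrected
blank maximum). This is deliberately empirical; rigorous
detection-limit theory (false-positive/negative tolerances on fitted
spectra) is out of scope.

## What the synthetic generator emulates — and what it does not

`makePhantom()` produces a non-negative concentration field whose PSD
declines at a requested log-log slope (spectrally filtered Gaussian
noise, optional Gaussian hotspots emulating localized Ca foci).
`simulateScan()` then applies the measurement chain: Gaussian
focal-spot blur of stated FWHMs, expected counts
$\lambda = c_u C\, t_{dwell} + b\, t_{dwell}$, Poisson draws, and
subtraction of the known expected background — reproducing the signed,
zero-mean fluctuations of real background-subtracted maps.
`makePowerlawPsd()` generates directly from the fitted model
$S(u) = (P u^a + S_{nf}) X_u$ with mean-one multiplicative scatter
$X_u \sim \chi^2_{df}/df$, the sampling law of an average of `df`
periodogram samples per radial bin.

Choices made once, on realism grounds:

* Default phantom fluctuation amplitude is 0.3 of the mean
  concentration — tissue-like contrast with negligible zero-clipping,
  keeping the square-root transform nearly linear so the amplitude
  PSD slope tracks the concentration-field slope.
* Default scan settings (1 µm pitch, 50 ms dwell, 6 µm PSF, 1000
  detected counts per (µg cm⁻²) s, 50 background counts/s) emulate a
  micro-probe tissue scan in which the noise floor is visible inside
  the sampled frequency band at short dwells.
* Synthetic-recovery fixtures use per-bin scatter `df = 200`,
  the typical mid-frequency radial-bin occupancy of the map sizes
  analysed here (a 128×128 map with 64 bins averages ~240 samples per
  median bin).
* Blur is applied spectrally with periodic boundaries — exact for the
  periodic random-field phantoms, but not a model of edge effects in
  real finite scans.

What passing synthetic tests do **not** show: real maps have
non-Poisson detector artefacts (incomplete charge collection, pile-up,
scatter background structure), spatially varying background,
non-Gaussian focal-spot tails, and fly-scan motion blur along the fast
axis. The synthetic suite validates the estimator's mathematics and
its qualitative response (resolution improves with dwell time and
degrades along a wider PSF axis), not instrument-specific accuracy.
Estimated $\delta_{res}$ need not equal the PSF FWHM — only the
monotone correspondence is asserted.

## Problem sizes and reproducibility

Test and acceptance computations use phantoms of 96–256 pixels per
side, 100-seed Monte-Carlo sweeps for recovery error, and 3-point
displacement series — sizes at which every check runs in seconds while
leaving the Monte-Carlo tolerances comfortably resolved. All
generators take an explicit integer `seed`, are bit-reproducible given
it, and restore the caller's RNG state.

## Worked example

```{r example}
ph <- makePhantom(shape = c(128, 128), spectralSlope = -3.5, seed = 11)
scan <- simulateScan(ph, psfFwhmX = 6, psfFwhmY = 6, dwell = 0.05,
                     seed = 42)
psd <- azimuthalAverage(psd2d(signedAmplitude(padToEven(scan))))
res <- estimateResolution(psd, signalRange = c(0.02, 0.08),
                          noiseRange = c(0.35, 0.6), snrRes = 5)
res
```

Increasing the dwell time raises the signal trend relative to the
floor and improves the estimate:

```{r dwell}
for (dw in c(0.02, 0.05, 0.1)) {
    sc <- simulateScan(ph, psfFwhmX = 6, psfFwhmY = 6, dwell = dw,
                       seed = 42)
    r <- mapResolution(sc, signalRange = c(0.02, 0.08),
                       noiseRange = c(0.35, 0.6))
    cat(sprintf("dwell %3.0f ms: delta_res = %.2f um\n",
                1000 * dw, deltaRes(r)))
}
```

## Known limitations

* Signal/noise range selection remains a user judgement; the
  heuristic can mis-split spectra with curvature or a barely visible
  floor.
* The power-law-plus-floor model assumes the floor is reached inside
  the sampled band; oversampled or extremely high-signal maps may
  show no floor, in which case the resolution is optic-limited and
  this method only bounds it.
* Sector estimates use fewer frequency samples and are accordingly
  noisier; ±30° is a compromise between axis mixing and sample count.
* The solid-angle formula is the planar small-angle approximation;
  at $\Omega_{eff}$ above ~1 sr per-element obliquity corrections
  (not implemented) become appreciable.
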