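# xrfres

Single-image spatial-resolution estimation for scanning fluorescence
X-ray microscopy (SFXM) elemental maps, with the accompanying beamline
characterization math and a synthetic scan simulator.

## The problem

SFXM raster-scans a focused X-ray spot over a specimen (tissue
sections, typically) and fits the recorded fluorescence spectra into
per-element areal mass concentration maps *C_Z(x, y)* [µg cm⁻²]. The
resolution achieved in such a map depends on both the optic and the
photon statistics of that element's signal, so it must be measured per
image and per element. Fourier ring correlation needs two independent
images; **xrfres** estimates resolution from one, using the image's
power spectral density (PSD):

1. the signed square-root amplitude ψ = sign(C)·√|C| is Fourier
   transformed and S = |Ψ|² azimuthally averaged into S(u_r);
2. the signal trend is a power law, S(u_r) ≈ P·u_r^a (a < 0), fitted
   by log-log least squares below the "knee";
3. pixel-uncorrelated Poisson noise gives a flat noise floor S_nf,
   estimated as the mean of bins above the knee;
4. the resolution frequency solves P·u^a = SNR_res·S_nf, with the Rose
   criterion SNR_res = 5 by default, and the spatial resolution is the
   half-period δ_res = 1/(2·u_res).

Sector-restricted averages (±30° about either frequency axis) give
directional estimates δ_res,x and δ_res,y; the same fit defines the
Wiener filter W(u) = S/(S + S_nf), which is exactly 1/2 at the knee.

The calibration module covers the surrounding instrument math:
absolute photon flux from a calibrated photodiode
(Φ = (V − V_dark)·g_s·10⁶·K), oblique beam broadening W/cosθ, the
inverse-square detector-distance fit I = α/(d_eff + Δd)², the
effective solid angle Ω_eff = N_d·A_act/d_eff², the probe-area
ellipse A_beam = π·δ_x·δ_y, the fluence chain Φ/A_beam · t_dwell,
and an empirical blank-histogram limit of detection with the
(t_blank/t_sample)^½ dwell-statistics width correction.

The synthetic module (`makePhantom()`, `simulateScan()`,
`makePowerlawPsd()`) generates power-law phantoms, blurs them with a
Gaussian focal spot, applies dwell-dependent Poisson counting and
background subtraction — so the whole pipeline is testable against
known ground truth, including the signed negative pixels real
background-subtracted maps contain.

## Worked example

```r
library(xrfres)

ph   <- makePhantom(shape = c(128, 128), spectralSlope = -3.5, seed = 11)
scan <- simulateScan(ph, psfFwhmX = 6, psfFwhmY = 6, dwell = 0.05,
                     seed = 42)
psd  <- azimuthalAverage(psd2d(signedAmplitude(padToEven(scan))))
estimateResolution(psd, signalRange = c(0.02, 0.08),
                   noiseRange = c(0.35, 0.6), snrRes = 5)
#> ResolutionResult (SNR_res = 5):
#>   u_knee = 0.09505 1/um   delta_knee = 5.26 um
#>   u_res  = 0.06492 1/um   delta_res  = 7.702 um
#>   trend P = 0.004249, a = -4.221; S_nf = 87.62
```

The 6 µm focal spot scanned at 50 ms dwell yields δ_res ≈ 7.7 µm: the
fitted trend P·u^a crosses 5× the noise floor at u_res ≈ 0.065
cycles/µm, i.e. features with half-periods coarser than ~7.7 µm carry
at least 5:1 signal-to-noise. Shorter dwells raise the floor and
coarsen δ_res; longer dwells improve it until the optic limits it. Calibration helpers are plain calls:

```r
solidAngle(DetectorGeometry(Nd = 7, Aact = 40, dEff = 14.4))  # 1.3503 sr
fluenceRate(7.7e9, beamArea(6.9, 6.4))                        # 5.55e7 photons/um^2/s
```

A command-line interface wrapping the same functions is installed at
`system.file("exec", "xrfres", package = "xrfres")`, with subcommands
`simulate`, `psd`, `resolution`, `sensitivity`, `calibrate-distance`,
`solid-angle`, `fluence` and `lod`, all emitting JSON:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","xrfres",package="xrfres"))') \
    resolution --map map.csv --signal-range 0.02:0.08 \
    --noise-range 0.35:0.6 --snr 5 --out report.json
```

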