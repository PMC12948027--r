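Package: xrfres
Title: Spatial Resolution Estimation for Scanning X-ray Fluorescence
    Microscopy via Power Spectral Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the achieved spatial resolution of scanning
    fluorescence X-ray microscopy (SFXM) elemental maps from a single
    image, using azimuthally averaged power spectral densities: a
    power-law fit of the signal trend, a noise-floor estimate, and an
    SNR-thresholded resolution frequency (Rose criterion by default).
    Includes sector-restricted (directional) resolution estimates, the
    associated Wiener filter, beamline characterization computations
    (absolute photon flux from a calibrated photodiode, oblique beam
    broadening, inverse-square detector-distance fitting, effective
    solid angle, probe area and fluence per time, and an empirical
    blank-histogram limit of detection), and a synthetic SFXM scan
    simulator (power-law phantoms, Gaussian focal-spot blur, dwell-
    dependent Poisson counting, background subtraction) for end-to-end
    validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ElementalMap-methods.R'
    'calibration.R'
    'io.R'
    'psd.R'
    'resolution.R'
    'pipeline.R'
    'synthetic.R'
    'xrfres-package.R'
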