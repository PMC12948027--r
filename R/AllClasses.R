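#' @import methods
NULL

#' ElementalMap: a 2-D areal mass concentration map
#'
#' Container for a single-element SFXM concentration map \eqn{C_Z(x, y)}
#' as produced by fluorescence spectrum-fitting programs, together with
#' the scan metadata the resolution analysis needs. Values are areal
#' mass concentrations in µg/cm² and may be negative: background
#' subtraction against a high-statistics background model leaves
#' element-free pixels fluctuating on either side of zero.
#'
#' Rows index the slow (y) scan axis, columns the fast (x) axis; row 1
#' is the top of the map. `dx`/`dy` are the pixel pitches along x
#' (columns) and y (rows) in µm; they may differ (anisotropic scans
#' such as 1 µm x 2 µm are common).
#'
#' @slot values numeric matrix of concentrations [µg/cm²]
#' @slot dx,dy pixel pitch along x and y [µm]
#' @slot element chemical symbol of the mapped element
#' @slot dwell per-pixel exposure time [s]
#' @export
setClass("ElementalMap",
    representation(
        values  = "matrix",
        dx      = "numeric",
        dy      = "numeric",
        element = "character",
        dwell   = "numeric"
    )
)

setValidity("ElementalMap", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v) || length(v) == 0L || any(dim(v) == 0L))
        msg <- c(msg, "'values' must be a non-empty numeric matrix")
    if (length(object@dx) != 1L || !is.finite(object@dx) || object@dx <= 0)
        msg <- c(msg, "'dx' must be a single positive number")
    if (length(object@dy) != 1L || !is.finite(object@dy) || object@dy <= 0)
        msg <- c(msg, "'dy' must be a single positive number")
    if (length(object@dwell) != 1L || !is.finite(object@dwell) ||
        object@dwell <= 0)
        msg <- c(msg, "'dwell' must be a single positive number")
    if (length(object@element) != 1L || is.na(object@element))
        msg <- c(msg, "'element' must be a single string")
    if (length(msg)) msg else TRUE
})

#' AmplitudeMap: signed square-root amplitude of a concentration map
#'
#' Holds \eqn{\psi(x, y)}, the signed square-root transform of an
#' [ElementalMap]: \eqn{\psi = +\sqrt{C}} where \eqn{C \ge 0} and
#' \eqn{\psi = -\sqrt{|C|}} where \eqn{C < 0}. The signed extension
#' keeps the zero-mean character of background-subtracted empty pixels
#' instead of rectifying their noise.
#'
#' @slot values signed amplitude matrix [(µg/cm²)^(1/2)]
#' @slot dx,dy pixel pitch along x and y [µm]
#' @export
setClass("AmplitudeMap",
    representation(values = "matrix", dx = "numeric", dy = "numeric")
)

setValidity("AmplitudeMap", function(object) {
    if (!is.numeric(object@values) || length(object@values) == 0L)
        return("'values' must be a non-empty numeric matrix")
    if (object@dx <= 0 || object@dy <= 0)
        return("pixel pitches must be positive")
    TRUE
})

#' PowerSpectrum2D: two-dimensional power spectral density
#'
#' The squared modulus \eqn{S(u_x, u_y) = |\Psi(u_x, u_y)|^2} of the
#' discrete Fourier transform of an [AmplitudeMap], on the physical
#' spatial-frequency grid in cycles/µm. The grid is stored in DFT
#' ordering (frequency 0 first, then positive, then negative
#' frequencies); for even \eqn{N_x} the axis spans
#' \eqn{-1/(2\Delta_x)} to \eqn{+b_x/(2\Delta_x)} with
#' \eqn{b_x = (N_x/2 - 1)/(N_x/2)}.
#'
#' @slot values non-negative power matrix (rows = u_y, cols = u_x)
#' @slot ux,uy spatial-frequency axes [1/µm], DFT ordering
#' @export
setClass("PowerSpectrum2D",
    representation(values = "matrix", ux = "numeric", uy = "numeric")
)

setValidity("PowerSpectrum2D", function(object) {
    msg <- character()
    if (any(object@values < 0))
        msg <- c(msg, "power values must be non-negative")
    if (length(object@ux) != ncol(object@values))
        msg <- c(msg, "'ux' length must match ncol(values)")
    if (length(object@uy) != nrow(object@values))
        msg <- c(msg, "'uy' length must match nrow(values)")
    if (length(msg)) msg else TRUE
})

#' RadialPSD: radially binned 1-D power spectral density
#'
#' The azimuthally (or sector-) averaged power spectral density
#' \eqn{S(u_r)}: for each radial-frequency bin, the arithmetic mean of
#' the 2-D PSD samples whose \eqn{u_r = \sqrt{u_x^2 + u_y^2}} falls in
#' the bin, together with the number of contributing samples. Bins
#' with no samples carry `n = 0` and `S = NA`.
#'
#' @slot u bin-center radial frequencies [1/µm], strictly increasing
#' @slot S mean power per bin (NA where n = 0)
#' @slot n integer count of 2-D frequency samples per bin
#' @export
setClass("RadialPSD",
    representation(u = "numeric", S = "numeric", n = "integer")
)

setValidity("RadialPSD", function(object) {
    msg <- character()
    if (length(object@u) != length(object@S) ||
        length(object@u) != length(object@n))
        msg <- c(msg, "'u', 'S' and 'n' must have equal length")
    if (is.unsorted(object@u, strictly = TRUE))
        msg <- c(msg, "'u' must be strictly increasing")
    ok <- object@n > 0L
    if (any(object@S[ok] < 0, na.rm = TRUE))
        msg <- c(msg, "'S' must be non-negative where n > 0")
    if (length(msg)) msg else TRUE
})

#' SectorSpec: an azimuthal sector about a frequency axis
#'
#' Selects 2-D PSD samples whose azimuth lies within `halfAngle`
#' degrees of the chosen axis (both half-planes, so the sector and its
#' point reflection). Used for directional resolution estimates; ±30°
#' is the conventional choice.
#'
#' @slot axis "x" (horizontal) or "y" (vertical)
#' @slot halfAngle azimuthal half-width [degrees], in (0, 45]
#' @export
setClass("SectorSpec",
    representation(axis = "character", halfAngle = "numeric")
)

setValidity("SectorSpec", function(object) {
    if (!object@axis %in% c("x", "y"))
        return("'axis' must be \"x\" or \"y\"")
    if (object@halfAngle <= 0 || object@halfAngle > 45)
        return("'halfAngle' must be in (0, 45] degrees")
    TRUE
})

#' FitRange: a closed spatial-frequency interval
#'
#' @slot uLo,uHi lower and upper frequency bounds [1/µm], 0 < uLo < uHi
#' @export
setClass("FitRange", representation(uLo = "numeric", uHi = "numeric"))

setValidity("FitRange", function(object) {
    if (!(object@uLo > 0 && object@uHi > object@uLo))
        return("need 0 < uLo < uHi")
    TRUE
})

#' PowerLawFit: fitted power-law signal trend of a radial PSD
#'
#' Parameters of the log-log linear signal trend
#' \eqn{S(u_r) \approx P u_r^a}: amplitude `P`, slope `a` (negative for
#' real image structure), the frequency range fitted and the number of
#' bins used. `valid` is FALSE when the fitted slope is non-negative
#' (as happens on pure-noise images); such a fit cannot define a knee.
#'
#' @slot P power-law amplitude [power units]
#' @slot a log-log slope (dimensionless)
#' @slot range the [FitRange] used
#' @slot nPoints number of bins in the fit
#' @slot valid TRUE when a < 0
#' @export
setClass("PowerLawFit",
    representation(P = "numeric", a = "numeric", range = "FitRange",
                   nPoints = "integer", valid = "logical")
)

setValidity("PowerLawFit", function(object) {
    if (object@P <= 0) return("'P' must be positive")
    if (object@nPoints < 2L) return("'nPoints' must be >= 2")
    TRUE
})

#' NoiseFloor: flat noise-floor estimate of a radial PSD
#'
#' The Poisson noise floor \eqn{S_{nf}}: the average of binned PSD
#' values over frequencies above the approximate knee, where
#' uncorrelated counting noise dominates and the spectrum is flat.
#'
#' @slot Snf mean floor power [power units]
#' @slot range the [FitRange] averaged over
#' @slot nPoints number of bins averaged
#' @export
setClass("NoiseFloor",
    representation(Snf = "numeric", range = "FitRange", nPoints = "integer")
)

setValidity("NoiseFloor", function(object) {
    if (object@Snf <= 0) return("'Snf' must be positive")
    if (object@nPoints < 1L) return("'nPoints' must be >= 1")
    TRUE
})

#' ResolutionResult: knee and SNR-thresholded resolution estimates
#'
#' The frequency \eqn{u_{knee}} where the fitted signal trend meets the
#' noise floor, the resolution frequency \eqn{u_{res}} where the trend
#' equals \eqn{SNR_{res} \cdot S_{nf}}, and the corresponding
#' half-period spatial resolutions \eqn{\delta = 1/(2u)}. With the
#' Rose-criterion default \eqn{SNR_{res} = 5}, \eqn{u_{res} \le
#' u_{knee}} and \eqn{\delta_{res} \ge \delta_{knee}}.
#'
#' @slot uKnee,uRes knee and resolution frequencies [1/µm]
#' @slot deltaKnee,deltaRes half-period resolutions 1/(2u) [µm]
#' @slot snrRes the signal-to-noise threshold used
#' @slot fit the [PowerLawFit] used
#' @slot floor the [NoiseFloor] used
#' @export
setClass("ResolutionResult",
    representation(uKnee = "numeric", uRes = "numeric",
                   deltaKnee = "numeric", deltaRes = "numeric",
                   snrRes = "numeric", fit = "PowerLawFit",
                   floor = "NoiseFloor")
)

setValidity("ResolutionResult", function(object) {
    msg <- character()
    if (object@snrRes <= 0) msg <- c(msg, "'snrRes' must be positive")
    if (object@snrRes >= 1 &&
        object@uRes > object@uKnee * (1 + 1e-12))
        msg <- c(msg, "uRes must not exceed uKnee when snrRes >= 1")
    if (length(msg)) msg else TRUE
})

#' WienerCurve: sampled Wiener filter
#'
#' \eqn{W(u) = S(u) / (S(u) + S_{nf})} with \eqn{S(u) = P u^a}. For a
#' decaying trend (a < 0), W decreases monotonically from ~1 at low
#' frequency to ~0 in the noise-dominated region and equals exactly 1/2
#' at the knee.
#'
#' @slot u frequency samples [1/µm]
#' @slot W filter values in [0, 1]
#' @export
setClass("WienerCurve", representation(u = "numeric", W = "numeric"))

setValidity("WienerCurve", function(object) {
    if (length(object@u) != length(object@W))
        return("'u' and 'W' must have equal length")
    if (any(object@W < 0 | object@W > 1))
        return("'W' must lie in [0, 1]")
    TRUE
})

#' DetectorGeometry: multi-element fluorescence detector geometry
#'
#' @slot Nd number of active detector elements
#' @slot Aact active area per element [mm²]
#' @slot dEff effective sample-to-detector-plane distance [mm]
#' @export
setClass("DetectorGeometry",
    representation(Nd = "numeric", Aact = "numeric", dEff = "numeric")
)

setValidity("DetectorGeometry", function(object) {
    msg <- character()
    if (object@Nd < 1 || object@Nd != round(object@Nd))
        msg <- c(msg, "'Nd' must be a positive integer")
    if (object@Aact <= 0) msg <- c(msg, "'Aact' must be positive")
    if (object@dEff <= 0) msg <- c(msg, "'dEff' must be positive")
    if (length(msg)) msg else TRUE
})

#' LodEstimate: empirical limit-of-detection estimate
#'
#' Result of the blank-histogram comparison: the dwell-time width
#' correction applied to the blank scan, the concentration threshold
#' above which at most `fpTolerance` corrected blank pixels lie, and
#' the realized false-positive count at that threshold.
#'
#' @slot threshold concentration threshold [µg/cm²]
#' @slot widthCorrection \eqn{(t_{blank}/t_{sample})^{1/2}}
#' @slot fpCount corrected blank pixels strictly above the threshold
#' @export
setClass("LodEstimate",
    representation(threshold = "numeric", widthCorrection = "numeric",
                   fpCount = "integer")
)

setValidity("LodEstimate", function(object) {
    if (object@widthCorrection <= 0)
        return("'widthCorrection' must be positive")
    TRUE
})
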