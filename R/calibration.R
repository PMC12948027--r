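#' @include AllClasses.R
NULL

#' Absolute photon flux from a calibrated photodiode reading
#'
#' Converts a PIN-photodiode preamplifier voltage into absolute
#' incident photon flux. The voltage times the preamplifier gain
#' sensitivity \eqn{g_s} [µA/V] gives the photocurrent in µA; scaled
#' to pA and multiplied by the diode's photon-flux-to-photocurrent
#' conversion factor \eqn{K(E)} [photons/pA/s] it yields
#' \deqn{\Phi = (V - V_{dark}) \, g_s \, 10^6 \, K(E).}
#' Dark voltage is subtracted even though it is typically under 1% of
#' the signal. \eqn{K} is a supplied calibration constant for the
#' diode at the working photon energy (2382 photons/pA/s for the
#' reference diode at 10 keV).
#'
#' @param V preamplifier output voltage [V]
#' @param gainSensitivity \eqn{g_s} [µA/V]
#' @param K photon-flux-to-photocurrent conversion [photons/pA/s]
#' @param darkV dark voltage [V]
#' @return photon flux [photons/s]
#' @examples
#' photonFlux(1, gainSensitivity = 1)  # 2.382e9 photons/s
#' @export
photonFlux <- function(V, gainSensitivity, K = 2382, darkV = 0) {
    stopifnot(gainSensitivity > 0, K > 0)
    if (any(V <= darkV))
        stop("invalid signal: voltage must exceed the dark voltage")
    (V - darkV) * gainSensitivity * 1e6 * K
}

#' Effective beam width on a tilted sample
#'
#' A planar sample mounted at angle \eqn{\theta} to normal incidence
#' sees the beam broadened along the scan direction to
#' \eqn{\tilde W = W_{beam} / \cos\theta}. Typical SFXM mounts use
#' 15° or 45° as a compromise between fluorescence self-absorption
#' and beam broadening.
#'
#' @param Wbeam beam width at normal incidence [µm]
#' @param theta sample tilt from normal incidence [degrees], in
#'   [0, 90)
#' @return effective beam width [µm]
#' @export
effectiveBeamWidth <- function(Wbeam, theta) {
    stopifnot(Wbeam > 0)
    if (theta < 0 || theta >= 90)
        stop("invalid geometry: theta must be in [0, 90) degrees")
    Wbeam / cos(theta * pi / 180)
}

#' Fit the effective detector distance from displacement series
#'
#' The detected fluorescence intensity at detector displacement
#' \eqn{\Delta d} along the detection axis follows an inverse-square
#' law \eqn{I(\Delta d) = \alpha / (d_{eff} + \Delta d)^2}. A
#' linearized ordinary least squares fit of \eqn{I^{-1/2}} against
#' \eqn{\Delta d} (slope \eqn{1/\sqrt\alpha}, intercept
#' \eqn{d_{eff}/\sqrt\alpha}) provides starting values, refined by a
#' Levenberg–Marquardt pass on the untransformed model; with exact
#' three-point data both agree.
#'
#' @param displacement detector displacements \eqn{\Delta d} [mm],
#'   >= 3 distinct values
#' @param intensity mean fluorescence intensities [counts/s], > 0
#' @return list with `dEff` [mm] and `alpha`
#' @examples
#' dd <- c(0, 3, 6)
#' fitDetectorDistance(dd, 1 / (14.4 + dd)^2)
#' @export
fitDetectorDistance <- function(displacement, intensity) {
    stopifnot(length(displacement) == length(intensity))
    if (length(unique(displacement)) < 3L)
        stop("need >= 3 distinct displacements")
    if (any(intensity <= 0)) stop("intensities must be positive")
    y <- 1 / sqrt(intensity)
    co <- stats::coef(stats::lm(y ~ displacement))
    slope <- unname(co[2L]); intercept <- unname(co[1L])
    if (!is.finite(slope) || slope <= 0 || intercept / slope <= 0)
        stop("fit failure: data are not compatible with a decaying ",
             "inverse-square law (effective distance not positive)")
    d0 <- intercept / slope
    a0 <- 1 / slope^2
    fit <- try(minpack.lm::nlsLM(
        intensity ~ alpha / (dEff + displacement)^2,
        start = list(alpha = a0, dEff = d0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
    if (!inherits(fit, "try-error")) {
        p <- stats::coef(fit)
        if (is.finite(p[["dEff"]]) && p[["dEff"]] > 0) {
            d0 <- unname(p[["dEff"]]); a0 <- unname(p[["alpha"]])
        }
    }
    list(dEff = d0, alpha = a0)
}

#' Construct a DetectorGeometry
#' @param Nd number of active detector elements
#' @param Aact active area per element [mm²]
#' @param dEff effective sample-to-detector-plane distance [mm]
#' @return a [DetectorGeometry-class]
#' @export
DetectorGeometry <- function(Nd, Aact, dEff) {
    new("DetectorGeometry", Nd = as.numeric(Nd),
        Aact = as.numeric(Aact), dEff = as.numeric(dEff))
}

#' Effective solid angle of collection
#'
#' Planar small-solid-angle approximation
#' \eqn{\Omega_{eff} = N_d A_{act} / d_{eff}^2} for a multi-element
#' detector with \eqn{N_d} active elements of area \eqn{A_{act}}
#' each, at effective distance \eqn{d_{eff}}. Per-element obliquity
#' corrections are not applied.
#'
#' @param g a [DetectorGeometry], or `Nd` if the three scalars are
#'   given directly
#' @param Aact,dEff used when `g` is given as `Nd`
#' @return effective solid angle [sr]
#' @examples
#' solidAngle(DetectorGeometry(7, 40, 14.4))   # ~1.35 sr
#' solidAngle(3, 42.5, 31.2)                   # ~0.13 sr
#' @export
solidAngle <- function(g, Aact = NULL, dEff = NULL) {
    if (!is(g, "DetectorGeometry"))
        g <- DetectorGeometry(g, Aact, dEff)
    g@Nd * g@Aact / g@dEff^2
}

setMethod("show", "DetectorGeometry", function(object) {
    cat(sprintf(
        "DetectorGeometry: %d x %.3g mm^2 at d_eff = %.3g mm (Omega_eff = %.3g sr)\n",
        as.integer(object@Nd), object@Aact, object@dEff,
        solidAngle(object)))
})

#' Probe beam area from directional resolutions
#'
#' Approximates the probe area as the ellipse
#' \eqn{A_{beam} = \pi \, \delta_x \delta_y}, which reduces to
#' \eqn{\pi \delta^2} for a symmetric probe (where the resolution
#' equals the radius of the first Airy minimum).
#'
#' @param deltaX,deltaY directional spatial resolutions [µm]
#' @return beam area [µm²]
#' @export
beamArea <- function(deltaX, deltaY = deltaX) {
    stopifnot(deltaX > 0, deltaY > 0)
    pi * deltaX * deltaY
}

#' Fluence per time and fluence on the sample
#'
#' `fluenceRate()` divides the absolute photon flux by the probe
#' area; `fluence()` multiplies the rate by the per-pixel dwell time
#' to give the cumulative photons per area delivered to each scan
#' position.
#'
#' @param phi photon flux [photons/s]
#' @param area probe beam area [µm²] (see [beamArea()])
#' @return fluence rate [photons/µm²/s]
#' @examples
#' fluenceRate(7.7e9, beamArea(6.9, 6.4))       # ~5.6e7
#' fluence(fluenceRate(7.7e9, beamArea(6.9, 6.4)), 0.05)
#' @export
fluenceRate <- function(phi, area) {
    stopifnot(phi > 0, area > 0)
    phi / area
}

#' @rdname fluenceRate
#' @param rate fluence rate [photons/µm²/s]
#' @param dwell per-pixel dwell time [s]
#' @return `fluence()`: fluence [photons/µm²]
#' @export
fluence <- function(rate, dwell) {
    stopifnot(rate > 0, dwell > 0)
    rate * dwell
}

#' Empirical limit of detection from sample and blank histograms
#'
#' Compares low-concentration pixels of a sample map against a blank
#' scan (a region known to be free of the element). Because counting
#' statistics scale with dwell time, the blank distribution is first
#' widened about its mean by
#' \eqn{(t_{blank}/t_{sample})^{1/2}} to emulate the sample's photon
#' statistics. The detection threshold is the smallest concentration
#' exceeded by at most `fpTolerance` corrected blank pixels — an
#' empirical estimate, not a rigorous detection-limit construction.
#'
#' @param samplePixels low-concentration sample pixel values
#'   [µg/cm²]
#' @param blankPixels blank-scan pixel values [µg/cm²]
#' @param tSample,tBlank dwell times of the two scans [s]
#' @param fpTolerance maximum tolerated false-positive blank pixels
#'   (default 0)
#' @return a [LodEstimate-class]
#' @examples
#' lodEstimate(rnorm(500, 0.1, 0.05), rnorm(400, 0, 0.01),
#'             tSample = 0.05, tBlank = 0.2)
#' @export
lodEstimate <- function(samplePixels, blankPixels, tSample, tBlank,
                        fpTolerance = 0L) {
    stopifnot(length(samplePixels) > 0L, length(blankPixels) > 0L,
              tSample > 0, tBlank > 0, fpTolerance >= 0L)
    if (length(blankPixels) < 100L)
        warning("fewer than 100 blank pixels: threshold estimate ",
                "has low statistics")
    wc <- sqrt(tBlank / tSample)
    corrected <- mean(blankPixels) +
        (blankPixels - mean(blankPixels)) * wc
    k <- as.integer(fpTolerance)
    srt <- sort(corrected, decreasing = TRUE)
    ## smallest c with #{corrected > c} <= k  =>  the (k+1)-th largest
    threshold <- if (k + 1L <= length(srt)) srt[k + 1L] else srt[length(srt)]
    new("LodEstimate", threshold = threshold, widthCorrection = wc,
        fpCount = sum(corrected > threshold))
}

#' Histogram table for limit-of-detection inspection
#'
#' Returns binned counts of the sample pixels and the dwell-corrected
#' blank pixels on a common grid, for export/plotting alongside
#' [lodEstimate()].
#'
#' @inheritParams lodEstimate
#' @param breaks number of histogram bins (default 50)
#' @return data.frame with columns `mid`, `sample`, `blankCorrected`
#' @export
lodHistograms <- function(samplePixels, blankPixels, tSample, tBlank,
                          breaks = 50L) {
    wc <- sqrt(tBlank / tSample)
    corrected <- mean(blankPixels) +
        (blankPixels - mean(blankPixels)) * wc
    rng <- range(c(samplePixels, corrected))
    edges <- seq(rng[1L], rng[2L], length.out = breaks + 1L)
    hs <- graphics::hist(samplePixels, breaks = edges, plot = FALSE)
    hb <- graphics::hist(corrected, breaks = edges, plot = FALSE)
    data.frame(mid = hs$mids, sample = hs$counts,
               blankCorrected = hb$counts)
}

setMethod("show", "LodEstimate", function(object) {
    cat(sprintf(
        "LodEstimate: threshold %.4g ug/cm^2 (width correction %.3g, %d false positives)\n",
        object@threshold, object@widthCorrection, object@fpCount))
})
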