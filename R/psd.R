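#' @include ElementalMap-methods.R
NULL

## DFT sample frequencies in cycles per unit length, DFT ordering
## (0, positive, negative). For even n the axis spans -1/(2*delta) to
## +(n/2 - 1)/(n*delta).
fftFreq <- function(n, delta) {
    k <- seq_len(n) - 1L
    k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
    k / (n * delta)
}

#' Two-dimensional power spectral density
#'
#' Computes \eqn{S(u_x, u_y) = |\Psi(u_x, u_y)|^2} from the signed
#' amplitude \eqn{\psi(x, y)} via the unnormalized forward discrete
#' Fourier transform. Only PSD ratios (signal trend over noise floor)
#' enter the resolution estimate, so the overall transform
#' normalization is immaterial; the unnormalized forward convention is
#' used and satisfies the discrete Parseval identity
#' \eqn{\sum |\Psi|^2 = N_{tot} \sum \psi^2}.
#'
#' Both dimensions must be even (so the frequency axes take the
#' standard asymmetric form); call [padToEven()] on the concentration
#' map first.
#'
#' @param amp an [AmplitudeMap] (or an [ElementalMap], which is
#'   passed through [signedAmplitude()] first)
#' @return a [PowerSpectrum2D]
#' @examples
#' m <- ElementalMap(matrix(rexp(64), 8, 8), dx = 1, dy = 1)
#' S2 <- psd2d(signedAmplitude(m))
#' @export
psd2d <- function(amp) {
    if (is(amp, "ElementalMap")) amp <- signedAmplitude(amp)
    stopifnot(is(amp, "AmplitudeMap"))
    v <- amp@values
    ny <- nrow(v); nx <- ncol(v)
    if (ny %% 2L == 1L || nx %% 2L == 1L)
        stop("psd2d() requires even dimensions; apply padToEven() ",
             "to the map first (got ", ny, " x ", nx, ")")
    S <- Mod(stats::fft(v))^2
    new("PowerSpectrum2D", values = S,
        ux = fftFreq(nx, amp@dx), uy = fftFreq(ny, amp@dy))
}

## radial frequency u_r = sqrt(ux^2 + uy^2) for every 2-D sample
radialFreqGrid <- function(S2) {
    sqrt(outer(S2@uy^2, S2@ux^2, "+"))
}

defaultNBins <- function(S2) {
    min(64L, floor(min(length(S2@ux), length(S2@uy)) / 2))
}

## shared binning core: average `S2@values[mask]` into linear radial
## bins over (0, umax]
radialBin <- function(S2, mask, nBins, excludeDC, warnEmpty = TRUE) {
    ur <- radialFreqGrid(S2)
    if (excludeDC) mask <- mask & ur > 0
    umax <- max(ur)
    edges <- seq(0, umax, length.out = nBins + 1L)
    ## (0, e1], (e1, e2], ...; DC (u_r = 0) falls into bin 1 when kept
    idx <- findInterval(ur, edges, left.open = TRUE,
                        rightmost.closed = TRUE)
    idx[ur == 0] <- 1L
    idx[!mask] <- NA_integer_
    keep <- !is.na(idx)
    n <- tabulate(idx[keep], nbins = nBins)
    Ssum <- rep(0, nBins)
    agg <- vapply(split(S2@values[keep], idx[keep]), sum, numeric(1))
    Ssum[as.integer(names(agg))] <- agg
    S <- ifelse(n > 0L, Ssum / n, NA_real_)
    if (warnEmpty && any(n == 0L))
        warning(sum(n == 0L), " of ", nBins,
                " radial bins received no frequency samples; ",
                "they are flagged with n = 0")
    new("RadialPSD", u = (edges[-1L] + edges[-(nBins + 1L)]) / 2,
        S = S, n = as.integer(n))
}

#' Azimuthally averaged radial power spectral density
#'
#' Bins every 2-D PSD sample by its radial spatial frequency
#' \eqn{u_r = \sqrt{u_x^2 + u_y^2}} (computed on the physical
#' frequency grid, so anisotropic pixel pitch is handled correctly)
#' into linear bins over \eqn{(0, u_{max}]} and averages within bins.
#' The DC sample is excluded by default: it dwarfs the power-law trend
#' and carries no resolution information.
#'
#' @param S2 a [PowerSpectrum2D]
#' @param nBins number of radial bins (default
#'   `min(64, floor(min(Nx, Ny)/2))`)
#' @param excludeDC drop the zero-frequency sample (default TRUE)
#' @return a [RadialPSD]
#' @export
azimuthalAverage <- function(S2, nBins = NULL, excludeDC = TRUE) {
    stopifnot(is(S2, "PowerSpectrum2D"))
    if (is.null(nBins)) nBins <- defaultNBins(S2)
    nBins <- as.integer(nBins)
    if (nBins < 2L) stop("'nBins' must be >= 2")
    radialBin(S2, mask = array(TRUE, dim(S2@values)), nBins = nBins,
              excludeDC = excludeDC)
}

#' Construct a SectorSpec
#' @param axis "x" or "y": the frequency axis the sector straddles
#' @param halfAngle azimuthal half-width in degrees (0, 45]; ±30° is
#'   the conventional choice
#' @return a [SectorSpec-class]
#' @export
SectorSpec <- function(axis = c("x", "y"), halfAngle = 30) {
    axis <- match.arg(axis)
    new("SectorSpec", axis = axis, halfAngle = as.numeric(halfAngle))
}

## TRUE for samples whose azimuth lies within halfAngle of the axis
## (both half-planes). Angles from the true physical frequencies.
sectorMask <- function(S2, sector) {
    ang <- atan2(abs(outer(S2@uy, rep(1, length(S2@ux)))),
                 abs(outer(rep(1, length(S2@uy)), S2@ux))) * 180 / pi
    if (sector@axis == "x") ang <= sector@halfAngle
    else ang >= 90 - sector@halfAngle
}

#' Sector-restricted radial power spectral density
#'
#' As [azimuthalAverage()], but using only 2-D samples whose azimuth
#' lies within `halfAngle` degrees of the chosen frequency axis (and
#' its point reflection). Averaging about the \eqn{u_x} axis probes
#' structure along x, giving the directional resolution
#' \eqn{\delta_{res,x}}, and likewise for y.
#'
#' @inheritParams azimuthalAverage
#' @param sector a [SectorSpec]
#' @return a [RadialPSD]; bins where the sector contains no samples
#'   are flagged with n = 0
#' @export
sectorAverage <- function(S2, sector, nBins = NULL, excludeDC = TRUE) {
    stopifnot(is(S2, "PowerSpectrum2D"), is(sector, "SectorSpec"))
    if (is.null(nBins)) nBins <- defaultNBins(S2)
    nBins <- as.integer(nBins)
    if (nBins < 2L) stop("'nBins' must be >= 2")
    ## empty sector bins are routine (a sector does not reach the
    ## corner radii); they are flagged via n = 0 without a warning
    radialBin(S2, mask = sectorMask(S2, sector), nBins = nBins,
              excludeDC = excludeDC, warnEmpty = FALSE)
}

#' @describeIn RadialPSD-class coerce to a data.frame with columns
#'   `u`, `S`, `n`
#' @param x a RadialPSD
#' @param ... ignored
#' @export
as.data.frame.RadialPSD <- function(x, ...) {
    data.frame(u = x@u, S = x@S, n = x@n)
}

setMethod("show", "RadialPSD", function(object) {
    cat(sprintf("RadialPSD: %d bins, u in (%.4g, %.4g] 1/um, %d empty\n",
                length(object@u), 0, max(object@u),
                sum(object@n == 0L)))
})

setMethod("show", "PowerSpectrum2D", function(object) {
    cat(sprintf(
        "PowerSpectrum2D: %d x %d samples, |ux| <= %.4g, |uy| <= %.4g 1/um\n",
        nrow(object@values), ncol(object@values),
        max(abs(object@ux)), max(abs(object@uy))))
})
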