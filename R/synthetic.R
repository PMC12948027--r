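#' @include psd.R
NULL

## Run expr with a local RNG seeded at `seed`, restoring the caller's
## RNG state afterwards; generators are bit-reproducible from (args,
## seed) and never disturb the session stream.
withLocalSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

## zero-mean random field with isotropic power-law PSD of the given
## log-log slope, unit standard deviation
powerlawField <- function(ny, nx, dx, dy, slope) {
    ux <- fftFreq(nx, dx); uy <- fftFreq(ny, dy)
    ur <- sqrt(outer(uy^2, ux^2, "+"))
    H <- ur^(slope / 2)
    H[1L, 1L] <- 0                       # zero DC: zero-mean field
    wn <- matrix(stats::rnorm(ny * nx), ny, nx)
    ## filtering the DFT of real white noise keeps Hermitian symmetry
    f <- Re(stats::fft(stats::fft(wn) * H, inverse = TRUE)) / (ny * nx)
    f / stats::sd(f)
}

#' Generate a phantom elemental map with power-law spectral structure
#'
#' Builds a non-negative concentration field whose azimuthally
#' averaged PSD declines log-log linearly with radial frequency at
#' (approximately) the requested slope — the spectral structure of
#' natural images that the resolution method assumes — optionally
#' with Gaussian hotspots emulating localized Ca foci. The field is
#' `amplitude * (1 + relFluct * f)` for a unit-variance power-law
#' field f, clipped at zero; `relFluct = 0.3` gives
#' tissue-realistic contrast with negligible clipping.
#'
#' @param shape c(Ny, Nx) grid size in pixels
#' @param dx,dy pixel pitch [µm]
#' @param spectralSlope target PSD log-log slope (< 0)
#' @param amplitude mean concentration [µg/cm²]
#' @param relFluct relative fluctuation amplitude of the field
#' @param hotspotCount number of Gaussian hotspots (default 0)
#' @param hotspotFwhm hotspot FWHM [µm]
#' @param hotspotPeak peak hotspot concentration above background
#'   [µg/cm²] (default `5 * amplitude`)
#' @param element,dwell metadata for the returned map
#' @param seed integer random seed; output is bit-reproducible given
#'   the seed and does not disturb the caller's RNG stream
#' @return an [ElementalMap]
#' @examples
#' ph <- makePhantom(shape = c(128, 128), spectralSlope = -3, seed = 1)
#' @export
makePhantom <- function(shape = c(128L, 128L), dx = 1, dy = 1,
                        spectralSlope = -3, amplitude = 1,
                        relFluct = 0.3, hotspotCount = 0L,
                        hotspotFwhm = 10, hotspotPeak = 5 * amplitude,
                        element = "Ca", dwell = 0.05, seed = 1L) {
    stopifnot(spectralSlope < 0, amplitude > 0, relFluct >= 0,
              length(shape) == 2L, all(shape >= 4L))
    ny <- as.integer(shape[1L]); nx <- as.integer(shape[2L])
    withLocalSeed(seed, {
        f <- powerlawField(ny, nx, dx, dy, spectralSlope)
        C <- amplitude * (1 + relFluct * f)
        if (hotspotCount > 0L) {
            xs <- stats::runif(hotspotCount, 1, nx)
            ys <- stats::runif(hotspotCount, 1, ny)
            sx <- hotspotFwhm / (2 * sqrt(2 * log(2))) / dx
            sy <- hotspotFwhm / (2 * sqrt(2 * log(2))) / dy
            col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
            row <- matrix(seq_len(ny), ny, nx)
            for (i in seq_len(hotspotCount))
                C <- C + hotspotPeak *
                    exp(-((col - xs[i])^2 / (2 * sx^2) +
                          (row - ys[i])^2 / (2 * sy^2)))
        }
        ElementalMap(pmax(C, 0), dx = dx, dy = dy,
                     element = element, dwell = dwell)
    })
}

## spectral Gaussian blur with periodic boundaries; sigma in µm
gaussianBlur <- function(v, dx, dy, fwhmX, fwhmY) {
    if (fwhmX <= 0 && fwhmY <= 0) return(v)
    sx <- fwhmX / (2 * sqrt(2 * log(2)))
    sy <- fwhmY / (2 * sqrt(2 * log(2)))
    ux <- fftFreq(ncol(v), dx); uy <- fftFreq(nrow(v), dy)
    H <- exp(-2 * pi^2 * outer(sy^2 * uy^2, sx^2 * ux^2, "+"))
    Re(stats::fft(stats::fft(v) * H, inverse = TRUE)) / length(v)
}

#' Simulate an SFXM scan of a phantom map
#'
#' Emulates the measurement chain that produces a fitted
#' concentration map: the true field is blurred by a Gaussian focal
#' spot of the stated FWHMs, expected fluorescence counts per pixel
#' are \eqn{\lambda = c_u C t_{dwell} + b t_{dwell}} (with
#' `countsPerUnit` \eqn{c_u} detected counts per unit concentration
#' per second and `backgroundRate` b background counts per second),
#' observed counts are Poisson, and the known expected background is
#' subtracted before converting back to concentration. Empty pixels
#' therefore fluctuate on either side of zero, exactly as
#' background-subtracted spectrum-fitting output does.
#'
#' @param map the ground-truth [ElementalMap]
#' @param psfFwhmX,psfFwhmY focal-spot FWHM along x and y [µm]
#' @param dwell per-pixel dwell time [s] (default: the map's)
#' @param countsPerUnit expected detected counts per (µg/cm²)·s
#' @param backgroundRate expected background counts per second
#' @param seed integer random seed (local, reproducible)
#' @return an [ElementalMap] of estimated concentrations
#' @export
simulateScan <- function(map, psfFwhmX = 6, psfFwhmY = 6,
                         dwell = dwellTime(map),
                         countsPerUnit = 1000, backgroundRate = 50,
                         seed = 1L) {
    stopifnot(is(map, "ElementalMap"), psfFwhmX >= 0, psfFwhmY >= 0,
              dwell > 0, countsPerUnit > 0, backgroundRate >= 0)
    blurred <- gaussianBlur(map@values, map@dx, map@dy,
                            psfFwhmX, psfFwhmY)
    lambda <- pmax(countsPerUnit * blurred, 0) * dwell +
        backgroundRate * dwell
    counts <- withLocalSeed(seed,
        matrix(stats::rpois(length(lambda), lambda),
               nrow(lambda), ncol(lambda)))
    est <- (counts - backgroundRate * dwell) / (countsPerUnit * dwell)
    ElementalMap(est, dx = map@dx, dy = map@dy,
                 element = map@element, dwell = dwell)
}

#' Generate a radial PSD from the power-law-plus-floor model
#'
#' Direct generative twin of the fitted model: \eqn{S(u) = (P u^a +
#' S_{nf}) X_u} with independent mean-one multiplicative fluctuations
#' \eqn{X_u \sim \chi^2_{df}/df}, the sampling law of an average of
#' `scatterDf` periodogram samples per bin. `scatterDf = Inf` gives
#' the noiseless curve.
#'
#' @param P,a power-law amplitude and slope (a < 0)
#' @param Snf noise-floor level (>= 0)
#' @param u frequency samples [1/µm], all > 0
#' @param scatterDf chi-squared degrees of freedom of the per-bin
#'   scatter (default Inf: none)
#' @param seed integer random seed (local, reproducible)
#' @return a [RadialPSD] with `n` set to the per-bin sample count the
#'   scatter models
#' @export
makePowerlawPsd <- function(P, a, Snf, u, scatterDf = Inf, seed = 1L) {
    stopifnot(P > 0, a < 0, Snf >= 0, all(u > 0))
    mu <- P * u^a + Snf
    X <- if (is.finite(scatterDf)) {
        withLocalSeed(seed,
            stats::rchisq(length(u), df = scatterDf) / scatterDf)
    } else rep(1, length(u))
    n <- if (is.finite(scatterDf)) max(1L, as.integer(round(scatterDf)))
         else 1L
    new("RadialPSD", u = as.numeric(u), S = mu * X,
        n = rep(n, length(u)))
}
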