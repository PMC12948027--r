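#' @include AllGenerics.R
NULL

#' Construct an ElementalMap
#'
#' @param values numeric matrix of areal mass concentrations
#'   [µg/cm²]; negative pixels are allowed (background-subtracted
#'   empty pixels fluctuate on either side of zero)
#' @param dx,dy pixel pitch along x (columns) and y (rows) [µm]
#' @param element chemical symbol (e.g. "Ca")
#' @param dwell per-pixel exposure time [s]
#' @return an [ElementalMap-class] object
#' @examples
#' m <- ElementalMap(matrix(rexp(12), 3, 4), dx = 1, dy = 2,
#'                   element = "Ca", dwell = 0.05)
#' pixelPitch(m)
#' @export
ElementalMap <- function(values, dx, dy, element = "X", dwell = 1) {
    if (is.data.frame(values)) values <- as.matrix(values)
    if (!is.matrix(values)) values <- as.matrix(values)
    storage.mode(values) <- "double"
    new("ElementalMap", values = values, dx = as.numeric(dx),
        dy = as.numeric(dy), element = as.character(element),
        dwell = as.numeric(dwell))
}

#' @rdname mapValues
#' @export
setMethod("mapValues", "ElementalMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "AmplitudeMap", function(x) x@values)

#' @rdname mapValues
#' @export
setMethod("mapValues", "PowerSpectrum2D", function(x) x@values)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ElementalMap",
          function(x) c(dx = x@dx, dy = x@dy))

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "AmplitudeMap",
          function(x) c(dx = x@dx, dy = x@dy))

#' @rdname elementLabel
#' @export
setMethod("elementLabel", "ElementalMap", function(x) x@element)

#' @rdname dwellTime
#' @export
setMethod("dwellTime", "ElementalMap", function(x) x@dwell)

setMethod("show", "ElementalMap", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "ElementalMap (%s): %d x %d pixels, pitch %.3g x %.3g um, dwell %.3g s\n",
        object@element, d[1], d[2], object@dx, object@dy, object@dwell))
    cat(sprintf("  concentration range [%.4g, %.4g] ug/cm^2\n",
                min(object@values), max(object@values)))
})

setMethod("show", "AmplitudeMap", function(object) {
    d <- dim(object@values)
    cat(sprintf("AmplitudeMap: %d x %d pixels, pitch %.3g x %.3g um\n",
                d[1], d[2], object@dx, object@dy))
})

#' @describeIn signedAmplitude signed square root of a concentration
#'   map: \eqn{\psi = \mathrm{sign}(C) \sqrt{|C|}}. Squaring the
#'   result elementwise recovers \eqn{|C|}.
#' @export
setMethod("signedAmplitude", "ElementalMap", function(map) {
    v <- map@values
    new("AmplitudeMap", values = sign(v) * sqrt(abs(v)),
        dx = map@dx, dy = map@dy)
})

#' @describeIn padToEven append one row and/or column filled with the
#'   average low signal level so both dimensions are even. The
#'   low-signal fill is the mean of the lowest `decile` of pixel
#'   values, a proxy for the local background that avoids injecting a
#'   sharp edge; a numeric `fill` overrides it. Even-dimension input
#'   is returned unchanged.
#' @export
setMethod("padToEven", "ElementalMap",
          function(map, fill = "low-decile", decile = 0.1) {
    v <- map@values
    ny <- nrow(v); nx <- ncol(v)
    if (ny %% 2L == 0L && nx %% 2L == 0L) return(map)
    fillval <- if (is.numeric(fill)) {
        fill
    } else {
        q <- stats::quantile(v, probs = decile, names = FALSE)
        low <- v[v <= q]
        mean(low)
    }
    if (ny %% 2L == 1L) v <- rbind(v, rep(fillval, ncol(v)))
    if (nx %% 2L == 1L) v <- cbind(v, rep(fillval, nrow(v)))
    ElementalMap(v, dx = map@dx, dy = map@dy,
                 element = map@element, dwell = map@dwell)
})
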