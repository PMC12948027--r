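#' @include AllClasses.R
NULL

#' Extract the numeric grid of a map or spectrum
#' @param x an ElementalMap, AmplitudeMap or PowerSpectrum2D
#' @return numeric matrix
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Pixel pitch of a map
#' @param x an ElementalMap or AmplitudeMap
#' @return named numeric vector c(dx = , dy = ) in µm
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' Element label of a map
#' @param x an ElementalMap
#' @return chemical symbol string
#' @export
setGeneric("elementLabel", function(x) standardGeneric("elementLabel"))

#' Per-pixel dwell time of a map
#' @param x an ElementalMap
#' @return dwell time in seconds
#' @export
setGeneric("dwellTime", function(x) standardGeneric("dwellTime"))

#' Signed square-root amplitude transform
#'
#' @param map an [ElementalMap]
#' @return an [AmplitudeMap]
#' @seealso [psd2d()]
#' @export
setGeneric("signedAmplitude",
           function(map) standardGeneric("signedAmplitude"))

#' Pad a map to even dimensions
#'
#' @param map an [ElementalMap]
#' @param fill fill value for appended rows/columns; default
#'   `"low-decile"` uses the mean of the lowest decile of pixel values
#' @param decile fraction of lowest pixels defining the low-signal
#'   level (default 0.1)
#' @return an [ElementalMap] with even dimensions
#' @export
setGeneric("padToEven",
           function(map, fill = "low-decile", decile = 0.1)
               standardGeneric("padToEven"))
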