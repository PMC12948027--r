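#' @include ElementalMap-methods.R
NULL

sidecarPath <- function(path) paste0(path, ".yaml")

readSidecar <- function(path) {
    sc <- sidecarPath(path)
    if (!file.exists(sc))
        stop("missing metadata: sidecar file '", sc, "' not found; ",
             "pixel pitch must be stated explicitly, never defaulted")
    meta <- yaml::read_yaml(sc)
    for (k in c("dx", "dy"))
        if (is.null(meta[[k]]))
            stop("missing metadata: '", k, "' absent from sidecar '",
                 sc, "'")
    meta
}

writeSidecar <- function(path, map, extra = list()) {
    meta <- c(list(dx = map@dx, dy = map@dy,
                   element = map@element, dwell = map@dwell), extra)
    yaml::write_yaml(meta, sidecarPath(path))
}

#' Read an elemental concentration map
#'
#' Reads a 2-D map plus metadata from one of three layouts:
#' \describe{
#'   \item{CSV}{headerless numeric grid, with a YAML sidecar
#'     `<path>.yaml` holding `dx`, `dy`, `element`, `dwell`.}
#'   \item{TIFF}{single-page 32-bit float image with the same YAML
#'     sidecar. Because float TIFF samples are stored rescaled to
#'     [0, 1], the sidecar additionally records `value_min` and
#'     `value_max`, which the reader inverts.}
#'   \item{HDF5}{a 2-D dataset (default name `"map"`) with attributes
#'     `dx`, `dy`, `element`, `dwell`; requires the rhdf5 package.}
#' }
#' Missing pixel-pitch metadata is an error, never a silent default.
#'
#' @param path file path; format inferred from the extension
#'   (.csv, .tif/.tiff, .h5/.hdf5) unless `format` is given
#' @param dataset HDF5 dataset name (default "map")
#' @param format one of "csv", "tiff", "hdf5" (default: by extension)
#' @return an [ElementalMap]
#' @seealso [writeElementalMap()]
#' @export
readElementalMap <- function(path, dataset = "map", format = NULL) {
    if (!file.exists(path)) stop("cannot read '", path, "'")
    format <- if (is.null(format)) formatFromExt(path) else
        match.arg(format, c("csv", "tiff", "hdf5"))
    switch(format,
        csv = {
            meta <- readSidecar(path)
            v <- as.matrix(utils::read.csv(path, header = FALSE))
            dimnames(v) <- NULL
            mapFromMeta(v, meta)
        },
        tiff = {
            meta <- readSidecar(path)
            v <- tiff::readTIFF(path)
            if (length(dim(v)) != 2L)
                stop("dimensionality error: expected a single-channel ",
                     "2-D TIFF, got dims ",
                     paste(dim(v), collapse = " x "))
            lo <- meta$value_min; hi <- meta$value_max
            if (!is.null(lo) && !is.null(hi))
                v <- if (hi > lo) v * (hi - lo) + lo else v * 0 + lo
            mapFromMeta(v, meta)
        },
        hdf5 = {
            requireHdf5()
            v <- rhdf5::h5read(path, dataset)
            if (length(dim(v)) != 2L)
                stop("dimensionality error: dataset '", dataset,
                     "' is not 2-D (dims ",
                     paste(dim(v), collapse = " x "), ")")
            at <- rhdf5::h5readAttributes(path, dataset)
            for (k in c("dx", "dy"))
                if (is.null(at[[k]]))
                    stop("missing metadata: attribute '", k,
                         "' absent from dataset '", dataset, "'")
            mapFromMeta(t(v), at)   # h5read returns x-fastest layout
        })
}

mapFromMeta <- function(v, meta) {
    ElementalMap(v, dx = as.numeric(meta$dx), dy = as.numeric(meta$dy),
                 element = if (is.null(meta$element)) "X"
                           else as.character(meta$element),
                 dwell = if (is.null(meta$dwell)) 1
                         else as.numeric(meta$dwell))
}

formatFromExt <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           csv = "csv", tif = "tiff", tiff = "tiff",
           h5 = "hdf5", hdf5 = "hdf5",
           stop("cannot infer map format from extension '.", ext,
                "'; pass 'format'"))
}

requireHdf5 <- function() {
    if (!requireNamespace("rhdf5", quietly = TRUE))
        stop("HDF5 map I/O needs the 'rhdf5' package; ",
             "use the CSV or TIFF layout instead")
}

#' Write an elemental concentration map
#'
#' Mirror of [readElementalMap()]: writes the grid in the chosen
#' layout and the metadata sidecar (CSV/TIFF) or dataset attributes
#' (HDF5). A write followed by a read reproduces the map (exactly
#' for CSV/HDF5, to float32 precision for TIFF).
#'
#' @param map an [ElementalMap]
#' @inheritParams readElementalMap
#' @return `path`, invisibly
#' @export
writeElementalMap <- function(map, path, dataset = "map",
                              format = NULL) {
    stopifnot(is(map, "ElementalMap"))
    format <- if (is.null(format)) formatFromExt(path) else
        match.arg(format, c("csv", "tiff", "hdf5"))
    switch(format,
        csv = {
            utils::write.table(map@values, path, sep = ",",
                               row.names = FALSE, col.names = FALSE)
            writeSidecar(path, map)
        },
        tiff = {
            v <- map@values
            lo <- min(v); hi <- max(v)
            scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
            tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
            writeSidecar(path, map,
                         extra = list(value_min = lo, value_max = hi))
        },
        hdf5 = {
            requireHdf5()
            if (file.exists(path)) unlink(path)
            rhdf5::h5createFile(path)
            rhdf5::h5write(t(map@values), path, dataset)
            fid <- rhdf5::H5Fopen(path)
            did <- rhdf5::H5Dopen(fid, dataset)
            rhdf5::h5writeAttribute(map@dx, did, "dx")
            rhdf5::h5writeAttribute(map@dy, did, "dy")
            rhdf5::h5writeAttribute(map@element, did, "element")
            rhdf5::h5writeAttribute(map@dwell, did, "dwell")
            rhdf5::H5Dclose(did)
            rhdf5::H5Fclose(fid)
        })
    invisible(path)
}

#' Export / read a radial PSD as CSV
#'
#' Three columns `u`, `S`, `n`: bin-center radial frequency [1/µm],
#' mean binned power, and the number of 2-D frequency samples per
#' bin (0 marks an empty bin, with S empty/NA).
#'
#' @param psd a [RadialPSD]
#' @param path output CSV path
#' @return `path` invisibly (`exportRadialPSD`); a [RadialPSD]
#'   (`readRadialPSD`)
#' @export
exportRadialPSD <- function(psd, path) {
    stopifnot(is(psd, "RadialPSD"))
    utils::write.csv(as.data.frame(psd), path, row.names = FALSE)
    invisible(path)
}

#' @rdname exportRadialPSD
#' @export
readRadialPSD <- function(path) {
    df <- utils::read.csv(path)
    stopifnot(all(c("u", "S", "n") %in% names(df)))
    new("RadialPSD", u = df$u, S = df$S, n = as.integer(df$n))
}
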