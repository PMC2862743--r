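sidecarPath <- function(path)
    paste0(tools::file_path_sans_ext(path), ".json")

guessFormat <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext, tif = , tiff = "tiff", csv = "csv", raw = , bin = "raw",
        stop("cannot guess carpet format from extension '", ext,
             "'; pass 'format' explicitly"))
}

readSidecar <- function(path, need_dims = FALSE) {
    sp <- sidecarPath(path)
    if (!file.exists(sp))
        stop("metadata sidecar not found: ", sp)
    meta <- jsonlite::fromJSON(sp)
    req <- c("pixel_size_um", "pixel_dwell_s", "line_period_s")
    if (need_dims) req <- c(req, "n_lines", "n_pixels")
    for (f in req)
        if (is.null(meta[[f]]) || !is.numeric(meta[[f]]))
            stop("sidecar ", sp, " is missing required field '", f, "'")
    meta
}

#' Read a line-scan carpet from disk
#'
#' Supported formats: single-page 16-bit grayscale TIFF (rows = scan lines),
#' header-less integer CSV, and raw little-endian uint32 (row-major). Scan
#' metadata comes from a JSON sidecar with the same basename and extension
#' \code{.json}, holding \code{pixel_size_um}, \code{pixel_dwell_s},
#' \code{line_period_s}, optionally \code{labels} (per column) and, for raw
#' files, \code{n_lines} / \code{n_pixels}. Missing metadata is an error,
#' never silently defaulted.
#'
#' @param path file to read.
#' @param format \code{"auto"} (by extension), \code{"tiff"}, \code{"csv"}
#'   or \code{"raw"}.
#' @return a \linkS4class{LineScanCarpet}.
#' @seealso [saveCarpet()]
#' @export
loadCarpet <- function(path, format = c("auto", "tiff", "csv", "raw")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") format <- guessFormat(path)
    meta <- readSidecar(path, need_dims = (format == "raw"))
    cts <- switch(format,
        tiff = {
            img <- tiff::readTIFF(path, as.is = TRUE)
            if (length(dim(img)) != 2L)
                stop("malformed TIFF: expected a single-page grayscale image")
            img
        },
        csv = {
            dt <- data.table::fread(path, header = FALSE, sep = ",")
            as.matrix(dt)
        },
        raw = {
            n <- meta$n_lines * meta$n_pixels
            con <- file(path, "rb")
            on.exit(close(con))
            v <- readBin(con, "integer", n = n, size = 4, endian = "little")
            if (length(v) != n)
                stop("malformed raw file: expected ", n, " uint32 values, got ",
                     length(v))
            matrix(v, nrow = meta$n_lines, byrow = TRUE)
        })
    if (any(!is.finite(cts)))
        stop("malformed carpet file: non-finite values in 'counts'")
    if (any(cts < 0))
        stop("validation error: negative values in 'counts'")
    if (any(cts != round(cts)))
        stop("validation error: non-integer values in 'counts'")
    dimnames(cts) <- NULL
    LineScanCarpet(cts, pixelSize = meta$pixel_size_um,
        pixelDwell = meta$pixel_dwell_s, linePeriod = meta$line_period_s,
        labels = if (!is.null(meta$labels)) meta$labels else NULL)
}

#' Write a line-scan carpet to disk
#'
#' Persists counts bit-exactly together with a JSON metadata sidecar (see
#' [loadCarpet()] for the format). TIFF storage is 16-bit, so counts above
#' 65535 must use the raw format.
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param path output file; the sidecar is written next to it.
#' @param format \code{"auto"}, \code{"tiff"}, \code{"csv"} or \code{"raw"}.
#' @return \code{path}, invisibly.
#' @export
saveCarpet <- function(x, path, format = c("auto", "tiff", "csv", "raw")) {
    stopifnot(is(x, "LineScanCarpet"))
    format <- match.arg(format)
    if (format == "auto") format <- guessFormat(path)
    cts <- x@counts
    switch(format,
        tiff = {
            if (max(cts) > 65535)
                stop("counts exceed 65535 and cannot be stored as 16-bit ",
                     "TIFF; use format = 'raw'")
            storage.mode(cts) <- "double"
            tiff::writeTIFF(cts / 65535, path, bits.per.sample = 16L,
                compression = "none")
        },
        csv = {
            data.table::fwrite(data.table::as.data.table(cts), path,
                col.names = FALSE)
        },
        raw = {
            if (max(cts) > .Machine$integer.max)
                stop("counts exceed the 32-bit range supported by raw output")
            con <- file(path, "wb")
            on.exit(close(con))
            writeBin(as.integer(t(cts)), con, size = 4, endian = "little")
        })
    meta <- list(pixel_size_um = x@pixelSize, pixel_dwell_s = x@pixelDwell,
        line_period_s = x@linePeriod, n_lines = nLines(x),
        n_pixels = nPixels(x))
    if (any(x@columnLabels != "unknown")) meta$labels <- x@columnLabels
    jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
        digits = NA)
    invisible(path)
}
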