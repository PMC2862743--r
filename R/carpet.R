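#' Construct a line-scan carpet
#'
#' @param counts non-negative integer-valued matrix, rows = scan lines (time),
#'   columns = pixels along the line.
#' @param pixelSize pixel spacing, um.
#' @param pixelDwell per-pixel sampling time, s.
#' @param linePeriod time between successive lines, s.
#' @param labels optional per-column compartment labels
#'   (nucleus|cytoplasm|barrier|unknown); defaults to \code{"unknown"}.
#' @param acquisitionStart acquisition start time, s.
#' @return a \linkS4class{LineScanCarpet}.
#' @examples
#' cpt <- LineScanCarpet(matrix(0L, 100, 4), pixelSize = 0.1,
#'                       pixelDwell = 6.3e-6, linePeriod = 4.73e-4)
#' dim(cpt)
#' @export
LineScanCarpet <- function(counts, pixelSize, pixelDwell, linePeriod,
                           labels = NULL, acquisitionStart = 0) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- if (max(counts) <= .Machine$integer.max &&
                                all(counts == round(counts))) "integer"
                            else "double"
    if (is.null(labels)) labels <- rep("unknown", ncol(counts))
    new("LineScanCarpet", counts = counts, pixelSize = pixelSize,
        pixelDwell = pixelDwell, linePeriod = linePeriod,
        columnLabels = as.character(labels),
        acquisitionStart = acquisitionStart)
}

#' @describeIn LineScanCarpet photon-count matrix accessor
#' @param object a \code{LineScanCarpet}
#' @export
setMethod("counts", "LineScanCarpet", function(object) object@counts)

#' @export
setMethod("nLines", "LineScanCarpet", function(x) nrow(x@counts))
#' @export
setMethod("nPixels", "LineScanCarpet", function(x) ncol(x@counts))
#' @export
setMethod("pixelSize", "LineScanCarpet", function(x) x@pixelSize)
#' @export
setMethod("pixelDwell", "LineScanCarpet", function(x) x@pixelDwell)
#' @export
setMethod("linePeriod", "LineScanCarpet", function(x) x@linePeriod)
#' @export
setMethod("columnLabels", "LineScanCarpet", function(x) x@columnLabels)
#' @export
setReplaceMethod("columnLabels", "LineScanCarpet", function(x, value) {
    x@columnLabels <- as.character(value)
    validObject(x)
    x
})

#' Physical positions of the pixel columns
#'
#' Column \code{i} maps to \code{(i - 1) * pixelSize} um (left edge of the
#' scan is position 0).
#' @param x a \linkS4class{LineScanCarpet}
#' @export
setMethod("columnPositions", "LineScanCarpet",
    function(x) (seq_len(nPixels(x)) - 1) * x@pixelSize)

#' @export
setMethod("dim", "LineScanCarpet", function(x) dim(x@counts))

setMethod("show", "LineScanCarpet", function(object) {
    cat(sprintf(
        "LineScanCarpet: %d lines x %d pixels\n", nLines(object), nPixels(object)))
    cat(sprintf("  pixel size %.4g um, dwell %.4g us, line period %.4g ms\n",
        object@pixelSize, object@pixelDwell * 1e6, object@linePeriod * 1e3))
    cat(sprintf("  duration %.3g s, mean count %.4g / pixel\n",
        nLines(object) * object@linePeriod, mean(object@counts)))
    lb <- unique(object@columnLabels)
    cat(sprintf("  labels: %s\n", paste(lb, collapse = ", ")))
})

#' Extract a contiguous block of scan lines
#'
#' Correlation analysis assumes a stationary record; in practice one selects
#' a sub-segment (typically ~30 s) free of slow intensity drift. Line
#' indices are 1-based and inclusive.
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param startLine,endLine first and last line to keep (1-based, inclusive).
#' @return a carpet with \code{endLine - startLine + 1} lines and unchanged
#'   metadata.
#' @examples
#' cpt <- LineScanCarpet(matrix(0L, 100, 4), 0.1, 6.3e-6, 4.73e-4)
#' nLines(selectSegment(cpt, 11, 60))
#' @export
selectSegment <- function(x, startLine, endLine) {
    stopifnot(is(x, "LineScanCarpet"))
    if (!(startLine >= 1 && startLine <= endLine && endLine <= nLines(x)))
        stop("invalid segment: need 1 <= startLine <= endLine <= nLines")
    initialize(x, counts = x@counts[startLine:endLine, , drop = FALSE],
        acquisitionStart = x@acquisitionStart +
            (startLine - 1) * x@linePeriod)
}

#' Per-column stationarity quality control
#'
#' Slow drift of the mean intensity (photobleaching, movement of the
#' envelope) biases correlation curves; drifting columns should be excluded
#' or re-segmented. The drift metric per column is
#' (max windowed mean - min windowed mean) / grand mean over non-overlapping
#' windows of \code{windowLines} lines; a column passes when the metric is
#' below \code{threshold}.
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param windowLines window length in lines (>= 2, <= nLines / 4).
#' @param threshold pass/fail drift threshold (default 0.2).
#' @return data.frame with \code{column}, \code{metric}, \code{empty}
#'   (all-zero column, metric defined as 0) and \code{pass}.
#' @export
stationarityReport <- function(x, windowLines, threshold = 0.2) {
    stopifnot(is(x, "LineScanCarpet"))
    n <- nLines(x)
    if (windowLines < 2 || windowLines > n / 4)
        stop("'windowLines' must be >= 2 and <= nLines / 4")
    nw <- n %/% windowLines
    idx <- rep(seq_len(nw), each = windowLines)
    res <- lapply(seq_len(nPixels(x)), function(j) {
        col <- as.numeric(x@counts[seq_len(nw * windowLines), j])
        g <- mean(as.numeric(x@counts[, j]))
        if (g == 0) return(c(metric = 0, empty = 1))
        wm <- vapply(split(col, idx), mean, numeric(1))
        c(metric = (max(wm) - min(wm)) / g, empty = 0)
    })
    res <- do.call(rbind, res)
    data.frame(column = seq_len(nPixels(x)), metric = res[, "metric"],
        empty = res[, "empty"] > 0, pass = res[, "metric"] < threshold)
}

#' Nuclear / cytoplasmic concentration ratio
#'
#' Keq, the steady-state partition coefficient, estimated as the ratio of
#' the mean intensity over nucleus-labeled columns to the mean over
#' cytoplasm-labeled columns (fluorescence is proportional to
#' concentration).
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param labels per-column labels; defaults to \code{columnLabels(x)}.
#' @return positive finite ratio.
#' @export
concentrationRatio <- function(x, labels = columnLabels(x)) {
    stopifnot(is(x, "LineScanCarpet"))
    if (length(labels) != nPixels(x))
        stop("'labels' must have one entry per column")
    nuc <- which(labels == "nucleus")
    cyt <- which(labels == "cytoplasm")
    if (!length(nuc) || !length(cyt))
        stop("both 'nucleus' and 'cytoplasm' label groups must be non-empty")
    m_nuc <- mean(x@counts[, nuc])
    m_cyt <- mean(x@counts[, cyt])
    if (m_cyt == 0)
        stop("undefined ratio: cytoplasm mean intensity is zero")
    m_nuc / m_cyt
}
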