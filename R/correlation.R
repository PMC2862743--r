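MIN_LINES_CORR <- 1024L

# multi-tau lag-grid depth: deepest level keeps the longest lag below a
# quarter of the record so every estimate averages many fluctuations
maxMultitauLevel <- function(nLines) {
    lev <- 0L
    while (32 * 2^(lev + 1) <= nLines / 4) lev <- lev + 1L
    lev
}

# The estimator, spelled out: both channels are co-binned by the level's
# factor (non-overlapping means), then at binned lag j
#   G = <A_head B_tail> / (<A_head> <B_tail>) - 1,
# head = bins [1, nb-j], tail = bins [j+1, nb]. The symmetric (head/tail)
# normalization halves drift bias relative to whole-record normalization.
directCorrelator <- function(a, b, maxLevel) {
    lag_lines <- integer(0); bins <- integer(0); vals <- numeric(0)
    for (lev in 0:maxLevel) {
        bin <- 2L^lev
        nb <- length(a) %/% bin
        ab <- .colMeans(a[seq_len(nb * bin)], bin, nb)
        bb <- .colMeans(b[seq_len(nb * bin)], bin, nb)
        for (j in (if (lev == 0) 1:32 else 17:32)) {
            h <- ab[seq_len(nb - j)]
            t <- bb[(j + 1):nb]
            mh <- mean(h); mt <- mean(t)
            if (mh == 0 || mt == 0)
                stop("correlation normalization undefined: window mean is zero")
            vals <- c(vals, mean(h * t) / (mh * mt) - 1)
            lag_lines <- c(lag_lines, j * bin)
            bins <- c(bins, bin)
        }
    }
    list(lag_lines = lag_lines, bin = bins, value = vals)
}

#' Pair correlation function of two pixel columns
#'
#' Cross-correlates the intensity record of the origin column with that of
#' the target column at logarithmically spaced lags: the pCF. Its peak lag
#' is the average time a molecule takes to travel from origin to target;
#' for separations beyond the PSF waist the earliest lags are
#' anti-correlated (the same molecule cannot be in two places at once) and
#' the curve rises to a maximum at the transit time. \code{target == origin}
#' gives the ACF exactly.
#'
#' The estimator is \eqn{G(\tau) = \langle \delta F_o(t) \delta F_t(t+\tau)
#' \rangle / (\langle F_o \rangle_{head} \langle F_t \rangle_{tail})} with
#' symmetric head/tail normalization, computed on a multi-tau grid (32
#' unit-spaced lags, then 16 lags per octave with factor-2 co-binning of
#' both channels). \code{scheme = "direct"} evaluates the identical
#' estimator by exhaustive summation in R and serves as the oracle for the
#' C++ multi-tau path. Reported lag values are
#' \code{k * linePeriod + (target - origin) * pixelDwell}: the intra-line
#' sampling offset between the two columns is included.
#'
#' @param x a \linkS4class{LineScanCarpet} with >= 1024 lines.
#' @param origin,target 1-based column indices.
#' @param scheme \code{"multitau"} (default) or \code{"direct"}.
#' @return a \linkS4class{CorrelationCurve}.
#' @examples
#' res <- simulateCarpet(simConfig(nLines = 2048, nParticles = 30, seed = 5))
#' computePCF(carpet(res), 4, 9)
#' @export
computePCF <- function(x, origin, target, scheme = c("multitau", "direct")) {
    stopifnot(is(x, "LineScanCarpet"))
    scheme <- match.arg(scheme)
    n <- nLines(x)
    if (n < MIN_LINES_CORR)
        stop("need at least ", MIN_LINES_CORR, " lines for correlation")
    for (cl in c(origin, target))
        if (cl < 1 || cl > nPixels(x))
            stop("column index out of range: ", cl)
    a <- as.numeric(x@counts[, origin])
    b <- as.numeric(x@counts[, target])
    if (mean(a) == 0 || mean(b) == 0)
        stop("correlation normalization undefined: column mean is zero")
    lev <- maxMultitauLevel(n)
    out <- if (scheme == "multitau") cpp_multitau(a, b, lev)
           else directCorrelator(a, b, lev)
    delta <- as.integer(target - origin)
    new("CorrelationCurve",
        lags = out$lag_lines * x@linePeriod + delta * x@pixelDwell,
        values = out$value, sd = numeric(0), deltaPixels = delta,
        deltaUm = delta * x@pixelSize,
        sourceColumns = as.integer(c(origin, target)),
        nLinesUsed = n, binFactor = as.integer(out$bin),
        linePeriod = x@linePeriod, pixelSize = x@pixelSize)
}

#' Autocorrelation function of one pixel column
#'
#' Per-column ACF: \code{computePCF(x, column, column, scheme)}. G(0) is
#' inversely proportional to the mean number of molecules in the focal
#' volume at that pixel; the decay time reflects the local diffusion
#' coefficient.
#'
#' @inheritParams computePCF
#' @param column 1-based column index.
#' @return a \linkS4class{CorrelationCurve} with \code{deltaPixels = 0}.
#' @export
computeACF <- function(x, column, scheme = c("multitau", "direct"))
    computePCF(x, column, column, scheme = match.arg(scheme))

#' @export
setMethod("lags", "CorrelationCurve", function(x) x@lags)
#' @export
setMethod("corrValues", "CorrelationCurve", function(x) x@values)
#' @export
setMethod("deltaPixels", "CorrelationCurve", function(x) x@deltaPixels)
#' @export
setMethod("deltaUm", "CorrelationCurve", function(x) x@deltaUm)
#' @export
setMethod("length", "CorrelationCurve", function(x) length(x@lags))

setMethod("show", "CorrelationCurve", function(object) {
    cat(sprintf(
        "CorrelationCurve: pCF(%d) of columns (%d -> %d), %d lags [%.3g, %.3g] s\n",
        object@deltaPixels, object@sourceColumns[1], object@sourceColumns[2],
        length(object@lags), min(object@lags), max(object@lags)))
    cat(sprintf("  delta = %.3g um, G range [%.3g, %.3g], %d lines\n",
        object@deltaUm, min(object@values), max(object@values),
        object@nLinesUsed))
})

#' Pair-correlation carpet at a fixed pixel separation
#'
#' One pCF curve per origin column at signed separation \code{delta}
#' (\code{delta = 0} reproduces the per-column ACF carpet). Origins default
#' to every column whose target \code{origin + delta} is inside the line.
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param delta signed pixel separation (target - origin).
#' @param columns origin columns (default: all valid).
#' @param scheme correlator scheme, as in [computePCF()].
#' @return a \linkS4class{CorrelationCarpet}.
#' @export
pcfCarpet <- function(x, delta, columns = NULL,
                      scheme = c("multitau", "direct")) {
    stopifnot(is(x, "LineScanCarpet"))
    scheme <- match.arg(scheme)
    delta <- as.integer(delta)
    np <- nPixels(x)
    if (is.null(columns))
        columns <- seq_len(np)[seq_len(np) + delta >= 1 &
                               seq_len(np) + delta <= np]
    columns <- as.integer(columns)
    if (!length(columns)) stop("no valid origin columns for delta = ", delta)
    if (any(columns + delta < 1 | columns + delta > np))
        stop("origin + delta outside the scanned line for some columns")
    cvs <- lapply(columns, function(o)
        computePCF(x, o, o + delta, scheme = scheme))
    new("CorrelationCarpet", curves = cvs, origins = columns,
        deltaPixels = delta, lags = cvs[[1]]@lags)
}

#' @export
setMethod("curves", "CorrelationCarpet", function(x) x@curves)
#' @export
setMethod("origins", "CorrelationCarpet", function(x) x@origins)
#' @export
setMethod("lags", "CorrelationCarpet", function(x) x@lags)
#' @export
setMethod("deltaPixels", "CorrelationCarpet", function(x) x@deltaPixels)
#' @export
setMethod("length", "CorrelationCarpet", function(x) length(x@curves))

setMethod("show", "CorrelationCarpet", function(object)
    cat(sprintf(
        "CorrelationCarpet: pCF(%d), %d origin columns [%d..%d], %d lags\n",
        object@deltaPixels, length(object@curves), min(object@origins),
        max(object@origins), length(object@lags))))

#' Average correlation curves over a column block
#'
#' Arithmetic mean of curves sharing one lag grid and pixel separation
#' (e.g. a 3-pixel column block, or every pair spanning the envelope). For
#' averages over 8 or more curves the across-curve standard deviation is
#' retained and used as inverse-variance weights by [fitACF()].
#'
#' @param x a \linkS4class{CorrelationCarpet}, or a list of
#'   \linkS4class{CorrelationCurve} objects.
#' @param columns optional subset of origin columns (carpet input only).
#' @param requireSameDelta set \code{FALSE} to pool curves computed at
#'   different pixel separations (e.g. every pair spanning the envelope at
#'   12-20 px): their lag grids differ only by the intra-line offset
#'   (microseconds), so values are averaged on the first curve's grid and
#'   the result keeps that curve's separation metadata.
#' @return a \linkS4class{CorrelationCurve}.
#' @export
averageCurves <- function(x, columns = NULL, requireSameDelta = TRUE) {
    if (is(x, "CorrelationCarpet")) {
        cvs <- x@curves
        if (!is.null(columns)) {
            keep <- match(as.integer(columns), x@origins)
            if (anyNA(keep)) stop("requested origin column not in the carpet")
            cvs <- cvs[keep]
        }
    } else cvs <- x
    if (!length(cvs)) stop("no curves to average")
    ref <- cvs[[1]]
    for (cv in cvs) {
        if (requireSameDelta && cv@deltaPixels != ref@deltaPixels)
            stop("curves do not share a common pixel separation")
        if (length(cv@lags) != length(ref@lags) ||
            (requireSameDelta && !isTRUE(all.equal(cv@lags, ref@lags))))
            stop("curves do not share a common lag grid")
    }
    vm <- vapply(cvs, function(cv) cv@values, numeric(length(ref@values)))
    vm <- matrix(vm, nrow = length(ref@values))
    avg <- rowMeans(vm)
    # per-lag scatter across members doubles as inverse-variance fit
    # weights; with few members the 2-sample variance is too unstable to
    # weight with, so it is only retained for 8 or more curves
    sdv <- if (ncol(vm) >= 8) apply(vm, 1, stats::sd) else numeric(0)
    initialize(ref, values = avg, sd = sdv,
        sourceColumns = ref@sourceColumns,
        nLinesUsed = min(vapply(cvs, function(cv) cv@nLinesUsed, integer(1))))
}

#' Divide out a slow intensity trend from one column record
#'
#' Divides the series by its centered moving average and rescales to the
#' original mean, removing drift slower than the window while preserving
#' fast fluctuations. Off by default throughout the package: the preferred
#' control for drift is segment selection after [stationarityReport()].
#'
#' @param series numeric intensity record of one column.
#' @param windowLines moving-average window, >= 16 lines.
#' @return detrended series of the same length and mean.
#' @export
detrendColumn <- function(series, windowLines) {
    if (windowLines < 16) stop("'windowLines' must be >= 16")
    n <- length(series)
    if (n < windowLines) stop("series shorter than the detrend window")
    h <- floor(windowLines / 2)
    cs <- cumsum(c(0, as.numeric(series)))
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    ma <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    if (any(ma <= 0))
        stop("moving average reaches zero; cannot detrend")
    series / ma * mean(series)
}
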