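gaussianSmooth <- function(v, sigma) {
    h <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-h):h / sigma)^2)
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
        lo <- max(1L, i - h); hi <- min(n, i + h)
        kk <- k[(lo - i + h + 1L):(hi - i + h + 1L)]
        out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
}

#' Locate the correlation maximum ("the hump") of a pCF curve
#'
#' The transit-time readout uses only the average position in time of the
#' correlation maximum: the curve is smoothed with a Gaussian kernel over
#' the (approximately log-spaced) lag bins and the argmax over
#' \code{tau >= tauMin} is taken. \code{tauMin} (default 2 line periods)
#' excludes the shot-noise / anti-correlation region from the search. The
#' amplitude is the smoothed maximum's topographic prominence: its height
#' above the level the hump rises from (the lower of the pre-peak minimum
#' inside the search window and the early-segment median - for transit
#' humps that level is the anti-correlation dip). Significance is that
#' amplitude over a MAD-based noise scale from the earliest
#' (anti-correlated or flat) segment; below \code{significanceThreshold}
#' the curve is declared to have no peak - the no-communication signature
#' of an impenetrable gap.
#'
#' @param curve a \linkS4class{CorrelationCurve}.
#' @param tauMin earliest lag searched, s (default \code{2 * linePeriod}).
#' @param tauMax latest lag searched, s (default: no bound). Bounding the
#'   search to the physically expected delay window protects the argmax
#'   from spurious very-long-lag structure, where the estimator averages
#'   few fluctuations.
#' @param smoothingBins Gaussian kernel sigma, in lag bins (default 2).
#' @param significanceThreshold minimum amplitude / noise ratio (default 3,
#'   giving >= 95 percent rejection of pure-noise curves).
#' @return list with \code{found}, \code{tauPeak} (argmax lag, s, NA when
#'   not found), \code{tauMean} (log-lag centroid of the hump's
#'   above-baseline region - the average position in time of the hump),
#'   \code{amplitude},
#'   \code{significance}.
#' @export
detectPeak <- function(curve, tauMin = NULL, tauMax = NULL,
                       smoothingBins = 2, significanceThreshold = 3) {
    stopifnot(is(curve, "CorrelationCurve"))
    v <- curve@values
    L <- curve@lags
    if (length(v) < 4 * smoothingBins + 3)
        stop("curve shorter than the smoothing window")
    if (is.null(tauMin)) tauMin <- 2 * curve@linePeriod
    s <- gaussianSmooth(v, smoothingBins)
    if (is.null(tauMax)) tauMax <- Inf
    search <- which(L >= tauMin & L <= tauMax)
    if (!length(search)) stop("no lags inside the [tauMin, tauMax] window")
    early <- v[L < tauMin]
    if (length(early) >= 4) {
        noise <- stats::mad(early)
        baseline <- stats::median(early)
    } else {
        # too few pre-window lags to characterize the early segment (the
        # hump starts within the first few lags): the uncorrelated level 0
        # is the baseline and the whole-curve scatter bounds the noise
        # (estimator noise is correlated across neighboring lags, so the
        # smoothing residual would understate it)
        noise <- stats::mad(v)
        baseline <- 0
    }
    if (noise == 0) noise <- stats::sd(v)
    noise <- max(noise, .Machine$double.eps)
    i <- search[which.max(s[search])]
    baseline <- min(c(s[search[search <= i]], baseline))
    amp <- s[i] - baseline
    sig <- amp / noise
    found <- is.finite(sig) && amp > 0 && sig >= significanceThreshold
    # average position in time of the hump: excess-correlation-weighted
    # log-lag centroid of the contiguous above-baseline region around the
    # maximum; far more stable than the bare argmax when the hump spans a
    # decade in lag
    tauMean <- NA_real_
    if (found) {
        lo <- i
        while (lo > search[1] && s[lo - 1] > baseline) lo <- lo - 1
        hi <- i
        last <- search[length(search)]
        while (hi < last && s[hi + 1] > baseline) hi <- hi + 1
        reg <- lo:hi
        w <- pmax(s[reg] - baseline, 0)
        tauMean <- exp(sum(w * log(L[reg])) / sum(w))
    }
    list(found = found, tauPeak = if (found) L[i] else NA_real_,
         tauMean = tauMean, amplitude = amp, significance = sig)
}

#' Transit-time map of a pair-correlation carpet
#'
#' Runs [detectPeak()] on every origin column and classifies each into
#' \code{intra} (delay consistent with intracompartment transit),
#' \code{barrier_delayed} (delay more than \code{ratioThreshold} times the
#' median intra delay - the envelope-crossing signature),
#' \code{no_communication} (no significant maximum, the impenetrable-gap
#' signature) or \code{unstable} (failed stationarity QC). All thresholds
#' are recorded on the result.
#'
#' @param cc a \linkS4class{CorrelationCarpet}.
#' @param barrierColumn barrier position: the plane lies between this
#'   column and the next (NA = no barrier known).
#' @param intraReference origin columns used for the intra delay reference;
#'   default: all origins whose pair does not span the barrier. Must not
#'   straddle the barrier.
#' @param qcFail origin columns that failed stationarity QC.
#' @param ratioThreshold barrier-delay ratio threshold (default 10, safely
#'   between intra scatter and the 40-100x ratios of envelope crossings).
#' @param tauMin,tauMax,smoothingBins,significanceThreshold passed to
#'   [detectPeak()].
#' @return a \linkS4class{TransitMap}.
#' @export
transitMap <- function(cc, barrierColumn = NA, intraReference = NULL,
                       qcFail = integer(0), ratioThreshold = 10,
                       tauMin = NULL, tauMax = NULL, smoothingBins = 2,
                       significanceThreshold = 3) {
    stopifnot(is(cc, "CorrelationCarpet"))
    org <- cc@origins
    delta <- cc@deltaPixels
    spans <- if (is.na(barrierColumn)) rep(FALSE, length(org))
        else if (delta >= 0) org <= barrierColumn & org + delta > barrierColumn
        else org > barrierColumn & org + delta <= barrierColumn
    if (is.null(intraReference)) {
        intraReference <- org[!spans]
    } else {
        intraReference <- as.integer(intraReference)
        if (!is.na(barrierColumn) && any(spans[match(intraReference, org)]))
            stop("'intraReference' columns must not straddle the barrier")
    }
    pk <- lapply(cc@curves, detectPeak, tauMin = tauMin, tauMax = tauMax,
        smoothingBins = smoothingBins,
        significanceThreshold = significanceThreshold)
    tau <- vapply(pk, function(p) p$tauPeak, numeric(1))
    found <- vapply(pk, function(p) p$found, logical(1))
    ref_tau <- tau[org %in% intraReference & found]
    med_intra <- if (length(ref_tau)) stats::median(ref_tau) else NA_real_
    cls <- character(length(org))
    for (i in seq_along(org)) {
        cls[i] <- if (org[i] %in% qcFail) "unstable"
        else if (!found[i]) "no_communication"
        else if (!is.na(med_intra) && tau[i] > ratioThreshold * med_intra)
            "barrier_delayed"
        else "intra"
    }
    px <- cc@curves[[1]]@pixelSize
    tab <- data.frame(column = org, position_um = (org - 1) * px,
        tau_peak_s = tau,
        amplitude = vapply(pk, function(p) p$amplitude, numeric(1)),
        significance = vapply(pk, function(p) p$significance, numeric(1)),
        class = cls, spans_barrier = spans)
    eff_taumin <- if (is.null(tauMin)) 2 * cc@curves[[1]]@linePeriod else tauMin
    new("TransitMap", table = tab, deltaPixels = delta,
        thresholds = list(tauMin = eff_taumin,
            tauMax = if (is.null(tauMax)) Inf else tauMax,
            smoothingBins = smoothingBins,
            significanceThreshold = significanceThreshold,
            ratioThreshold = ratioThreshold, medianIntraTau = med_intra),
        barrierColumn = as.numeric(barrierColumn))
}

#' @export
setMethod("transitTable", "TransitMap", function(x) x@table)
#' @export
setMethod("deltaPixels", "TransitMap", function(x) x@deltaPixels)

setMethod("show", "TransitMap", function(object) {
    tb <- object@table
    cat(sprintf("TransitMap: pCF(%d), %d origin columns\n",
        object@deltaPixels, nrow(tb)))
    for (cl in c("intra", "barrier_delayed", "no_communication", "unstable")) {
        n <- sum(tb$class == cl)
        if (n) cat(sprintf("  %-16s %d\n", cl, n))
    }
    if (!is.na(object@thresholds$medianIntraTau))
        cat(sprintf("  median intra delay %.3g ms\n",
            object@thresholds$medianIntraTau * 1e3))
})

#' Barrier index: delay ratio across versus within a compartment
#'
#' Ratio of the median peak delay of barrier-spanning column pairs to the
#' median intra-compartment peak delay at the same pixel separation.
#' Envelope-limited transport shows ratios of tens to a hundred; the index
#' is the sentinel \code{NA} (never 1) when either group is empty.
#'
#' @param map a \linkS4class{TransitMap} built with a barrier column.
#' @return positive ratio, or NA when undefined.
#' @export
barrierIndex <- function(map) {
    stopifnot(is(map, "TransitMap"))
    tb <- map@table
    ok <- !is.na(tb$tau_peak_s)
    span_tau <- tb$tau_peak_s[ok & tb$spans_barrier]
    intra_tau <- tb$tau_peak_s[ok & !tb$spans_barrier & tb$class == "intra"]
    if (!length(span_tau) || !length(intra_tau)) return(NA_real_)
    stats::median(span_tau) / stats::median(intra_tau)
}

#' Direction-resolved cross-barrier transit analysis
#'
#' The pCF is directional: correlating an origin with a target further
#' along the scan (positive separation) reads out left-to-right transport,
#' and the reverse orientation reads out right-to-left transport. With the
#' nucleus on the left, \code{forward} is nucleus-to-cytoplasm and
#' \code{backward} cytoplasm-to-nucleus. For purely passive exchange the
#' two directions agree (detailed balance); a directional carrier channel
#' shortens delays in its direction only.
#'
#' @param x a \linkS4class{LineScanCarpet}.
#' @param delta positive pixel separation magnitude.
#' @param barrierColumn barrier position (plane between this column and the
#'   next); must be strictly inside the analyzed range.
#' @param scheme correlator scheme.
#' @param ... thresholds passed to [transitMap()].
#' @return list with \code{forward} and \code{backward}
#'   \linkS4class{TransitMap}s, their cross-barrier median delays, and
#'   \code{asymmetry} = backward / forward median cross-barrier delay
#'   (> 1 means faster forward transport).
#' @export
directionalAnalysis <- function(x, delta, barrierColumn,
                                scheme = c("multitau", "direct"), ...) {
    stopifnot(is(x, "LineScanCarpet"))
    scheme <- match.arg(scheme)
    delta <- abs(as.integer(delta))
    if (delta < 1) stop("'delta' must be a non-zero pixel separation")
    if (barrierColumn < 1 || barrierColumn >= nPixels(x))
        stop("'barrierColumn' must lie strictly inside the scanned line")
    tmF <- transitMap(pcfCarpet(x, delta, scheme = scheme),
        barrierColumn = barrierColumn, ...)
    tmB <- transitMap(pcfCarpet(x, -delta, scheme = scheme),
        barrierColumn = barrierColumn, ...)
    crossMedian <- function(tm) {
        tb <- tm@table
        v <- tb$tau_peak_s[tb$spans_barrier & !is.na(tb$tau_peak_s)]
        if (length(v)) stats::median(v) else NA_real_
    }
    mF <- crossMedian(tmF)
    mB <- crossMedian(tmB)
    list(forward = tmF, backward = tmB, crossMedianForward = mF,
         crossMedianBackward = mB, asymmetry = mB / mF)
}
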