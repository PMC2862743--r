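#' @import methods
NULL

#' Gaussian illumination profile of the confocal spot
#'
#' The point spread function is modeled as a 3D Gaussian,
#' \eqn{W(r) = \exp(-2(x^2+y^2)/w_0^2 - 2 z^2/w_z^2)}, with radial 1/e^2
#' waist \code{w0} and axial waist \code{wz} (both in micrometers).
#'
#' @slot w0 radial waist in um.
#' @slot wz axial waist in um; must satisfy \code{wz >= w0}.
#' @export
setClass("PSFModel",
    representation(w0 = "numeric", wz = "numeric"),
    prototype(w0 = 0.25, wz = 1.25))

setValidity("PSFModel", function(object) {
    msg <- character(0)
    if (length(object@w0) != 1L || !is.finite(object@w0) || object@w0 <= 0)
        msg <- c(msg, "'w0' must be a single positive number (um)")
    if (length(object@wz) != 1L || !is.finite(object@wz) || object@wz < object@w0)
        msg <- c(msg, "'wz' must be a single number >= w0 (um)")
    if (length(msg)) msg else TRUE
})

#' Line-scan intensity carpet
#'
#' Photon counts collected by repeatedly scanning a focused laser beam along
#' the same line: rows are successive scan lines (time), columns are pixel
#' positions along the line. Column \code{i} sits at physical position
#' \code{(i - 1) * pixelSize} um from the left end of the scan.
#'
#' @slot counts non-negative integer-valued matrix, lines x pixels.
#' @slot pixelSize pixel spacing along the line, um.
#' @slot pixelDwell sampling time per pixel, s.
#' @slot linePeriod time between successive lines, s (>= nPixels * pixelDwell;
#'   the difference is the retrace dead time).
#' @slot columnLabels per-column compartment tag: one of \code{"nucleus"},
#'   \code{"cytoplasm"}, \code{"barrier"}, \code{"unknown"}.
#' @slot acquisitionStart acquisition start time, s (0 for simulated data).
#' @export
setClass("LineScanCarpet",
    representation(counts = "matrix", pixelSize = "numeric",
        pixelDwell = "numeric", linePeriod = "numeric",
        columnLabels = "character", acquisitionStart = "numeric"))

setValidity("LineScanCarpet", function(object) {
    msg <- character(0)
    cts <- object@counts
    if (!is.numeric(cts)) msg <- c(msg, "'counts' must be a numeric matrix")
    else {
        if (any(!is.finite(cts))) msg <- c(msg, "'counts' contains non-finite values")
        else if (any(cts < 0)) msg <- c(msg, "'counts' contains negative values")
        else if (any(cts != round(cts)))
            msg <- c(msg, "'counts' must be integer-valued photon counts")
        if (ncol(cts) < 2L) msg <- c(msg, "a carpet needs at least 2 pixels per line")
    }
    for (s in c("pixelSize", "pixelDwell", "linePeriod")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive number", s))
    }
    if (!length(msg)) {
        if (object@linePeriod < ncol(cts) * object@pixelDwell - 1e-12)
            msg <- c(msg, "'linePeriod' must be >= nPixels * pixelDwell")
        if (length(object@columnLabels) != ncol(cts))
            msg <- c(msg, "'columnLabels' must have one entry per pixel column")
        if (!all(object@columnLabels %in%
                 c("nucleus", "cytoplasm", "barrier", "unknown")))
            msg <- c(msg, "'columnLabels' must be nucleus|cytoplasm|barrier|unknown")
    }
    if (length(msg)) msg else TRUE
})

#' Correlation curve at a fixed pixel separation
#'
#' G(tau) of one column (autocorrelation, \code{deltaPixels = 0}) or of a
#' column pair (pair correlation at separation \code{deltaPixels}), on a
#' multi-tau (log-binned) lag grid. Reported lag values include the constant
#' intra-line offset \code{deltaPixels * pixelDwell}, so they are physically
#' exact arrival-time differences.
#'
#' @slot lags lag times, s, strictly increasing.
#' @slot values correlation values G(tau); negative values (the short-lag
#'   anti-correlation dip) are preserved, never clipped.
#' @slot sd optional per-lag standard deviation across averaged columns
#'   (length 0 when unavailable).
#' @slot deltaPixels signed column separation (target - origin).
#' @slot deltaUm \code{deltaPixels * pixelSize}, um.
#' @slot sourceColumns integer (origin, target), 1-based.
#' @slot nLinesUsed number of scan lines that entered the estimator.
#' @slot binFactor multi-tau binning factor at each lag.
#' @slot linePeriod line period of the source carpet, s.
#' @slot pixelSize pixel size of the source carpet, um.
#' @export
setClass("CorrelationCurve",
    representation(lags = "numeric", values = "numeric", sd = "numeric",
        deltaPixels = "integer", deltaUm = "numeric",
        sourceColumns = "integer", nLinesUsed = "integer",
        binFactor = "integer", linePeriod = "numeric", pixelSize = "numeric"))

setValidity("CorrelationCurve", function(object) {
    msg <- character(0)
    if (length(object@lags) != length(object@values))
        msg <- c(msg, "'lags' and 'values' must have the same length")
    if (any(!is.finite(object@lags)) || any(object@lags <= 0))
        msg <- c(msg, "'lags' must be positive and finite")
    if (is.unsorted(object@lags, strictly = TRUE))
        msg <- c(msg, "'lags' must be strictly increasing")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "'values' must be finite")
    if (length(object@sd) && length(object@sd) != length(object@values))
        msg <- c(msg, "'sd', when present, must match 'values' in length")
    if (length(msg)) msg else TRUE
})

#' A stack of correlation curves, one per origin column
#'
#' All member curves share the same lag grid and pixel separation; this is
#' the column-resolved pCF (or ACF, at separation 0) carpet.
#'
#' @slot curves list of \linkS4class{CorrelationCurve}.
#' @slot origins 1-based origin column of each curve.
#' @slot deltaPixels common signed pixel separation.
#' @slot lags shared lag grid, s.
#' @export
setClass("CorrelationCarpet",
    representation(curves = "list", origins = "integer",
        deltaPixels = "integer", lags = "numeric"))

setValidity("CorrelationCarpet", function(object) {
    msg <- character(0)
    if (length(object@curves) != length(object@origins))
        msg <- c(msg, "'curves' and 'origins' must have the same length")
    ok <- vapply(object@curves, function(cv)
        is(cv, "CorrelationCurve") &&
        isTRUE(all.equal(cv@lags, object@lags)) &&
        cv@deltaPixels == object@deltaPixels, logical(1))
    if (!all(ok))
        msg <- c(msg, "all curves must share the carpet's lag grid and deltaPixels")
    if (length(msg)) msg else TRUE
})

#' Configuration of a simulated line-scan experiment
#'
#' Physical specification of a Brownian-dynamics line-scan simulation: a box
#' with reflecting walls, optionally split by a semi-permeable barrier plane
#' (the nuclear-envelope analog) at \code{barrierX}, with compartment-specific
#' diffusion coefficients, an optional directional carrier channel, a scanned
#' Gaussian focal spot, and Poisson photon detection.
#'
#' @slot box box dimensions (Lx, Ly, Lz), um. The scan line runs along x at
#'   the box midplane in y and z.
#' @slot barrierX barrier plane position, um (\code{NA} for no barrier).
#' @slot dLeft,dRight diffusion coefficients left/right of the barrier,
#'   um^2/s ("left" is the nucleus by convention when scanning
#'   nucleus-to-cytoplasm). Without a barrier \code{dLeft} applies everywhere.
#' @slot nParticles number of fluorescent molecules.
#' @slot brightness expected photon counts per molecule per pixel dwell at
#'   the PSF center.
#' @slot background expected background counts per pixel dwell.
#' @slot barrierThickness physical thickness of an impenetrable gap slab
#'   centered on \code{barrierX}, um (0 = ordinary semi-permeable plane;
#'   > 0 models the fluorophore-free gap between adjacent cells and makes
#'   the barrier impenetrable regardless of \code{pCross}).
#' @slot pCross passive transmission probability per barrier-crossing
#'   attempt, in [0, 1].
#' @slot activeEnabled enable the directional carrier channel.
#' @slot activeDirection \code{"right_to_left"} (cytoplasm-to-nucleus with the
#'   nucleus on the left) or \code{"left_to_right"}.
#' @slot pActive capture probability per rejected barrier contact on the
#'   channel's source side.
#' @slot translocationMean mean of the exponential translocation dwell, s.
#' @slot psf \linkS4class{PSFModel}.
#' @slot nPixels,pixelSize,pixelDwell,linePeriod scan geometry (um, s).
#' @slot scanDirection beam sweep direction, \code{"left_to_right"} default.
#' @slot nLines number of recorded scan lines.
#' @slot burnIn equilibration time before recording, s.
#' @slot seed integer seed; expands into independent streams for
#'   trajectories, translocation dwells and photon noise.
#' @export
setClass("SimConfig",
    representation(box = "numeric", barrierX = "numeric",
        barrierThickness = "numeric",
        dLeft = "numeric", dRight = "numeric", nParticles = "integer",
        brightness = "numeric", background = "numeric", pCross = "numeric",
        activeEnabled = "logical", activeDirection = "character",
        pActive = "numeric", translocationMean = "numeric",
        psf = "PSFModel", nPixels = "integer", pixelSize = "numeric",
        pixelDwell = "numeric", linePeriod = "numeric",
        scanDirection = "character", nLines = "integer",
        burnIn = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    pos1 <- function(v) length(v) == 1L && is.finite(v) && v > 0
    if (length(object@box) != 3L || any(!is.finite(object@box)) ||
        any(object@box <= 0))
        msg <- c(msg, "'box' must be three positive lengths (um)")
    if (!pos1(object@dLeft) || !pos1(object@dRight))
        msg <- c(msg, "'dLeft'/'dRight' must be positive (um^2/s)")
    for (s in c("brightness", "background"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
            slot(object, s) < 0)
            msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
    for (s in c("pCross", "pActive")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
            msg <- c(msg, sprintf("'%s' must lie in [0, 1]", s))
    }
    if (!pos1(object@translocationMean))
        msg <- c(msg, "'translocationMean' must be positive (s)")
    if (object@nParticles < 1L) msg <- c(msg, "'nParticles' must be >= 1")
    if (object@nPixels < 2L) msg <- c(msg, "'nPixels' must be >= 2")
    for (s in c("pixelSize", "pixelDwell", "linePeriod", "burnIn"))
        if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)) ||
            slot(object, s) < 0 || (s != "burnIn" && slot(object, s) <= 0))
            msg <- c(msg, sprintf("'%s' must be a valid scan parameter", s))
    if (object@nLines < 1L) msg <- c(msg, "'nLines' must be >= 1")
    if (!object@scanDirection %in% c("left_to_right", "right_to_left"))
        msg <- c(msg, "'scanDirection' must be left_to_right|right_to_left")
    if (!object@activeDirection %in% c("left_to_right", "right_to_left"))
        msg <- c(msg, "'activeDirection' must be left_to_right|right_to_left")
    if (!length(msg)) {
        w0 <- object@psf@w0
        if (object@box[2] < 6 * w0 || object@box[3] < 6 * w0)
            msg <- c(msg, "'box' Ly and Lz must be >= 6 * w0 (boundary-artifact guard)")
        if (object@linePeriod < object@nPixels * object@pixelDwell - 1e-12)
            msg <- c(msg, "'linePeriod' must be >= nPixels * pixelDwell")
        scan_len <- (object@nPixels - 1) * object@pixelSize
        if (scan_len >= object@box[1])
            msg <- c(msg, "scan line does not fit inside the box along x")
        if (!is.na(object@barrierX) &&
            (object@barrierX <= 0 || object@barrierX >= object@box[1]))
            msg <- c(msg, "'barrierX' must lie strictly inside the box")
        if (length(object@barrierThickness) != 1L ||
            !is.finite(object@barrierThickness) ||
            object@barrierThickness < 0)
            msg <- c(msg, "'barrierThickness' must be a non-negative length")
        if (object@barrierThickness > 0 && object@activeEnabled)
            msg <- c(msg, "an impenetrable gap slab cannot carry active transport")
        if (object@activeEnabled && is.na(object@barrierX))
            msg <- c(msg, "active transport requires a barrier")
        if (length(object@seed) != 1L || !is.finite(object@seed) ||
            object@seed != round(object@seed))
            msg <- c(msg, "'seed' must be a single integer")
    }
    if (length(msg)) msg else TRUE
})

#' Result of a line-scan simulation
#'
#' @slot carpet the simulated \linkS4class{LineScanCarpet}.
#' @slot crossingEvents data.frame of completed barrier crossings
#'   (\code{time_s}, \code{direction}, \code{type} passive/active), times
#'   relative to the start of recording.
#' @slot occupancy integer matrix (lines x 3): particles left of the barrier,
#'   right of it, and inside the translocation channel, per recorded line.
#' @slot keq realized left/right occupancy ratio (NA without a barrier).
#' @slot config the \linkS4class{SimConfig} that produced the result.
#' @slot positions optional list of position snapshot matrices (x, y, z),
#'   one row per recorded snapshot, one column per particle.
#' @export
setClass("SimResult",
    representation(carpet = "LineScanCarpet", crossingEvents = "data.frame",
        occupancy = "matrix", keq = "numeric", config = "SimConfig",
        positions = "list"))

#' Diffusion-model fit of a correlation curve
#'
#' @slot modelId \code{"3d_1comp"} or \code{"3d_2comp"}.
#' @slot nMolecules apparent mean occupancy N of the focal volume
#'   (amplitude convention gamma = 1, so G(0) = 1/N).
#' @slot D fitted diffusion coefficient(s), um^2/s (length 2 for 3d_2comp,
#'   fast then slow).
#' @slot fractionSlow amplitude fraction of the slow component (2comp only).
#' @slot G0 fitted zero-lag amplitude, = 1/N.
#' @slot se named standard errors of the fitted parameters.
#' @slot residualNorm residual sum of squares at the solution.
#' @slot converged TRUE if the optimizer reported convergence.
#' @slot psf the PSF model held fixed during the fit.
#' @slot fitRange lag range used, s.
#' @slot nPoints number of lags in the fit.
#' @export
setClass("DiffusionFit",
    representation(modelId = "character", nMolecules = "numeric",
        D = "numeric", fractionSlow = "numeric", G0 = "numeric",
        se = "numeric", residualNorm = "numeric", converged = "logical",
        psf = "PSFModel", fitRange = "numeric", nPoints = "integer"))

#' Per-column transit-delay map
#'
#' Peak delays of a pCF carpet with a connectivity classification per origin
#' column: \code{intra} (ordinary intracompartment transit),
#' \code{barrier_delayed} (delay much longer than the intra reference),
#' \code{no_communication} (no significant correlation maximum), or
#' \code{unstable} (column failed stationarity QC).
#'
#' @slot table data.frame with columns \code{column}, \code{position_um},
#'   \code{tau_peak_s}, \code{amplitude}, \code{significance}, \code{class},
#'   \code{spans_barrier}.
#' @slot deltaPixels signed pixel separation of the underlying pCF carpet.
#' @slot thresholds list of every threshold used (full provenance).
#' @slot barrierColumn barrier position: the plane lies between this column
#'   and the next (NA when no barrier was supplied).
#' @export
setClass("TransitMap",
    representation(table = "data.frame", deltaPixels = "integer",
        thresholds = "list", barrierColumn = "numeric"))
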