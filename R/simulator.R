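cfgToCpp <- function(config, photons = TRUE, positionStride = 0L,
                     nLines = config@nLines, seed = config@seed,
                     burnIn = config@burnIn) {
    list(lx = config@box[1], ly = config@box[2], lz = config@box[3],
        has_barrier = !is.na(config@barrierX),
        barrier_x = if (is.na(config@barrierX)) -1 else config@barrierX,
        barrier_thickness = config@barrierThickness,
        d_left = config@dLeft, d_right = config@dRight,
        n_particles = config@nParticles, brightness = config@brightness,
        background = config@background, p_cross = config@pCross,
        active_enabled = config@activeEnabled,
        active_src_left = as.integer(config@activeDirection == "left_to_right"),
        p_active = config@pActive,
        translocation_mean_s = config@translocationMean,
        w0 = config@psf@w0, wz = config@psf@wz,
        n_pixels = config@nPixels, pixel_size = config@pixelSize,
        pixel_dwell = config@pixelDwell, line_period = config@linePeriod,
        scan_left_to_right = config@scanDirection == "left_to_right",
        scan_x0 = scanOriginX(config), n_lines = as.integer(nLines),
        burn_in_s = burnIn, seed = as.numeric(seed),
        position_stride = as.integer(positionStride),
        photons = photons)
}

#' Simulate a line-scan carpet by Brownian dynamics
#'
#' Molecules diffuse in a reflecting box, optionally split by a
#' semi-permeable barrier plane; a Gaussian focal spot is stepped along the
#' scan line (one Brownian update per pixel dwell, one lumped update over
#' the retrace dead time) and photon counts are drawn as
#' Poisson(background + brightness * sum_i W(r_i - beam)). A step whose
#' x-path crosses the barrier is transmitted with probability
#' \code{pCross}; otherwise, if the carrier channel is enabled and the
#' molecule is on its source side, it is captured with probability
#' \code{pActive} and released on the far side after an exponential dwell;
#' otherwise the step is reflected about the barrier plane. Fully
#' deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param positionStride record particle positions every this many lines
#'   (0 = off; used for propagator validation).
#' @param photons compute the photon-count carpet (disable for pure
#'   trajectory runs such as occupancy studies).
#' @return a \linkS4class{SimResult}.
#' @examples
#' res <- simulateCarpet(simConfig(nLines = 1200, nParticles = 20, seed = 3))
#' carpet(res)
#' @export
simulateCarpet <- function(config, positionStride = 0L, photons = TRUE) {
    validObject(config)
    out <- cpp_simulate_carpet(cfgToCpp(config, photons = photons,
        positionStride = positionStride))
    labels <- if (!is.na(config@barrierX)) {
        ifelse(scanPositions(config) < config@barrierX, "nucleus", "cytoplasm")
    } else rep("unknown", config@nPixels)
    cpt <- if (photons)
        LineScanCarpet(out$counts, pixelSize = config@pixelSize,
            pixelDwell = config@pixelDwell, linePeriod = config@linePeriod,
            labels = labels)
    else
        LineScanCarpet(matrix(0L, 2, config@nPixels),
            pixelSize = config@pixelSize, pixelDwell = config@pixelDwell,
            linePeriod = config@linePeriod, labels = labels)
    ev <- data.frame(time_s = out$event_time,
        direction = ifelse(out$event_dir > 0, "left_to_right",
            "right_to_left"),
        type = ifelse(out$event_type > 0, "active", "passive"))
    occ <- out$occupancy
    keq <- if (is.na(config@barrierX)) NA_real_
        else mean(occ[, 1]) / mean(occ[, 2])
    pos <- if (positionStride > 0)
        list(x = out$pos_x, y = out$pos_y, z = out$pos_z) else list()
    new("SimResult", carpet = cpt, crossingEvents = ev, occupancy = occ,
        keq = keq, config = config, positions = pos)
}

#' @export
setMethod("carpet", "SimResult", function(x) x@carpet)
#' @export
setMethod("crossingEvents", "SimResult", function(x) x@crossingEvents)
#' @export
setMethod("realizedKeq", "SimResult", function(x) x@keq)

setMethod("show", "SimResult", function(object) {
    cat("SimResult\n")
    show(object@carpet)
    cat(sprintf("  %d completed barrier crossings, realized Keq = %.4g\n",
        nrow(object@crossingEvents), object@keq))
})

#' First-passage time across the barrier (trajectory oracle)
#'
#' Brute-force one-dimensional first-passage simulation with the same
#' step-size sequence and barrier transmission rule as the full scanner, but
#' no PSF or photon model: molecules start \code{startOffset} um left of the
#' barrier and the time of the first accepted crossing is recorded.
#' Censored passages (none within \code{horizon}) are reported separately,
#' never averaged in.
#'
#' @param config a \linkS4class{SimConfig} with a barrier.
#' @param startOffset start distance left of the barrier, um.
#' @param nRep number of independent trajectories (>= 100).
#' @param horizon censoring horizon, s.
#' @param seed RNG seed (defaults to \code{config@seed}).
#' @return list with \code{mean}, \code{sd} (uncensored passages; NA when
#'   all are censored), \code{nCensored}, \code{nRep}, \code{times}.
#' @export
meanCrossingTime <- function(config, startOffset, nRep = 400, horizon = 5,
                             seed = config@seed) {
    validObject(config)
    if (is.na(config@barrierX)) stop("config has no barrier")
    if (nRep < 100) stop("'nRep' must be >= 100")
    if (startOffset <= 0 || startOffset >= config@barrierX)
        stop("'startOffset' must place the start inside the left compartment")
    out <- cpp_crossing_times(config@box[1], config@barrierX, config@dLeft,
        config@dRight, config@pCross, startOffset, config@nPixels,
        config@pixelDwell, config@linePeriod, as.integer(nRep), horizon,
        as.numeric(seed))
    tms <- out$times
    cen <- sum(is.na(tms))
    ok <- tms[!is.na(tms)]
    list(mean = if (length(ok)) mean(ok) else NA_real_,
         sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
         nCensored = cen, nRep = nRep, times = tms)
}

#' Calibrate the barrier transmission probability
#'
#' The per-attempt transmission probability \code{pCross} is a numerical
#' parameter whose physical meaning depends on the step size; the barrier is
#' therefore characterized by an observable - the mean first-crossing time
#' from a stated start offset - and \code{pCross} is found by bisection (in
#' log space) of [meanCrossingTime()] until the achieved mean is within
#' \code{tol} of \code{targetMean}.
#'
#' @param targetMean target mean first-crossing time, s.
#' @param config template \linkS4class{SimConfig} with a barrier.
#' @param startOffset start distance left of the barrier, um.
#' @param nRep trajectories per evaluation.
#' @param horizon censoring horizon, s (default 8 * targetMean).
#' @param tol relative tolerance on the achieved mean (default 0.1).
#' @param maxIter bisection iteration cap.
#' @param seed RNG seed (one fixed stream per evaluation keeps the
#'   bisection objective monotone).
#' @return list with \code{pCross}, \code{achievedMean}, \code{achievedSd},
#'   \code{nCensored}, \code{iterations}.
#' @export
calibratePermeability <- function(targetMean, config, startOffset = 0.5,
                                  nRep = 400, horizon = 8 * targetMean,
                                  tol = 0.1, maxIter = 40,
                                  seed = config@seed) {
    if (targetMean <= 0) stop("'targetMean' must be positive")
    eval_p <- function(p) {
        cfg <- config
        cfg@pCross <- p
        meanCrossingTime(cfg, startOffset, nRep = nRep, horizon = horizon,
            seed = seed)
    }
    res1 <- eval_p(1)
    if (is.na(res1$mean) || res1$mean > targetMean * (1 + tol))
        stop("infeasible target: ", signif(targetMean, 3),
             " s is shorter than the free-diffusion passage time (",
             signif(res1$mean, 3), " s)")
    if (abs(res1$mean - targetMean) <= tol * targetMean)
        return(list(pCross = 1, achievedMean = res1$mean,
            achievedSd = res1$sd, nCensored = res1$nCensored, iterations = 1L))
    # bracket: decrease p until the mean crossing time exceeds the target
    p_lo <- 1; it <- 1L
    repeat {
        p_lo <- p_lo / 4
        it <- it + 1L
        if (p_lo < 1e-8)
            stop("failed to bracket the target within pCross >= 1e-8")
        r <- eval_p(p_lo)
        if (abs(r$mean - targetMean) <= tol * targetMean)
            return(list(pCross = p_lo, achievedMean = r$mean,
                achievedSd = r$sd, nCensored = r$nCensored, iterations = it))
        if (is.na(r$mean) || r$mean > targetMean) break
    }
    p_hi <- p_lo * 4
    for (k in seq_len(maxIter)) {
        p_mid <- sqrt(p_lo * p_hi)
        r <- eval_p(p_mid)
        it <- it + 1L
        if (!is.na(r$mean) && abs(r$mean - targetMean) <= tol * targetMean)
            return(list(pCross = p_mid, achievedMean = r$mean,
                achievedSd = r$sd, nCensored = r$nCensored, iterations = it))
        if (is.na(r$mean) || r$mean > targetMean) p_lo <- p_mid
        else p_hi <- p_mid
    }
    stop("permeability calibration did not converge within ", maxIter,
         " bisection steps")
}

#' Steady-state occupancy ratio of the two compartments
#'
#' Runs trajectory-only dynamics for \code{horizon} seconds (after burn-in)
#' and returns the time-averaged left/right occupancy ratio. With passive
#' transport only, detailed balance drives the ratio to the compartment
#' volume ratio (1 for a centered barrier); a directional carrier channel
#' pumps it above (toward the left) or below 1.
#'
#' @param config a \linkS4class{SimConfig} with a barrier.
#' @param horizon averaging time, s.
#' @return list with \code{keq}, \code{meanLeft}, \code{meanRight},
#'   \code{meanTranslocating}.
#' @export
steadyStateKeq <- function(config, horizon = 20) {
    validObject(config)
    if (is.na(config@barrierX)) stop("config has no barrier")
    n_lines <- max(2L, as.integer(ceiling(horizon / config@linePeriod)))
    cfg <- config
    cfg@nLines <- n_lines
    res <- simulateCarpet(cfg, photons = FALSE)
    occ <- res@occupancy
    list(keq = mean(occ[, 1]) / mean(occ[, 2]), meanLeft = mean(occ[, 1]),
         meanRight = mean(occ[, 2]), meanTranslocating = mean(occ[, 3]))
}
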