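#' Construct a PSF model
#'
#' @param w0 radial 1/e^2 waist, um (typical confocal values: 0.2-0.3 um).
#' @param wz axial waist, um; if \code{NULL}, \code{kappa * w0}.
#' @param kappa axial-to-radial aspect ratio, default 5 (typical confocal
#'   elongation).
#' @return a \linkS4class{PSFModel}.
#' @examples
#' psfModel(0.25)
#' @export
psfModel <- function(w0 = 0.25, wz = NULL, kappa = 5) {
    if (is.null(wz)) wz <- kappa * w0
    new("PSFModel", w0 = w0, wz = wz)
}

setMethod("show", "PSFModel", function(object)
    cat(sprintf("PSFModel: w0 = %.4g um, wz = %.4g um (kappa = %.3g)\n",
        object@w0, object@wz, object@wz / object@w0)))

#' Evaluate the illumination profile
#'
#' \eqn{W(r) = \exp(-2(dx^2+dy^2)/w_0^2 - 2 dz^2/w_z^2)}; \code{W(0) = 1}.
#' @param psf a \linkS4class{PSFModel}.
#' @param dx,dy,dz displacement from the beam center, um.
#' @export
psfProfile <- function(psf, dx, dy = 0, dz = 0)
    exp(-2 * (dx^2 + dy^2) / psf@w0^2 - 2 * dz^2 / psf@wz^2)

# effective focal volume under the gamma = 1 amplitude convention,
# Veff = (int W)^2 / int W^2 = pi^(3/2) w0^2 wz; the apparent occupancy
# fitted from G(0) = 1/N equals concentration * Veff
focalVolume <- function(psf)
    pi^(3 / 2) * psf@w0^2 * psf@wz

#' Configure a line-scan simulation
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults reproduce the
#' acquisition geometry this package targets: a 32-pixel line at 100 nm
#' pixel size, 6.3 us pixel dwell and 0.473 ms line period, a 0.25 um
#' radial waist with 5x axial elongation, and a simulation box large enough
#' that the reflecting outer walls do not distort the focal statistics.
#' \code{nParticles = NA} picks the particle number giving about one
#' molecule in the effective focal volume.
#'
#' @param nPixels,pixelSize,pixelDwell,linePeriod scan geometry (um, s).
#' @param nLines recorded lines.
#' @param dLeft,dRight diffusion coefficients, um^2/s (left compartment is
#'   the nucleus by convention; \code{dRight} defaults to \code{dLeft}).
#' @param barrierX barrier plane position in um, \code{NA} for none;
#'   \code{"center"} places it at the box center (between the two middle
#'   pixel columns of a centered scan).
#' @param barrierThickness thickness of an impenetrable fluorophore-free
#'   gap slab centered on the barrier, um (default 0: thin semi-permeable
#'   plane). Used for the two-adjacent-cells control geometry.
#' @param pCross passive transmission probability per crossing attempt.
#' @param activeEnabled,activeDirection,pActive,translocationMean carrier
#'   channel: enable flag, direction (source -> destination), capture
#'   probability on barrier contact, mean exponential translocation dwell (s).
#' @param psf \linkS4class{PSFModel}.
#' @param box box dimensions (Lx, Ly, Lz) um; default
#'   \code{c(scanLength + 4, 3, 6)}.
#' @param nParticles molecule count (NA = ~1 per focal volume).
#' @param brightness counts per molecule per dwell at the PSF center.
#' @param background counts per dwell.
#' @param scanDirection beam sweep direction.
#' @param burnIn equilibration time, s.
#' @param seed integer seed.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nLines = 2000, dLeft = 12.5, seed = 7)
#' cfg
#' @export
simConfig <- function(nPixels = 32, pixelSize = 0.1, pixelDwell = 6.3e-6,
                      linePeriod = 4.73e-4, nLines = 64000,
                      dLeft = 12.5, dRight = dLeft,
                      barrierX = NA_real_, barrierThickness = 0, pCross = 1,
                      activeEnabled = FALSE,
                      activeDirection = "right_to_left",
                      pActive = 0.5, translocationMean = 5e-3,
                      psf = psfModel(), box = NULL, nParticles = NA,
                      brightness = 0.5, background = 0.02,
                      scanDirection = "left_to_right",
                      burnIn = 5, seed = 1) {
    scan_len <- (nPixels - 1) * pixelSize
    if (is.null(box)) {
        # Without a barrier, generous x-margins keep wall effects away from
        # every column. With a barrier the compartments are kept shallow
        # (0.5 um beyond the scan ends): the box emulates only the
        # envelope-proximal region of each compartment, which keeps the
        # calibrated barrier transmission-limited - as the pore-limited
        # nuclear envelope is - instead of diffusion-limited.
        margin <- if (is.na(barrierX[1]) && !identical(barrierX, "center")) 4 else 1
        box <- c(scan_len + margin, 3, 6)
    }
    if (identical(barrierX, "center")) barrierX <- box[1] / 2
    if (is.na(nParticles))
        nParticles <- max(1L, round(prod(box) / focalVolume(psf)))
    new("SimConfig", box = as.numeric(box), barrierX = as.numeric(barrierX),
        barrierThickness = barrierThickness,
        dLeft = dLeft, dRight = dRight, nParticles = as.integer(nParticles),
        brightness = brightness, background = background, pCross = pCross,
        activeEnabled = activeEnabled, activeDirection = activeDirection,
        pActive = pActive, translocationMean = translocationMean,
        psf = psf, nPixels = as.integer(nPixels), pixelSize = pixelSize,
        pixelDwell = pixelDwell, linePeriod = linePeriod,
        scanDirection = scanDirection, nLines = as.integer(nLines),
        burnIn = burnIn, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d px x %d lines, dwell %.3g us, period %.3g ms\n",
        object@nPixels, object@nLines, object@pixelDwell * 1e6,
        object@linePeriod * 1e3))
    cat(sprintf("  box %.3g x %.3g x %.3g um, %d particles, D = %.3g / %.3g um^2/s\n",
        object@box[1], object@box[2], object@box[3], object@nParticles,
        object@dLeft, object@dRight))
    if (is.na(object@barrierX)) cat("  no barrier\n")
    else cat(sprintf("  barrier at x = %.3g um, pCross = %.3g, active: %s\n",
        object@barrierX, object@pCross,
        if (object@activeEnabled)
            sprintf("%s (pActive = %.3g, dwell %.3g ms)",
                object@activeDirection, object@pActive,
                object@translocationMean * 1e3)
        else "off"))
    cat(sprintf("  seed %d, burn-in %.3g s\n", as.integer(object@seed),
        object@burnIn))
})

# left edge of the scan along x: the scanned line is centered in the box
scanOriginX <- function(config)
    (config@box[1] - (config@nPixels - 1) * config@pixelSize) / 2

#' Physical x positions of the scanned pixel columns of a simulation
#' @param config a \linkS4class{SimConfig}
#' @export
scanPositions <- function(config)
    scanOriginX(config) + (seq_len(config@nPixels) - 1) * config@pixelSize

#' The column index just left of the barrier plane
#'
#' The barrier lies between the returned column and the next one; pairs
#' (origin, origin + delta) with origin <= barrierColumn < origin + delta
#' span the barrier.
#' @param config a \linkS4class{SimConfig} with a barrier.
#' @export
barrierColumn <- function(config) {
    if (is.na(config@barrierX)) stop("config has no barrier")
    sum(scanPositions(config) < config@barrierX)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [simConfig()] (snake_case accepted), plus an
#' optional \code{preset: standard_scan} that fills the standard acquisition
#' geometry. Unknown keys are rejected; every physical quantity is in um or
#' seconds as documented in [simConfig()].
#'
#' @param path YAML file.
#' @return a \linkS4class{SimConfig}.
#' @export
readSimConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (!is.list(y)) stop("malformed config: expected a key-value mapping")
    to_camel <- function(s)
        gsub("_(\\w)", "\\U\\1", s, perl = TRUE)
    nm <- vapply(names(y), to_camel, character(1))
    names(y) <- nm
    preset <- y$preset
    y$preset <- NULL
    known <- names(formals(simConfig))
    known <- c(known, "w0", "wz", "kappa")
    bad <- setdiff(names(y), known)
    if (length(bad))
        stop("unknown config key(s): ", paste(bad, collapse = ", "))
    if (!is.null(preset)) {
        if (!identical(preset, "standard_scan") && !identical(preset, "standard-scan"))
            stop("unknown preset '", preset, "'")
        base <- list(nPixels = 32, pixelSize = 0.1, pixelDwell = 6.3e-6,
            linePeriod = 4.73e-4)
        for (k in names(base)) if (is.null(y[[k]])) y[[k]] <- base[[k]]
    }
    if (!is.null(y$w0) || !is.null(y$wz) || !is.null(y$kappa)) {
        y$psf <- psfModel(w0 = if (is.null(y$w0)) 0.25 else y$w0,
            wz = y$wz, kappa = if (is.null(y$kappa)) 5 else y$kappa)
        y$w0 <- y$wz <- y$kappa <- NULL
    }
    if (is.null(y$seed))
        stop("config is missing required key 'seed'")
    do.call(simConfig, y)
}
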