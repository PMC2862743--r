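#' Closed-form ACF of free 3D diffusion through a Gaussian focal volume
#'
#' \deqn{G(\tau) = \frac{1}{N} \left(1 + \frac{4D\tau}{w_0^2}\right)^{-1}
#'   \left(1 + \frac{4D\tau}{w_z^2}\right)^{-1/2}}
#' under the amplitude convention gamma = 1, so \code{G(0) = 1/N} with N the
#' apparent mean focal-volume occupancy. D and peak positions - the
#' physically meaningful readouts - do not depend on the gamma convention.
#'
#' @param tau lag time(s), s.
#' @param N mean occupancy (> 0).
#' @param D diffusion coefficient, um^2/s.
#' @param psf a \linkS4class{PSFModel}.
#' @return G values, same length as \code{tau}.
#' @examples
#' modelACF3D(0, N = 2, D = 10)           # 1/N = 0.5
#' @export
modelACF3D <- function(tau, N, D, psf = psfModel()) {
    stopifnot(N > 0, D > 0)
    (1 / N) / ((1 + 4 * D * tau / psf@w0^2) *
               sqrt(1 + 4 * D * tau / psf@wz^2))
}

#' Closed-form pair correlation for two spots a distance apart
#'
#' The mean-field pCF model for free 3D diffusion with both observation
#' spots on the scan axis:
#' \deqn{G(\tau; \delta) = G_{ACF}(\tau) \,
#'   \exp\!\left(-\frac{\delta^2}{w_0^2 + 4D\tau}\right).}
#' The model is non-negative everywhere; the short-lag anti-correlation of
#' the measured estimator arises from single-molecule occupancy
#' fluctuations that this mean-concentration model does not carry.
#'
#' @inheritParams modelACF3D
#' @param deltaUm spot separation along the scan axis, um (>= 0).
#' @export
modelPCF3D <- function(tau, N, D, psf = psfModel(), deltaUm) {
    stopifnot(deltaUm >= 0)
    modelACF3D(tau, N, D, psf) *
        exp(-deltaUm^2 / (psf@w0^2 + 4 * D * tau))
}

#' Lag of the pCF maximum predicted by the closed-form model
#'
#' Bracketed one-dimensional maximization of [modelPCF3D()] over log-lag;
#' the two-dimensional limit has the closed form
#' \eqn{\tau_{peak} = (\delta^2 - w_0^2) / (4D)}, returned alongside as a
#' reference. For \code{deltaUm <= w0} the maximum sits at tau -> 0.
#'
#' @param D diffusion coefficient, um^2/s.
#' @param deltaUm spot separation, um.
#' @param psf a \linkS4class{PSFModel}.
#' @return list with \code{tauPeak} (3D numeric maximizer, s) and
#'   \code{tauPeak2D} (2D closed form, s).
#' @examples
#' peakTimeTheory(12.5, 0.9, psfModel(0.25))  # 2D form: 14.95 ms
#' @export
peakTimeTheory <- function(D, deltaUm, psf = psfModel()) {
    stopifnot(D > 0, deltaUm >= 0)
    t2d <- max(0, (deltaUm^2 - psf@w0^2) / (4 * D))
    if (deltaUm <= psf@w0)
        return(list(tauPeak = 0, tauPeak2D = t2d))
    opt <- stats::optimize(
        function(lt) -modelPCF3D(10^lt, N = 1, D = D, psf = psf,
            deltaUm = deltaUm),
        interval = log10(t2d) + c(-3, 2), tol = 1e-12)
    list(tauPeak = 10^opt$minimum, tauPeak2D = t2d)
}

#' @export
setMethod("diffusionCoef", "DiffusionFit", function(x) x@D)
#' @export
setMethod("nMolecules", "DiffusionFit", function(x) x@nMolecules)

setMethod("show", "DiffusionFit", function(object) {
    cat(sprintf("DiffusionFit (%s)%s\n", object@modelId,
        if (object@converged) "" else "  ** NOT CONVERGED **"))
    if (object@modelId == "3d_1comp") {
        cat(sprintf("  D = %.4g +/- %.2g um^2/s, N = %.4g, G0 = %.4g\n",
            object@D[1], object@se["D"], object@nMolecules, object@G0))
    } else {
        cat(sprintf(
            "  D_fast = %.4g, D_slow = %.4g um^2/s, slow fraction = %.3g\n",
            object@D[1], object@D[2], object@fractionSlow))
        cat(sprintf("  N = %.4g, G0 = %.4g\n", object@nMolecules, object@G0))
    }
    cat(sprintf("  fit over [%.3g, %.3g] s, %d lags, RSS = %.3g\n",
        object@fitRange[1], object@fitRange[2], object@nPoints,
        object@residualNorm))
})

fitCurveLM <- function(tau, G, w, residFun, par0, parNames) {
    res <- minpack.lm::nls.lm(par = par0, fn = residFun,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
            ptol = 1e-10))
    converged <- res$info %in% c(1, 2, 3)
    se <- rep(NA_real_, length(par0))
    cov <- tryCatch({
        s2 <- res$deviance / max(1, length(tau) - length(par0))
        s2 * solve(0.5 * res$hessian)
    }, error = function(e) NULL)
    if (!is.null(cov)) {
        dg <- diag(cov)
        se <- ifelse(dg > 0, sqrt(dg), NA_real_)
    }
    names(se) <- parNames
    list(par = res$par, se = se, deviance = res$deviance,
         converged = converged)
}

#' Fit a diffusion model to a measured correlation curve
#'
#' Weighted Levenberg-Marquardt fit of [modelACF3D()] (\code{"3d_1comp"}) or
#' its two-component extension (\code{"3d_2comp"}) to a measured ACF.
#' Weights are the inverse variance across contributing columns when the
#' curve carries one (see [averageCurves()]), otherwise uniform.
#' Initialization: \code{N0 = 1/G} at the first fitted lag, \code{D0} from
#' the half-decay lag. Positivity is enforced by fitting log-parameters.
#' Non-convergence is flagged on the result, never silent.
#'
#' @param curve a \linkS4class{CorrelationCurve} (ACF, deltaPixels 0).
#' @param psf calibrated \linkS4class{PSFModel}, held fixed.
#' @param modelId \code{"3d_1comp"} or \code{"3d_2comp"}. The two-component
#'   model is never auto-selected; choosing it is an explicit analysis
#'   decision (e.g. for cytoplasmic records with a slow component).
#' @param fitRange lag range (s); default \code{[linePeriod, maxLag / 4]} -
#'   the longest lags are dominated by drift and statistical noise.
#' @param weights optional per-lag weights overriding the default.
#' @return a \linkS4class{DiffusionFit}.
#' @export
fitACF <- function(curve, psf = psfModel(),
                   modelId = c("3d_1comp", "3d_2comp"), fitRange = NULL,
                   weights = NULL) {
    stopifnot(is(curve, "CorrelationCurve"))
    modelId <- match.arg(modelId)
    if (is.null(fitRange))
        fitRange <- c(curve@linePeriod, max(curve@lags) / 4)
    keep <- which(curve@lags >= fitRange[1] & curve@lags <= fitRange[2])
    if (length(keep) < 8)
        stop("need at least 8 lags inside the fit range")
    tau <- curve@lags[keep]
    G <- curve@values[keep]
    if (all(G <= 0))
        stop("fit infeasible: correlation curve is non-positive everywhere")
    w <- if (!is.null(weights)) {
        stopifnot(length(weights) == length(keep) ||
                  length(weights) == length(curve@lags))
        if (length(weights) == length(curve@lags)) weights[keep] else weights
    } else if (length(curve@sd) && all(curve@sd[keep] > 0)) {
        1 / curve@sd[keep]^2
    } else rep(1, length(keep))
    sw <- sqrt(w)

    G1 <- G[1]
    N0 <- if (G1 > 0) 1 / G1 else 1 / max(G)
    ih <- which(G < max(G[1], max(G)) / 2)[1]
    D0 <- if (!is.na(ih)) psf@w0^2 / (4 * tau[ih]) else psf@w0^2 / (4 * stats::median(tau))
    D0 <- max(D0, 1e-6)

    if (modelId == "3d_1comp") {
        resid <- function(p) {
            m <- modelACF3D(tau, N = exp(p[1]), D = exp(p[2]), psf = psf)
            sw * (m - G)
        }
        fit <- fitCurveLM(tau, G, w, resid, c(log(N0), log(D0)),
            c("logN", "logD"))
        N <- exp(fit$par[1]); D <- exp(fit$par[2])
        se <- c(N = unname(N * fit$se[1]), D = unname(D * fit$se[2]))
        new("DiffusionFit", modelId = modelId, nMolecules = N, D = D,
            fractionSlow = NA_real_, G0 = 1 / N, se = se,
            residualNorm = fit$deviance, converged = fit$converged,
            psf = psf, fitRange = as.numeric(fitRange),
            nPoints = length(keep))
    } else {
        shape <- function(D, t)
            1 / ((1 + 4 * D * t / psf@w0^2) * sqrt(1 + 4 * D * t / psf@wz^2))
        resid <- function(p) {
            N <- exp(p[1]); D1 <- exp(p[2]); D2 <- exp(p[3])
            f <- stats::plogis(p[4])
            m <- (1 / N) * ((1 - f) * shape(D1, tau) + f * shape(D2, tau))
            sw * (m - G)
        }
        fit <- fitCurveLM(tau, G, w, resid,
            c(log(N0), log(D0), log(D0 / 10), stats::qlogis(0.3)),
            c("logN", "logD1", "logD2", "logitF"))
        N <- exp(fit$par[1])
        D <- c(exp(fit$par[2]), exp(fit$par[3]))
        f <- stats::plogis(fit$par[4])
        if (D[2] > D[1]) { D <- rev(D); f <- 1 - f }
        se <- c(N = unname(N * fit$se[1]), D1 = unname(D[1] * fit$se[2]),
                D2 = unname(D[2] * fit$se[3]), fractionSlow = NA_real_)
        new("DiffusionFit", modelId = modelId, nMolecules = N, D = D,
            fractionSlow = f, G0 = 1 / N, se = se,
            residualNorm = fit$deviance, converged = fit$converged,
            psf = psf, fitRange = as.numeric(fitRange),
            nPoints = length(keep))
    }
}

#' Calibrate the PSF waist from a reference measurement
#'
#' Standard focal-volume calibration: the ACF of a dye with known diffusion
#' coefficient (e.g. fluorescein in dilute NaOH, D = 300 um^2/s) is fitted
#' with D held fixed and the radial waist \code{w0} free. The axial aspect
#' \code{kappa} is fixed by default; on noiseless model data freeing it
#' does not move \code{w0}.
#'
#' @param curve measured ACF of the calibration dye.
#' @param DKnown reference diffusion coefficient, um^2/s.
#' @param kappa axial aspect wz/w0 (default 5).
#' @param fitKappa also fit kappa.
#' @param fitRange lag range, as in [fitACF()].
#' @return list with \code{psf} (the calibrated \linkS4class{PSFModel}),
#'   \code{w0}, \code{w0se}, \code{nMolecules}, \code{converged},
#'   \code{residualNorm}.
#' @export
calibratePSF <- function(curve, DKnown, kappa = 5, fitKappa = FALSE,
                         fitRange = NULL) {
    stopifnot(is(curve, "CorrelationCurve"), DKnown > 0)
    if (is.null(fitRange))
        fitRange <- c(curve@linePeriod, max(curve@lags) / 4)
    keep <- which(curve@lags >= fitRange[1] & curve@lags <= fitRange[2])
    if (length(keep) < 8)
        stop("need at least 8 lags inside the fit range")
    tau <- curve@lags[keep]
    G <- curve@values[keep]
    if (all(G <= 0))
        stop("fit infeasible: correlation curve is non-positive everywhere")
    w <- if (length(curve@sd) && all(curve@sd[keep] > 0)) 1 / curve@sd[keep]^2
         else rep(1, length(keep))
    sw <- sqrt(w)
    N0 <- if (G[1] > 0) 1 / G[1] else 1 / max(G)
    ih <- which(G < max(G) / 2)[1]
    w0_0 <- if (!is.na(ih)) sqrt(4 * DKnown * tau[ih]) else 0.25

    make_resid <- function(free_kappa) function(p) {
        N <- exp(p[1]); w0 <- exp(p[2])
        kap <- if (free_kappa) exp(p[3]) else kappa
        m <- modelACF3D(tau, N = N, D = DKnown,
            psf = new("PSFModel", w0 = w0, wz = max(kap, 1) * w0))
        sw * (m - G)
    }
    par0 <- c(log(N0), log(w0_0))
    nm <- c("logN", "logw0")
    if (fitKappa) { par0 <- c(par0, log(kappa)); nm <- c(nm, "logkappa") }
    fit <- fitCurveLM(tau, G, w, make_resid(fitKappa), par0, nm)
    w0 <- exp(fit$par[2])
    kap <- if (fitKappa) exp(fit$par[3]) else kappa
    list(psf = psfModel(w0 = w0, kappa = kap), w0 = w0,
         w0se = unname(w0 * fit$se[2]), nMolecules = exp(fit$par[1]),
         converged = fit$converged, residualNorm = fit$deviance)
}
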