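# deterministic fixture builders shared across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

standardGeometry <- list(pixelSize = 0.1, pixelDwell = 6.3e-6,
                      linePeriod = 4.73e-4)

# carpet of i.i.d. Poisson counts
poissonCarpet <- function(nLines, nPixels, lambda = 5, seed = 1) {
    set.seed(seed)
    LineScanCarpet(matrix(rpois(nLines * nPixels, lambda), nLines, nPixels),
        pixelSize = standardGeometry$pixelSize,
        pixelDwell = standardGeometry$pixelDwell,
        linePeriod = standardGeometry$linePeriod)
}

# small, fast free-diffusion simulation
quickSim <- function(nLines = 4096, D = 12.5, nParticles = 60, seed = 7, ...) {
    simulateCarpet(simConfig(nLines = nLines, dLeft = D,
        nParticles = nParticles, brightness = 1, seed = seed, ...))
}

# synthetic CorrelationCurve on a realistic multi-tau grid
modelCurve <- function(values, lags, bins = rep(1L, length(lags)),
                       delta = 0L, linePeriod = 4.73e-4, pixelSize = 0.1) {
    new("CorrelationCurve", lags = lags, values = values, sd = numeric(0),
        deltaPixels = as.integer(delta), deltaUm = delta * pixelSize,
        sourceColumns = c(1L, 1L + as.integer(delta)), nLinesUsed = 10000L,
        binFactor = as.integer(bins), linePeriod = linePeriod,
        pixelSize = pixelSize)
}

# the package's multi-tau lag grid (in lines), rebuilt independently
referenceLagGrid <- function(nLines) {
    lev <- 0L
    while (32 * 2^(lev + 1) <= nLines / 4) lev <- lev + 1L
    lag <- integer(0); bin <- integer(0)
    for (m in 0:lev) {
        j <- if (m == 0) 1:32 else 17:32
        lag <- c(lag, j * 2^m)
        bin <- c(bin, rep(2^m, length(j)))
    }
    list(lag = lag, bin = bin)
}
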