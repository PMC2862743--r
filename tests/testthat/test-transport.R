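# build a synthetic curve on the standard grid from the closed-form model
syntheticPCF <- function(D, deltaUm, nLines = 120000, N = 1,
                         noise = 0, seed = 1, linePeriod = 4.73e-4) {
    grid <- referenceLagGrid(nLines)
    lagT <- grid$lag * linePeriod
    v <- modelPCF3D(lagT, N, D, psfModel(0.25), deltaUm)
    if (noise > 0) {
        set.seed(seed)
        v <- v + rnorm(length(v), 0, noise)
    }
    modelCurve(v, lagT, bins = grid$bin, delta = round(deltaUm / 0.1),
        linePeriod = linePeriod)
}

test_that("peak detection matches the analytic transit-time oracle", {
    for (pars in list(c(12.5, 0.4), c(5.5, 0.8), c(12.5, 1.2))) {
        cv <- syntheticPCF(pars[1], pars[2])
        pk <- detectPeak(cv)
        expect_true(pk$found)
        th <- peakTimeTheory(pars[1], pars[2], psfModel(0.25))$tauPeak
        # within one lag bin of the model maximizer
        i <- findInterval(th, lags(cv))
        bin_width <- diff(lags(cv))[max(i, 1)]
        expect_lt(abs(pk$tauPeak - th), 2.5 * bin_width + 0.1 * th)
    }
    expect_error(detectPeak(syntheticPCF(12.5, 0.4), tauMin = 100), "window")
})

test_that("peak position is stable under lag-grid refinement", {
    # doubling the grid density moves the detected peak by at most one
    # coarse bin on noiseless model curves
    lp <- 4.73e-4
    coarse <- syntheticPCF(12.5, 0.8)
    fine_lags <- exp(seq(log(lp), log(max(lags(coarse))), length.out = 320))
    fine <- modelCurve(modelPCF3D(fine_lags, 1, 12.5, psfModel(0.25), 0.8),
        fine_lags, bins = rep(1L, length(fine_lags)), delta = 8L)
    pc <- detectPeak(coarse)
    pf <- detectPeak(fine)
    i <- findInterval(pc$tauPeak, lags(coarse))
    coarse_bin <- diff(lags(coarse))[i]
    expect_lt(abs(pc$tauPeak - pf$tauPeak), coarse_bin + 0.05 * pc$tauPeak)
})

test_that("pure-noise curves are declared peakless at the default threshold", {
    n_rep <- 400
    grid <- referenceLagGrid(60000)
    lagT <- grid$lag * 4.73e-4
    hits <- 0L
    set.seed(1234)
    for (r in seq_len(n_rep)) {
        cv <- modelCurve(rnorm(length(lagT), 0, 0.01), lagT, bins = grid$bin)
        if (detectPeak(cv)$found) hits <- hits + 1L
    }
    expect_lt(hits / n_rep, 0.05)
})

test_that("transit map classifies a uniform simulation as all-intra", {
    res <- quickSim(nLines = 30000, D = 12.5, nParticles = 150, seed = 41)
    cc <- pcfCarpet(carpet(res), 5L)
    # 3-pixel block averaging, as used for carpet readouts
    blocks <- lapply(seq(1, 25, by = 3), function(o)
        averageCurves(cc, columns = o:(o + 2)))
    bcc <- new("CorrelationCarpet", curves = blocks,
        origins = as.integer(seq(2, 26, by = 3)), deltaPixels = 5L,
        lags = lags(cc))
    tm <- transitMap(bcc)
    tb <- transitTable(tm)
    expect_true(all(tb$class %in% c("intra", "no_communication")))
    expect_gt(mean(tb$class == "intra"), 0.7)
    # isotropy: delays agree within sampling scatter across the line
    tau <- tb$tau_peak_s[tb$class == "intra"]
    expect_lt(stats::mad(tau) / stats::median(tau), 0.8)
    # thresholds are recorded in full
    expect_named(tm@thresholds, c("tauMin", "tauMax", "smoothingBins",
        "significanceThreshold", "ratioThreshold", "medianIntraTau"))
})

test_that("an impenetrable gap shows up as a no-communication stripe", {
    # two adjacent cells separated by a fluorophore-free 0.7 um gap:
    # molecules cannot cross, so pairs spanning the gap must not correlate
    cfg <- simConfig(nLines = 50000, nParticles = 170, dLeft = 12.5,
        dRight = 12.5, barrierX = "center", barrierThickness = 0.7,
        pCross = 0, brightness = 1, box = c(4.1, 3, 6), seed = 43,
        burnIn = 1)
    res <- simulateCarpet(cpt_cfg <- cfg)
    expect_identical(nrow(crossingEvents(res)), 0L)
    cpt <- carpet(res)
    bc <- barrierColumn(cfg)
    delta <- 7L
    cc <- pcfCarpet(cpt, delta)
    tm <- transitMap(cc, barrierColumn = bc, tauMax = 1.5)
    tb <- transitTable(tm)
    spanning <- tb$spans_barrier
    # the apparent no-communication stripe has width ~ delta
    expect_identical(sum(spanning), 7L)
    # pairs with an endpoint inside the dark slab cannot communicate; pairs
    # brushing a slab face may pick up residual same-side PSF bleed, which
    # softens the stripe edges (the apparent gap width is approximate in
    # real cell-gap controls too)
    inner <- tb$column >= 12 & tb$column <= 14
    expect_true(all(tb$class[inner] == "no_communication"))
    expect_gte(sum(tb$class[spanning] == "no_communication"), 4L)
    # columns well inside each cell communicate internally
    interior <- tb$column <= 8 | tb$column >= 21
    expect_gt(mean(tb$class[interior] == "intra"), 0.6)
    # at a separation exceeding the gap plus the PSF reach, the averaged
    # cross-gap curve has no significant maximum even at very long times
    cc12 <- pcfCarpet(cpt, 12L)
    tm12 <- transitMap(cc12, barrierColumn = bc, tauMax = 1.5)
    sp12 <- transitTable(tm12)$column[transitTable(tm12)$spans_barrier]
    avg <- averageCurves(cc12, columns = sp12)
    expect_false(detectPeak(avg, tauMax = 1.5)$found)
})

test_that("barrier index arithmetic and sentinels", {
    mk_map <- function(span_tau, intra_tau) {
        tab <- data.frame(
            column = seq_along(c(span_tau, intra_tau)),
            position_um = 0,
            tau_peak_s = c(span_tau, intra_tau),
            amplitude = 0.1, significance = 10,
            class = rep(c("barrier_delayed", "intra"),
                c(length(span_tau), length(intra_tau))),
            spans_barrier = rep(c(TRUE, FALSE),
                c(length(span_tau), length(intra_tau))))
        new("TransitMap", table = tab, deltaPixels = 9L,
            thresholds = list(), barrierColumn = 4)
    }
    # 250 ms across the envelope over 5 ms within: the ~50-fold slowdown
    expect_equal(barrierIndex(mk_map(0.25, 0.005)), 50)
    # no barrier-delayed columns: sentinel, never silently 1
    expect_true(is.na(barrierIndex(mk_map(numeric(0), 0.005))))
    # median stability: duplicating identical columns changes nothing
    expect_equal(barrierIndex(mk_map(rep(0.25, 4), rep(0.005, 6))), 50)
})

test_that("directional analysis returns paired maps and the delay ratio", {
    res <- quickSim(nLines = 20000, D = 12.5, nParticles = 150, seed = 47)
    da <- directionalAnalysis(carpet(res), 5, barrierColumn = 16)
    expect_s4_class(da$forward, "TransitMap")
    expect_s4_class(da$backward, "TransitMap")
    expect_identical(deltaPixels(da$forward), 5L)
    expect_identical(deltaPixels(da$backward), -5L)
    expect_true(is.numeric(da$asymmetry))
    expect_error(directionalAnalysis(carpet(res), 5, barrierColumn = 40),
        "inside")
})
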