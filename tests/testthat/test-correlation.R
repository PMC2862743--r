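test_that("constant columns give exactly zero correlation", {
    cpt <- LineScanCarpet(matrix(6L, 2048, 4), 0.1, 6.3e-6, 4.73e-4)
    for (scheme in c("multitau", "direct")) {
        cv <- computeACF(cpt, 2, scheme = scheme)
        expect_identical(unique(corrValues(cv)), 0)
    }
})

test_that("i.i.d. Poisson counts stay inside the null band at every lag", {
    n <- 4096
    for (seed in 1:4) {
        cpt <- poissonCarpet(n, 2, lambda = 5, seed = seed)
        cv <- computeACF(cpt, 1)
        expect_true(all(abs(corrValues(cv)) < 4 / sqrt(n)),
            info = paste("seed", seed))
    }
})

test_that("pCF at zero separation is the ACF, bit-exact", {
    cpt <- carpet(quickSim(nLines = 2048, nParticles = 40))
    expect_identical(corrValues(computePCF(cpt, 5, 5)),
                     corrValues(computeACF(cpt, 5)))
})

test_that("multi-tau equals the exhaustive direct estimator everywhere", {
    cpt <- carpet(quickSim(nLines = 4096, nParticles = 40))
    for (pair in list(c(3L, 3L), c(3L, 8L), c(10L, 5L))) {
        mt <- computePCF(cpt, pair[1], pair[2], scheme = "multitau")
        dr <- computePCF(cpt, pair[1], pair[2], scheme = "direct")
        expect_identical(lags(mt), lags(dr))
        expect_lt(max(abs(corrValues(mt) - corrValues(dr))), 1e-12)
    }
    # also on pure noise, where no structure could mask a discrepancy
    np <- poissonCarpet(2048, 3, seed = 9)
    expect_lt(max(abs(corrValues(computePCF(np, 1, 3)) -
                      corrValues(computePCF(np, 1, 3, scheme = "direct")))),
        1e-12)
})

test_that("the lag grid matches the documented multi-tau design", {
    n <- 8192L
    cpt <- poissonCarpet(n, 2, seed = 4)
    cv <- computeACF(cpt, 1)
    ref <- referenceLagGrid(n)
    expect_equal(lags(cv), ref$lag * linePeriod(cpt))
    expect_identical(cv@binFactor, as.integer(ref$bin))
    # intra-line offset shifts pCF lags by delta * dwell, exactly
    cv2 <- computePCF(cpt, 1, 2)
    expect_equal(lags(cv2) - lags(cv), rep(pixelDwell(cpt), length(lags(cv))))
})

test_that("estimator is invariant to global intensity rescaling", {
    cpt <- poissonCarpet(2048, 2, seed = 12)
    doubled <- LineScanCarpet(counts(cpt) * 2L, 0.1, 6.3e-6, 4.73e-4)
    expect_equal(corrValues(computePCF(doubled, 1, 2)),
                 corrValues(computePCF(cpt, 1, 2)), tolerance = 1e-12)
})

test_that("zero-mean columns raise a normalization error", {
    m <- cbind(matrix(3L, 1200, 1), 0L)
    cpt <- LineScanCarpet(m, 0.1, 6.3e-6, 4.73e-4)
    expect_error(computeACF(cpt, 2), "zero")
    expect_error(computeACF(poissonCarpet(512, 2), 1), "1024")
})

test_that("free-diffusion ACF decays on the focal residence timescale", {
    # D = 12.5 um^2/s, w0 = 0.25 um: tau_D = w0^2/4D ~ 1.25 ms. The
    # half-decay lag (relative to the first measured lag) must match the
    # closed-form model prediction within a factor 1.5.
    res <- quickSim(nLines = 30000, D = 12.5, nParticles = 150, seed = 21)
    avg <- averageCurves(pcfCarpet(carpet(res), 0))
    G <- corrValues(avg); L <- lags(avg)
    i_half <- which(G < G[1] / 2)[1]
    psf <- psfModel(0.25)
    model <- modelACF3D(L, N = 1, D = 12.5, psf = psf)
    expected <- L[which(model < model[1] / 2)[1]]
    expect_gt(L[i_half], expected / 1.5)
    expect_lt(L[i_half], expected * 1.5)
})

test_that("pCF beyond the waist: anti-correlated start, delayed maximum", {
    # at 0.8 um separation (> 3 w0) the residual PSF overlap is negligible
    # and the single-molecule exclusion shows as a negative start; the box
    # is a fully illuminated slab so that no slow out-of-view reservoir
    # masks the (1/N-sized) dip
    res <- quickSim(nLines = 30000, D = 12.5, nParticles = 150, seed = 22,
        box = c(4.1, 1.5, 6))
    cc <- pcfCarpet(carpet(res), 8L)
    avg <- averageCurves(cc)
    v <- corrValues(avg)
    expect_lt(mean(v[1:3]), 0)              # spatial anti-bunching
    expect_gt(max(v[-(1:3)]), 0)            # later transit maximum
    # the maximum sits near the predicted transit delay, not at the start
    # (searched beyond 2 ms: a 0.8 um transit cannot be faster, and the
    # anti-correlated lags below form the baseline segment)
    pk <- detectPeak(avg, tauMin = 0.002)
    expect_true(pk$found)
    th <- peakTimeTheory(12.5, 0.8, psfModel(0.25))$tauPeak
    expect_gt(pk$tauPeak, th / 4)
    expect_lt(pk$tauPeak, th * 4)
})

test_that("pcfCarpet: delta 0 reproduces the ACF carpet; origins respected", {
    cpt <- carpet(quickSim(nLines = 2048, nParticles = 40))
    cc0 <- pcfCarpet(cpt, 0)
    expect_identical(origins(cc0), 1:32)
    expect_identical(corrValues(curves(cc0)[[7]]),
                     corrValues(computeACF(cpt, 7)))
    cc <- pcfCarpet(cpt, 8)
    expect_identical(origins(cc), 1:24)
    expect_error(pcfCarpet(cpt, 8, columns = 30), "outside")
})

test_that("curve averaging: identity, cancellation, and sd bookkeeping", {
    cpt <- carpet(quickSim(nLines = 2048, nParticles = 40))
    cv <- computeACF(cpt, 3)
    same <- averageCurves(list(cv, cv, cv))
    expect_equal(corrValues(same), corrValues(cv))
    expect_identical(length(same@sd), 0L)   # too few members to weight with
    nine <- averageCurves(rep(list(cv), 9))
    expect_equal(unique(nine@sd), 0)

    neg <- cv
    neg@values <- -corrValues(cv)
    zero <- averageCurves(list(cv, neg))
    expect_equal(unique(corrValues(zero)), 0)

    cc <- pcfCarpet(cpt, 0, columns = 1:3)
    avg <- averageCurves(cc)
    expect_equal(corrValues(avg),
        rowMeans(vapply(curves(cc), corrValues, numeric(length(lags(cc))))))
    expect_error(averageCurves(list(cv, computePCF(cpt, 1, 4))),
        "separation")
})

test_that("3-pixel block averaging tightens the peak-delay scatter", {
    # isotropy: every column of a uniform simulation sees the same transit
    # delay, and block averaging reduces the column-to-column scatter
    res <- quickSim(nLines = 30000, D = 12.5, nParticles = 150, seed = 23)
    cpt <- carpet(res)
    cc <- pcfCarpet(cpt, 5L)
    single <- vapply(curves(cc), function(cv) {
        p <- detectPeak(cv)
        if (p$found) p$tauPeak else NA_real_
    }, numeric(1))
    blocks <- lapply(seq(1, 25, by = 3), function(o)
        averageCurves(cc, columns = o:(o + 2)))
    block <- vapply(blocks, function(cv) {
        p <- detectPeak(cv)
        if (p$found) p$tauPeak else NA_real_
    }, numeric(1))
    expect_gt(mean(!is.na(block)), 0.7)
    expect_lte(stats::mad(block, na.rm = TRUE),
               stats::mad(single, na.rm = TRUE) + 1e-9)
})

test_that("detrending restores stationarity and removes the drift plateau", {
    n <- 8192
    set.seed(31)
    base <- rpois(n, 10)
    # a drift-free series passes through: exactly for a constant record,
    # within the sampling wobble of the moving average for a noisy one
    expect_equal(detrendColumn(rep(7, n), 512), rep(7, n), tolerance = 1e-6)
    expect_equal(detrendColumn(base, 512), base * 1, tolerance = 0.2)

    ramp <- seq(1, 1.2, length.out = n)          # 20 percent linear ramp
    drifted <- base * ramp
    fixed <- detrendColumn(drifted, 512)
    metric <- function(x) {
        wm <- vapply(split(x[1:8000], rep(1:16, each = 500)), mean, 1)
        (max(wm) - min(wm)) / mean(x)
    }
    expect_gt(metric(drifted), 0.1)
    expect_lt(metric(fixed), 0.02)

    # stationary input passes through nearly unchanged in its correlation
    still <- detrendColumn(base, 1024)
    expect_equal(mean(still), mean(base), tolerance = 1e-3)

    # a bleaching record gains a long-lag ACF plateau; detrending removes it
    bleach <- rpois(n, 10 * exp(-seq_len(n) / n * 0.5))
    mkcpt <- function(col) LineScanCarpet(
        cbind(as.integer(round(col)), as.integer(round(col))),
        0.1, 6.3e-6, 4.73e-4)
    g_raw <- corrValues(computeACF(mkcpt(bleach), 1))
    g_fix <- corrValues(computeACF(mkcpt(detrendColumn(bleach, 512)), 1))
    tail_idx <- seq(length(g_raw) - 15, length(g_raw))
    expect_gt(mean(g_raw[tail_idx]), 0.005)
    expect_lt(mean(abs(g_fix[tail_idx])), 0.005)

    expect_error(detrendColumn(base, 8), ">= 16")
})
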