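test_that("config validation rejects non-physical settings before sampling", {
    expect_error(simConfig(pCross = 1.5), "0, 1")
    expect_error(simConfig(dLeft = -1), "positive")
    expect_error(simConfig(box = c(5, 0.5, 6)), "6 \\* w0")
    expect_error(simConfig(activeEnabled = TRUE), "barrier")
    expect_error(simConfig(barrierX = 99), "inside the box")
    expect_error(simConfig(linePeriod = 1e-5), "linePeriod")
    expect_error(simConfig(seed = 1.5), "seed")
})

test_that("dark and blocked configurations behave exactly", {
    dark <- simConfig(nLines = 1100, nParticles = 10, brightness = 0,
        background = 0, seed = 2, burnIn = 0)
    expect_identical(sum(counts(carpet(simulateCarpet(dark)))), 0L)

    # impenetrable barrier: zero crossing events over any horizon
    blocked <- simConfig(nLines = 3000, barrierX = "center", pCross = 0,
        nParticles = 40, seed = 3, burnIn = 0.2)
    res <- simulateCarpet(blocked)
    expect_identical(nrow(crossingEvents(res)), 0L)
})

test_that("simulation is bit-reproducible for a seed and conserves matter", {
    cfg <- simConfig(nLines = 1500, nParticles = 30, barrierX = "center",
        pCross = 0.1, seed = 11, burnIn = 0.1)
    r1 <- simulateCarpet(cfg)
    r2 <- simulateCarpet(cfg)
    expect_identical(counts(carpet(r1)), counts(carpet(r2)))
    expect_identical(crossingEvents(r1), crossingEvents(r2))

    cfg2 <- cfg; cfg2@seed <- 12
    expect_false(identical(counts(carpet(simulateCarpet(cfg2))),
                           counts(carpet(r1))))

    # particle number is conserved exactly, translocation states included
    active <- simConfig(nLines = 2000, nParticles = 25, barrierX = "center",
        pCross = 0.02, activeEnabled = TRUE, pActive = 0.5,
        translocationMean = 5e-3, seed = 4, burnIn = 0.2)
    occ <- simulateCarpet(active, photons = FALSE)@occupancy
    expect_true(all(rowSums(occ) == 25))
    expect_gt(max(occ[, 3]), 0)    # the channel is actually used
})

test_that("free Brownian propagator: MSD grows as 2Dt per axis", {
    D <- 5
    cfg <- simConfig(nLines = 2000, nParticles = 100, dLeft = D,
        box = c(20, 20, 20), brightness = 0, seed = 9, burnIn = 0)
    res <- simulateCarpet(cfg, positionStride = 1L, photons = FALSE)
    lp <- cfg@linePeriod
    for (k in c(5, 20)) {
        for (ax in c("y", "z")) {
            p <- res@positions[[ax]]
            idx <- seq(1, nrow(p) - k, by = k)      # non-overlapping
            d2 <- (p[idx + k, ] - p[idx, ])^2
            msd <- mean(d2)
            se <- stats::sd(d2) / sqrt(length(d2))
            expect_lt(abs(msd - 2 * D * k * lp), 3 * se + 0.02 * 2 * D * k * lp)
        }
    }
})

test_that("mean photon count matches background + brightness * <sum W>", {
    cfg <- simConfig(nLines = 4000, nParticles = 120, brightness = 0.8,
        background = 0.05, seed = 13)
    res <- simulateCarpet(cfg)
    psf <- cfg@psf
    intW <- psf@w0^2 * psf@wz * (pi / 2)^(3 / 2)
    expected <- cfg@background +
        cfg@brightness * cfg@nParticles * intW / prod(cfg@box)
    expect_equal(mean(counts(carpet(res))), expected, tolerance = 0.1)
})

test_that("detailed balance: passive crossings are direction-symmetric", {
    cfg <- simConfig(nLines = 30000, nParticles = 80, barrierX = "center",
        dLeft = 12.5, dRight = 5.5, pCross = 0.05, brightness = 0,
        seed = 17, burnIn = 1)
    res <- simulateCarpet(cfg, photons = FALSE)
    ev <- crossingEvents(res)
    nLR <- sum(ev$direction == "left_to_right")
    nRL <- sum(ev$direction == "right_to_left")
    expect_gt(nLR + nRL, 100)
    expect_lt(abs(nLR - nRL), 4 * sqrt(nLR + nRL))
    # and the occupancy ratio sits at the volume ratio (1, centered barrier)
    expect_equal(realizedKeq(res), 1, tolerance = 0.15)
})

test_that("directional carrier pumps the occupancy ratio above one", {
    cfg <- simConfig(nLines = 30000, nParticles = 80, barrierX = "center",
        dLeft = 12.5, dRight = 5.5, pCross = 0.02, activeEnabled = TRUE,
        activeDirection = "right_to_left", pActive = 0.5,
        translocationMean = 5e-3, brightness = 0, seed = 19, burnIn = 2)
    out <- steadyStateKeq(cfg, horizon = 14)
    expect_gt(out$keq, 1.2)
    # active events flow toward the nucleus (left)
    res <- simulateCarpet(cfg, photons = FALSE)
    ev <- crossingEvents(res)
    act <- ev[ev$type == "active", ]
    expect_gt(nrow(act), 10)
    expect_true(all(act$direction == "right_to_left"))
})

test_that("first-passage oracle: censoring, free limit, monotonicity", {
    cfg <- simConfig(barrierX = "center", dLeft = 12.5, dRight = 5.5,
        nLines = 100, seed = 23)

    blocked <- cfg; blocked@pCross <- 0
    out <- meanCrossingTime(blocked, 0.5, nRep = 100, horizon = 0.05)
    expect_identical(out$nCensored, 100L)
    expect_true(is.na(out$mean))

    # p = 1: agrees with an independent 1-D random-walk simulation
    open <- cfg; open@pCross <- 1
    got <- meanCrossingTime(open, 0.5, nRep = 300, horizon = 4, seed = 5)
    set.seed(99)
    oracle <- replicate(300, {
        x <- open@barrierX - 0.5
        t <- 0; k <- 0
        dts <- c(rep(cfg@pixelDwell, cfg@nPixels),
                 cfg@linePeriod - cfg@nPixels * cfg@pixelDwell)
        repeat {
            dt <- dts[k %% length(dts) + 1]; k <- k + 1
            D <- if (x > open@barrierX) 12.5 else 12.5
            x2 <- x + sqrt(2 * 12.5 * dt) * rnorm(1)
            if (x2 < 0) x2 <- -x2
            if (x2 > cfg@box[1]) x2 <- 2 * cfg@box[1] - x2
            t <- t + dt
            if ((x - open@barrierX) * (x2 - open@barrierX) < 0) break
            x <- x2
            if (t > 4) break
        }
        if (t > 4) NA else t
    })
    expect_lt(abs(got$mean - mean(oracle, na.rm = TRUE)),
        2 * (got$sd / sqrt(got$nRep - got$nCensored) +
             stats::sd(oracle, na.rm = TRUE) / sqrt(sum(!is.na(oracle)))) +
        0.1 * got$mean)

    # mean crossing time strictly decreases as transmission rises
    mct <- vapply(c(0.01, 0.1, 1), function(p) {
        c2 <- cfg; c2@pCross <- p
        meanCrossingTime(c2, 0.5, nRep = 300, horizon = 20, seed = 7)$mean
    }, numeric(1))
    expect_true(all(diff(mct) < 0))
})

test_that("permeability calibration hits its target and is monotone", {
    cfg <- simConfig(barrierX = "center", dLeft = 12.5, dRight = 5.5,
        nLines = 100, box = c(4.1, 3, 6), seed = 31)

    free <- meanCrossingTime({c2 <- cfg; c2@pCross <- 1; c2}, 0.5,
        nRep = 300, horizon = 3, seed = 8)$mean
    # target equal to the free-diffusion passage: transparent barrier
    cal_free <- calibratePermeability(free, cfg, startOffset = 0.5,
        nRep = 300, seed = 8)
    expect_gte(cal_free$pCross, 0.5)

    cal <- calibratePermeability(0.25, cfg, startOffset = 0.5, nRep = 300,
        seed = 8)
    expect_lt(abs(cal$achievedMean - 0.25), 0.1 * 0.25)
    cal2 <- calibratePermeability(0.5, cfg, startOffset = 0.5, nRep = 300,
        seed = 8)
    expect_lt(cal2$pCross, cal$pCross)     # slower crossing, tighter barrier

    expect_error(calibratePermeability(free / 50, cfg, startOffset = 0.5,
        nRep = 200, seed = 8), "infeasible")
})

test_that("YAML configuration round-trips with strict key checking", {
    dir <- withr::local_tempdir()
    path <- file.path(dir, "sim.yaml")
    writeLines(c("preset: standard_scan", "n_lines: 1500", "d_left: 12.5",
        "n_particles: 25", "seed: 6"), path)
    cfg <- readSimConfig(path)
    expect_identical(cfg@nPixels, 32L)
    expect_identical(cfg@pixelDwell, 6.3e-6)
    expect_identical(cfg@linePeriod, 4.73e-4)
    expect_identical(cfg@nLines, 1500L)
    expect_identical(cfg@nParticles, 25L)

    writeLines(c("n_lines: 100", "wobble: 3", "seed: 1"), path)
    expect_error(readSimConfig(path), "wobble")
    writeLines(c("n_lines: 100"), path)
    expect_error(readSimConfig(path), "seed")
    writeLines(c("preset: exotic", "seed: 1"), path)
    expect_error(readSimConfig(path), "preset")
})
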