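makePsd <- function(u, S, n = rep(1L, length(u))) {
    new("RadialPSD", u = u, S = S, n = as.integer(n))
}

test_that("noiseless power laws are fitted exactly", {
    u <- c(0.1, 0.2, 0.4)
    f <- fitSignalTrend(makePsd(u, 3 * u^-2), FitRange(0.05, 0.5))
    expect_equal(f@a, -2, tolerance = 1e-12)
    expect_equal(f@P, 3, tolerance = 1e-12)
    expect_true(f@valid)
    expect_equal(f@nPoints, 3L)
})

test_that("constant spectra fit with zero slope and are flagged", {
    u <- seq(0.1, 1, by = 0.1)
    f <- fitSignalTrend(makePsd(u, rep(2.5, 10)), FitRange(0.05, 2))
    expect_equal(f@a, 0, tolerance = 1e-12)
    expect_equal(f@P, 2.5, tolerance = 1e-12)
    expect_false(f@valid)
    expect_error(kneeFrequency(f,
        new("NoiseFloor", Snf = 1, range = FitRange(1, 2),
            nPoints = 1L)), "no knee")
})

test_that("log-log OLS matches an independent normal-equations oracle", {
    set.seed(31)
    u <- 10^seq(-2, 0, length.out = 20)
    eps <- rnorm(20, 0, 0.05)
    S <- 7 * u^-3.2 * 10^eps
    f <- fitSignalTrend(makePsd(u, S), FitRange(1e-3, 2))
    X <- cbind(1, log10(u))
    beta <- solve(t(X) %*% X, t(X) %*% log10(S))
    expect_equal(f@P, 10^beta[1], tolerance = 1e-10)
    expect_equal(f@a, beta[2], tolerance = 1e-10)

    # count-weighted variant against weighted normal equations
    n <- rep(c(2L, 10L), 10)
    fw <- fitSignalTrend(makePsd(u, S, n), FitRange(1e-3, 2),
                         weighted = TRUE)
    W <- diag(as.numeric(n))
    bw <- solve(t(X) %*% W %*% X, t(X) %*% W %*% log10(S))
    expect_equal(fw@a, bw[2], tolerance = 1e-10)
})

test_that("unusable bins are excluded or raise errors", {
    u <- c(0.1, 0.2, 0.3, 0.4)
    expect_warning(
        f <- fitSignalTrend(makePsd(u, c(1, 0, 0.5, 0.25)),
                            FitRange(0.05, 0.5)),
        "non-positive")
    expect_equal(f@nPoints, 3L)
    expect_error(fitSignalTrend(makePsd(u, u^-2), FitRange(2, 3)),
                 "insufficient")
    # n = 0 bins never enter
    f0 <- fitSignalTrend(makePsd(u, u^-2, c(1L, 0L, 1L, 1L)),
                         FitRange(0.05, 0.5))
    expect_equal(f0@nPoints, 3L)
})

test_that("noise floor is the plain average of in-range bins", {
    u <- c(1, 1.2, 1.4)
    nf <- estimateNoiseFloor(makePsd(u, c(1.0, 1.2, 0.8)),
                             FitRange(0.9, 1.5))
    expect_equal(nf@Snf, 1.0)
    expect_equal(nf@nPoints, 3L)
    one <- estimateNoiseFloor(makePsd(u, c(1, 2, 3)),
                              FitRange(1.1, 1.3))
    expect_equal(one@Snf, 2)
    med <- estimateNoiseFloor(makePsd(u, c(1, 1.1, 50)),
                              FitRange(0.9, 1.5), stat = "median")
    expect_equal(med@Snf, 1.1)
    expect_error(estimateNoiseFloor(makePsd(u, u), FitRange(5, 6)),
                 "insufficient")
})

test_that("white-noise images show a flat floor at the 2-D PSD mean", {
    set.seed(33)
    n <- 64L
    m <- ElementalMap(matrix(rnorm(n * n, 0, 2), n, n), 1, 1)
    S2 <- psd2d(signedAmplitude(m))
    psd <- azimuthalAverage(S2, nBins = 16)
    nf <- estimateNoiseFloor(psd, FitRange(0.3, 0.71))
    # oracle: direct mean over the full 2-D grid minus DC
    ur <- sqrt(outer(S2@uy^2, S2@ux^2, "+"))
    full <- mean(mapValues(S2)[ur > 0])
    expect_equal(nf@Snf, full, tolerance = 0.1)
})

test_that("knee frequency solves P u^a = S_nf", {
    PL <- function(P, a) new("PowerLawFit", P = P, a = a,
        range = FitRange(0.01, 1), nPoints = 2L, valid = a < 0)
    NF <- function(s) new("NoiseFloor", Snf = s,
        range = FitRange(1, 2), nPoints = 1L)
    expect_equal(kneeFrequency(PL(1, -2), NF(1e-4)), 100)
    expect_equal(kneeFrequency(PL(5, -1), NF(5)), 1)
    set.seed(35)
    for (i in 1:25) {
        P <- 10^runif(1, -2, 4); a <- runif(1, -7, -0.5)
        s <- P * runif(1, 1e-6, 1e-2)
        uk <- kneeFrequency(PL(P, a), NF(s))
        expect_equal(P * uk^a, s, tolerance = 1e-12)
    }
    # floor above the trend at the fit's low end: extrapolation warning
    expect_warning(kneeFrequency(PL(1, -2), NF(1e6)), "below")
})

test_that("resolution frequency and half-period follow closed form", {
    f <- new("PowerLawFit", P = 1, a = -2, range = FitRange(0.01, 1),
             nPoints = 2L, valid = TRUE)
    nf <- new("NoiseFloor", Snf = 1e-4, range = FitRange(1, 2),
              nPoints = 1L)
    r <- resolutionFrequency(f, nf, snrRes = 5)
    expect_equal(uRes(r), (5e-4)^(-1 / 2), tolerance = 1e-12)
    expect_equal(deltaRes(r), 0.0111803, tolerance = 1e-5)
    expect_equal(uKnee(r), 100)
    expect_equal(deltaKnee(r), 1 / 200)

    r1 <- resolutionFrequency(f, nf, snrRes = 1)
    expect_identical(uRes(r1), uKnee(r1))
    expect_error(resolutionFrequency(f, nf, snrRes = 0))
})

test_that("delta_res grows with snr threshold and with the floor", {
    f <- new("PowerLawFit", P = 50, a = -4.5,
             range = FitRange(0.01, 1), nPoints = 2L, valid = TRUE)
    NF <- function(s) new("NoiseFloor", Snf = s,
        range = FitRange(1, 2), nPoints = 1L)
    snrs <- c(1, 2, 5, 10, 50)
    d <- vapply(snrs, function(s)
        deltaRes(resolutionFrequency(f, NF(1e-3), snrRes = s)),
        numeric(1))
    expect_true(all(diff(d) > 0))
    floors <- 10^seq(-5, -1)
    dS <- vapply(floors, function(s)
        deltaRes(resolutionFrequency(f, NF(s))), numeric(1))
    expect_true(all(diff(dS) > 0))
})

test_that("global PSD rescaling leaves the resolution unchanged", {
    psd <- cleanPowerlawPsd()
    sig <- FitRange(0.5, 3); noi <- FitRange(14, 20)
    r1 <- estimateResolution(psd, sig, noi)
    for (k in c(1e-6, 0.37, 1e4)) {
        scaled <- new("RadialPSD", u = psd@u, S = psd@S * k,
                      n = psd@n)
        r2 <- estimateResolution(scaled, sig, noi)
        expect_equal(uKnee(r2), uKnee(r1), tolerance = 1e-12)
        expect_equal(deltaRes(r2), deltaRes(r1), tolerance = 1e-12)
    }
})

test_that("Wiener filter is a unit-interval, knee-centred rolloff", {
    f <- new("PowerLawFit", P = 1, a = -2, range = FitRange(0.01, 1),
             nPoints = 2L, valid = TRUE)
    nf <- new("NoiseFloor", Snf = 1e-4, range = FitRange(1, 2),
              nPoints = 1L)
    uk <- kneeFrequency(f, nf)
    w <- wienerFilter(f, nf, c(1e-6, 1, uk, 200, 1e4))
    expect_equal(w@W[3], 0.5, tolerance = 1e-12)    # at the knee
    expect_equal(w@W[1], 1, tolerance = 1e-6)       # u -> 0 limit
    expect_equal(w@W[4], 0.2, tolerance = 1e-12)    # hand arithmetic
    expect_true(all(diff(w@W) <= 0))                 # monotone
    expect_true(all(w@W >= 0 & w@W <= 1))
})

test_that("sensitivity scan reports per-range results and spread", {
    # floor-free power law: every selection fits the same trend
    pure <- makePowerlawPsd(1e3, -5, 0, u = seq(0.5, 20, by = 0.1))
    noi <- FitRange(14, 20)
    rs <- list(FitRange(0.5, 1.5), FitRange(0.8, 2.5),
               FitRange(0.5, 3))
    sens <- sensitivityScan(pure, rs, noi)
    expect_equal(sens$spread, 0, tolerance = 1e-8)
    expect_length(sens$results, 3L)
    psd <- cleanPowerlawPsd()

    # multiplicative scatter: spread stays within the fixture bound
    noisy <- makePowerlawPsd(1e3, -5, 1e-2, u = seq(0.5, 20, by = 0.1),
                             scatterDf = 200, seed = 77)
    s2 <- sensitivityScan(noisy, rs, noi)
    expect_lt(s2$spread, 0.10)

    # a failing range is reported, others continue
    s3 <- sensitivityScan(psd, c(rs, list(FitRange(30, 40))), noi)
    expect_true(is.na(s3$deltaRes[4]))
    expect_s4_class(s3$results[[1]], "ResolutionResult")
    expect_error(sensitivityScan(psd, rs[1], noi))
})

test_that("range suggestion heuristic splits near the knee", {
    psd <- cleanPowerlawPsd()       # knee at u = 10
    rg <- suggestFitRanges(psd)
    expect_lt(rg$signalRange@uHi, 14)
    expect_gt(rg$noiseRange@uLo, 6)
    r <- estimateResolution(psd, rg$signalRange, rg$noiseRange)
    expect_equal(deltaRes(r), 1 / (2 * (5e-5)^(-1 / 5)),
                 tolerance = 0.05)
})

test_that("mapResolution runs the full pipeline on an odd-sized map", {
    sc <- simulateScan(makePhantom(shape = c(95, 97), seed = 5),
                       seed = 6)
    r <- mapResolution(sc, signalRange = c(0.02, 0.08),
                       noiseRange = c(0.35, 0.6))
    expect_s4_class(r, "ResolutionResult")
    expect_gt(deltaRes(r), 0)
    expect_gte(deltaRes(r), deltaKnee(r))
})
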