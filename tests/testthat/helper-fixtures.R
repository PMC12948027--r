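# fixtures built in code; no stored data

# PowerSpectrum2D with values prescribed by f(ur) on an even grid
analyticSpectrum <- function(n = 32L, dx = 1, dy = 1,
                             f = function(ur) ur^0) {
    S2 <- psd2d(signedAmplitude(
        ElementalMap(matrix(1, n, n), dx, dy)))
    ur <- sqrt(outer(S2@uy^2, S2@ux^2, "+"))
    v <- f(ur)
    v[ur == 0] <- 0
    new("PowerSpectrum2D", values = v, ux = S2@ux, uy = S2@uy)
}

# independent radial binning oracle: plain loops over edges
oracleRadialBin <- function(S2, nBins, mask = NULL) {
    ur <- sqrt(outer(S2@uy^2, S2@ux^2, "+"))
    if (is.null(mask)) mask <- array(TRUE, dim(ur))
    mask <- mask & ur > 0
    edges <- seq(0, max(ur), length.out = nBins + 1)
    S <- n <- numeric(nBins)
    for (b in seq_len(nBins)) {
        sel <- mask & ur > edges[b] & ur <= edges[b + 1]
        n[b] <- sum(sel)
        S[b] <- if (n[b] > 0) mean(S2@values[sel]) else NA_real_
    }
    list(u = (edges[-1] + edges[-(nBins + 1)]) / 2, S = S, n = n)
}

# noiseless power-law-plus-floor RadialPSD on a wide grid whose knee
# (u = 10 for the default parameters) lies well inside the grid
cleanPowerlawPsd <- function(P = 1e3, a = -5, Snf = 1e-2) {
    makePowerlawPsd(P, a, Snf, u = seq(0.5, 20, by = 0.1))
}
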