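# small in-code fixtures shared across test files

# PairCounts with anchors laid out left to right on one chromosome
makePairs <- function(x1, x2, chrom = "chr1", width = 100L, gap = 1000L) {
    n <- length(x1)
    s1 <- seq_len(n) * (2L * gap)
    s2 <- s1 + gap
    PairCounts(
        GenomicRanges::GRanges(chrom, IRanges::IRanges(s1, s1 + width)),
        GenomicRanges::GRanges(chrom, IRanges::IRanges(s2, s2 + width)),
        cbind(as.integer(x1), as.integer(x2)))
}

# neutral feature table: identical covariates for every pair, so the
# weight priors carry no between-pair information
neutralFeatures <- function(pc, mc = 10, dist = 100) {
    covs <- priorCovariates(rep(mc, length(pc)), rep(mc, length(pc)),
                            rep(dist, length(pc)))
    cbind(S4Vectors::DataFrame(pairId = pairIds(pc)), covs)
}

# rejection sampler from the jointly truncated bivariate Poisson
rJointTrunc <- function(n, lam1, lam2, T = 2L) {
    out <- matrix(0L, 0, 2)
    while (nrow(out) < n) {
        x1 <- stats::rpois(2L * n, lam1)
        x2 <- stats::rpois(2L * n, lam2)
        keep <- pmax(x1, x2) >= T
        out <- rbind(out, cbind(x1[keep], x2[keep]))
    }
    out[seq_len(n), , drop = FALSE]
}

# rejection sampler from the product of two per-sample truncated Poissons
rBothTrunc <- function(n, lam1, lam2, T = 2L) {
    draw1 <- function(lam) {
        v <- stats::rpois(4L * n, lam)
        v <- v[v >= T]
        while (length(v) < n) v <- c(v, {
            w <- stats::rpois(4L * n, lam); w[w >= T] })
        v[seq_len(n)]
    }
    cbind(draw1(lam1), draw1(lam2))
}
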