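test_that("normalization scales the shallower sample and rounds half away", {
    pc <- makePairs(c(2L, 2L), c(4L, 4L))       # totals 4 vs 8, c = 2
    out <- pairCounts(normalizeCounts(pc))
    expect_equal(out[, 1], c(4L, 4L))
    expect_equal(out[, 2], c(4L, 4L))

    pc <- makePairs(c(3L, 1L), c(4L, 2L))       # totals 4 vs 6, c = 1.5
    out <- pairCounts(normalizeCounts(pc))
    expect_equal(out[, 1], c(5L, 2L))           # 4.5 -> 5 (half away)
    expect_equal(out[, 2], c(4L, 2L))           # untouched sample exact

    pc <- makePairs(c(10L, 10L), c(10L, 10L))   # equal totals: identity
    expect_identical(pairCounts(normalizeCounts(pc)), pairCounts(pc))

    expect_error(normalizeCounts(makePairs(c(0L, 0L), c(1L, 1L))),
                 "total count 0")
})

test_that("normalization totals agree within the rounding slack", {
    set.seed(5)
    for (rep in 1:20) {
        n <- sample(5:60, 1)
        pc <- makePairs(rpois(n, 6) + 1L, rpois(n, 11) + 1L)
        tot <- colSums(pairCounts(normalizeCounts(pc)))
        expect_lte(abs(tot[1] - tot[2]), n / 2)
    }
})

test_that("explicit scale overrides the computed factor", {
    pc <- makePairs(c(3L, 3L), c(1L, 1L))
    out <- pairCounts(normalizeCounts(pc, scale = 2))
    expect_equal(out[, 1], c(6L, 6L))
    expect_equal(out[, 2], c(1L, 1L))
})

test_that("screening modes implement joint-max and both-min supports", {
    pc <- makePairs(c(0L, 0L, 2L, 5L, 1L), c(1L, 2L, 2L, 1L, 1L))
    expect_equal(pairIds(screenPairs(pc, T = 2, mode = "joint_max")),
                 c(2L, 3L, 4L))
    expect_equal(pairIds(screenPairs(pc, T = 2, mode = "both_min")), 3L)
    # T = 1 keeps any pair with a positive count under joint_max
    expect_equal(length(screenPairs(pc, T = 1, mode = "joint_max")), 5L)
    expect_error(screenPairs(pc, T = 0), "T must be")
})

test_that("marginal counts match a brute-force double loop", {
    # worked example: pairs (A,B)=3, (A,C)=2, (B,C)=5 in sample one
    g <- function(s) GenomicRanges::GRanges("chr1",
        IRanges::IRanges(s, s + 99L))
    pc <- PairCounts(c(g(1), g(1), g(1000)),
                     c(g(1000), g(2000), g(2000)),
                     cbind(c(3L, 2L, 5L), c(0L, 0L, 0L)))
    mc <- marginalCounts(pc)
    # mc(A)=5, mc(B)=8, mc(C)=7 -> pair (A,B) marginal 13
    expect_equal(mc[, 1], c(13, 12, 15))
    expect_equal(mc[, 2], c(0, 0, 0))

    # single pair: own count contributes twice
    pc1 <- makePairs(4L, 0L)
    expect_equal(unname(marginalCounts(pc1)[1, 1]), 8)

    # property: random tables vs brute force
    set.seed(42)
    for (rep in 1:5) {
        n <- 60
        frag <- sample(20, 2 * n, replace = TRUE)
        a <- frag[seq_len(n)]; b <- frag[n + seq_len(n)]
        keep <- a != b
        a <- a[keep]; b <- b[keep]
        starts <- (1:20) * 500L
        pc <- PairCounts(g(starts[a]), g(starts[b]),
                         cbind(rpois(length(a), 3), rpois(length(a), 3)))
        mc <- marginalCounts(pc)
        cnt <- pairCounts(pc)
        for (s in 1:2) {
            fragMarg <- sapply(1:20, function(fr)
                sum(cnt[a == fr | b == fr, s]))
            expect_equal(mc[, s], fragMarg[a] + fragMarg[b])
        }
    }
})

test_that("pair distance is the min over the two anchoring orientations", {
    # anchor mids 100 and 1000; TFBS mid 120; TSS mids 200 and 990
    pc <- PairCounts(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(951, 1050)),
        cbind(2L, 2L))
    tfbs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(121, width = 1))
    tss <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(201, 991), width = 1))
    # min(20 + 10, 100 + 880) = 30
    expect_equal(as.numeric(pairDistance(pc, tfbs, tss)), 30)

    # site exactly at both mids -> 0 (substituted downstream)
    tfbs0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, width = 1))
    tss0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, width = 1))
    expect_equal(as.numeric(pairDistance(pc, tfbs0, tss0)), 0)
    expect_equal(priorCovariates(1, 1, 0)$dist, 0.5)

    # anchor-order invariance
    swapped <- PairCounts(anchorTwo(pc), anchorOne(pc), pairCounts(pc))
    expect_equal(as.numeric(pairDistance(swapped, tfbs, tss)),
                 as.numeric(pairDistance(pc, tfbs, tss)))
})

test_that("cross-chromosome sites are unreachable; ceiling flags pairs", {
    pc <- PairCounts(
        GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150)),
        GenomicRanges::GRanges("chr1", IRanges::IRanges(951, 1050)),
        cbind(2L, 2L))
    tfbs <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, width = 1))
    tss <- GenomicRanges::GRanges("chr9", IRanges::IRanges(5, width = 1))
    d <- pairDistance(pc, tfbs, tss, ceiling = 123)
    expect_equal(as.numeric(d), 123)
    expect_true(attr(d, "flagged"))
})

test_that("prior covariates substitute zeros by 0.5", {
    f <- priorCovariates(10, 4, 100)
    expect_equal(f$dmcDn, 6)
    expect_equal(f$dmcUp, 0.5)
    expect_equal(f$r1, 0.1)
    expect_equal(f$r2, 0.04)
    f2 <- priorCovariates(5, 5, 10)
    expect_equal(f2$dmcDn, 0.5)
    expect_equal(f2$dmcUp, 0.5)
    f3 <- priorCovariates(0, 0, 10)
    expect_equal(f3$r1, 0.5)
    expect_equal(f3$r2, 0.5)
    f4 <- as.data.frame(priorCovariates(c(0, 3), c(3, 0), c(0, 7)))
    expect_true(all(f4[, c("dist", "dmcDn", "dmcUp", "r1", "r2")] > 0))
})

test_that("feature table joins marginals, distance and covariates", {
    pc <- makePairs(c(3L, 2L), c(2L, 4L))
    tfbs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2040, width = 1))
    tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3040, width = 1))
    feats <- pairFeatures(pc, tfbs, tss)
    expect_named(as.data.frame(feats),
                 c("pairId", "mc1", "mc2", "dist", "dmcDn", "dmcUp",
                   "r1", "r2"))
    mc <- marginalCounts(pc)
    expect_equal(feats$mc1, mc[, 1])
    f <- withr::local_tempfile()
    writeFeatures(feats, f)
    expect_equal(nrow(utils::read.table(f, header = TRUE)), 2L)
})
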