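#' Normalize two-sample counts to a common depth
#'
#' Makes the two samples' counts comparable: the sample with the smaller
#' total is multiplied by \code{c = larger total / smaller total} and the
#' results are rounded to the nearest integers (halves away from zero);
#' the other sample is left untouched. An explicit \code{scale} overrides
#' the computed factor and is applied to sample one (this supports
#' normalizing by raw sequencing depth instead of pair totals, as done for
#' real libraries).
#'
#' @param x a \linkS4class{PairCounts} object; both column totals must be
#'   positive.
#' @param scale optional explicit factor applied to sample one.
#' @return A \linkS4class{PairCounts} with normalized counts.
#' @examples
#' pc <- PairCounts(
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 1), c(100, 100))),
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(c(501, 901), c(600, 1000))),
#'   cbind(c(2L, 3L), c(4L, 6L)))
#' pairCounts(normalizeCounts(pc))  # sample one doubled
#' @export
normalizeCounts <- function(x, scale = NULL) {
    cnt <- x@counts
    tot <- colSums(cnt)
    if (is.null(scale)) {
        if (any(tot == 0))
            stop("cannot normalize: a sample has total count 0")
        if (tot[1] <= tot[2]) {
            cnt[, 1] <- roundHalfAway(cnt[, 1] * (tot[2] / tot[1]))
        } else {
            cnt[, 2] <- roundHalfAway(cnt[, 2] * (tot[1] / tot[2]))
        }
    } else {
        if (scale <= 0) stop("scale must be positive")
        cnt[, 1] <- roundHalfAway(cnt[, 1] * scale)
    }
    storage.mode(cnt) <- "integer"
    out <- x
    out@counts <- cnt
    out
}

# round to nearest integer, halves away from zero
roundHalfAway <- function(v) sign(v) * floor(abs(v) + 0.5)

#' Screen fragment pairs by the count threshold T
#'
#' Removes pairs below the preprocessing cut-off used to weed out random
#' collisions. \code{"joint_max"} keeps pairs with \code{max(x1, x2) >= T}
#' (the support of the One-Step model's jointly truncated likelihood);
#' \code{"both_min"} keeps pairs with \code{min(x1, x2) >= T} (the support
#' of the per-sample truncated components of the Two-Step machinery).
#'
#' @param x a \linkS4class{PairCounts}.
#' @param T integer threshold, >= 1 (2 in the original preprocessing:
#'   pairs seen only once in both samples are taken to be random
#'   collisions).
#' @param mode \code{"joint_max"} or \code{"both_min"}.
#' @return The subset \linkS4class{PairCounts} (pair ids preserved).
#' @export
screenPairs <- function(x, T = 2L, mode = c("joint_max", "both_min")) {
    mode <- match.arg(mode)
    if (T < 1) stop("T must be >= 1")
    keep <- switch(mode,
        joint_max = pmax(x@counts[, 1], x@counts[, 2]) >= T,
        both_min  = pmin(x@counts[, 1], x@counts[, 2]) >= T)
    x[keep]
}

# fragment key: exact interval identity
.fragKey <- function(gr)
    paste0(as.character(seqnames(gr)), ":", start(gr), "-", end(gr))

#' Per-pair marginal counts
#'
#' The marginal count of a fragment in a sample is the sum of the counts of
#' all pairs containing that fragment; the marginal count of a pair is the
#' sum of its two fragments' marginals (so the pair's own count contributes
#' twice). Fragments are matched by exact interval identity. Marginal
#' counts express the within-sample dependency between pairs sharing a
#' fragment and drive the Dirichlet weight priors.
#'
#' @param x a \linkS4class{PairCounts} (normally normalized and screened:
#'   the priors should reflect the data the likelihood sees).
#' @return n x 2 matrix with columns \code{mc1}, \code{mc2}.
#' @export
marginalCounts <- function(x) {
    k1 <- .fragKey(x@anchor1)
    k2 <- .fragKey(x@anchor2)
    frag <- unique(c(k1, k2))
    i1 <- match(k1, frag)
    i2 <- match(k2, frag)
    mc <- matrix(0, length(x), 2L, dimnames = list(NULL, c("mc1", "mc2")))
    for (s in 1:2) {
        fm <- numeric(length(frag))
        cnt <- x@counts[, s]
        for (idx in list(i1, i2)) {
            agg <- rowsum(cnt, idx)
            fm[as.integer(rownames(agg))] <- fm[as.integer(rownames(agg))] +
                agg[, 1]
        }
        mc[, s] <- fm[i1] + fm[i2]
    }
    mc
}

.mids <- function(gr) floor((start(gr) - 1L + end(gr)) / 2)

# distance from each query midpoint to nearest site midpoint on the same
# chromosome; Inf where the chromosome has no site
.nearestMidDistance <- function(chrom, mid, sites) {
    smid <- .mids(sites)
    schrom <- as.character(seqnames(sites))
    out <- rep(Inf, length(mid))
    for (ch in unique(chrom)) {
        s <- sort(smid[schrom == ch])
        if (!length(s)) next
        q <- which(chrom == ch)
        idx <- findInterval(mid[q], s)
        lo <- pmax(idx, 1L)
        hi <- pmin(idx + 1L, length(s))
        out[q] <- pmin(abs(mid[q] - s[lo]), abs(mid[q] - s[hi]))
    }
    out
}

#' TFBS/TSS anchoring distance of each pair
#'
#' For each pair, the distance is the minimum over the two orientations of
#' (midpoint of one anchor to the nearest TFBS midpoint) + (midpoint of the
#' other anchor to the nearest gene TSS). Small distances mark pairs whose
#' anchors sit on a protein binding site and a promoter, i.e. plausible
#' mediated loops. Nearest sites are searched on the anchor's own
#' chromosome (base-pair distances across chromosomes are undefined); if
#' neither orientation is finite the pair is flagged and assigned
#' \code{ceiling}.
#'
#' @param x a \linkS4class{PairCounts}.
#' @param tfbs,tss non-empty \linkS4class{GRanges} site tracks (see
#'   [readAnnotation()]).
#' @param ceiling distance assigned when no same-chromosome site exists for
#'   any orientation (default 1e7 bp).
#' @return Numeric vector of distances in bp, with attribute
#'   \code{"flagged"} marking ceiling-assigned pairs. Exact zeros are kept
#'   here; they are replaced by 0.5 in [priorCovariates()].
#' @export
pairDistance <- function(x, tfbs, tss, ceiling = 1e7) {
    if (length(tfbs) == 0L || length(tss) == 0L)
        stop("annotation tracks must be non-empty")
    c1 <- as.character(seqnames(x@anchor1)); m1 <- .mids(x@anchor1)
    c2 <- as.character(seqnames(x@anchor2)); m2 <- .mids(x@anchor2)
    d1f <- .nearestMidDistance(c1, m1, tfbs)
    d1s <- .nearestMidDistance(c1, m1, tss)
    d2f <- .nearestMidDistance(c2, m2, tfbs)
    d2s <- .nearestMidDistance(c2, m2, tss)
    d <- pmin(d1f + d2s, d1s + d2f)
    flagged <- !is.finite(d)
    d[flagged] <- ceiling
    attr(d, "flagged") <- flagged
    d
}

#' Prior covariates of each pair
#'
#' Derives the quantities that parameterize the Dirichlet/beta weight
#' priors: the directional marginal-count differences
#' \code{dmcDn = max(mc1 - mc2, 0)} and \code{dmcUp = max(mc2 - mc1, 0)}
#' (which side lost or gained intensity), and the per-sample marginal-count
#' to distance ratios \code{r1 = mc1/dist}, \code{r2 = mc2/dist}. Any exact
#' zero among these is replaced by 0.5 so that no Dirichlet parameter can
#' vanish.
#'
#' @param mc1,mc2 non-negative marginal counts.
#' @param dist positive distances (zeros are substituted by 0.5 first).
#' @return \code{DataFrame} with columns \code{mc1, mc2, dist, dmcDn,
#'   dmcUp, r1, r2}; all covariates strictly positive.
#' @examples
#' priorCovariates(10, 4, 100)  # dmcDn 6, dmcUp 0.5, r1 0.1, r2 0.04
#' @export
priorCovariates <- function(mc1, mc2, dist) {
    if (any(dist < 0)) stop("dist must be non-negative")
    dist <- ifelse(dist == 0, 0.5, dist)
    sub0 <- function(v) ifelse(v == 0, 0.5, v)
    DataFrame(mc1 = mc1, mc2 = mc2, dist = dist,
              dmcDn = sub0(pmax(mc1 - mc2, 0)),
              dmcUp = sub0(pmax(mc2 - mc1, 0)),
              r1 = sub0(mc1 / dist),
              r2 = sub0(mc2 / dist))
}

#' Full per-pair feature table
#'
#' Convenience wrapper: marginal counts on the analysis set, anchoring
#' distances against the TFBS/TSS tracks, and the substituted prior
#' covariates, keyed by pair id.
#'
#' @inheritParams pairDistance
#' @return \code{DataFrame} with \code{pairId} plus the
#'   [priorCovariates()] columns.
#' @export
pairFeatures <- function(x, tfbs, tss, ceiling = 1e7) {
    mc <- marginalCounts(x)
    d <- pairDistance(x, tfbs, tss, ceiling = ceiling)
    out <- priorCovariates(mc[, 1], mc[, 2], as.numeric(d))
    out <- cbind(DataFrame(pairId = x@pairId), out)
    out
}

#' Export a feature table as TSV (for audit)
#'
#' @param feat a feature \code{DataFrame} from [pairFeatures()].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatures <- function(feat, path) {
    utils::write.table(as.data.frame(feat), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
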