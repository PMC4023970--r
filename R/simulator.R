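#' Synthetic fragment and pair libraries
#'
#' Builds the in-silico study design: 170 restriction fragments on 22
#' synthetic autosomes of 10 Mb, in three groups. Group A (52 fragments)
#' each carry exactly one binding site of the mediating protein (TFBS);
#' group B (52 fragments) each carry one gene TSS; group C (66 fragments,
#' three per autosome) carry neither. Each A/B fragment's distance is the
#' bp offset between the fragment midpoint and its site. The pair library
#' holds 4,912 pairs: pair set one (1,600) crosses the 40 smallest-distance
#' A fragments with the 40 smallest-distance B fragments; pair set two
#' (3,312) crosses 24 A-side fragments (12 random of the 40 plus the 12
#' largest-distance A) and likewise 24 B-side fragments with the 66 group-C
#' fragments (2 x 1,584 pairs), plus the 144 "gold" pairs joining the 12
#' largest-distance A with the 12 largest-distance B fragments.
#'
#' Fragment lengths are drawn uniformly on 2-10 kb and site offsets
#' uniformly within the fragment; only the distance ranking matters to the
#' models, not absolute genome identity.
#'
#' @param seed optional integer seed (the library is deterministic given
#'   the seed).
#' @return List with \code{fragments} (a \code{data.frame}: id, group,
#'   chrom, start, end, siteMid, fragDist), \code{pairs} (a
#'   \code{data.frame}: frag1, frag2, set), index vectors
#'   \code{aSmall, aLarge, bSmall, bLarge, lA, lB} (the selected A/B
#'   subsets), and \code{tfbs} / \code{tss} site \code{GRanges}.
#' @export
buildLibrary <- function(seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nChrom <- 22L
    chromLen <- 1e7
    nA <- 52L; nB <- 52L; nC <- 66L
    grp <- c(rep("A", nA), rep("B", nB), rep("C", nC))
    chrom <- c(sample(nChrom, nA + nB, replace = TRUE),
               rep(seq_len(nChrom), each = 3L))
    len <- round(stats::runif(nA + nB + nC, 2000, 10000))
    start <- floor(stats::runif(nA + nB + nC, 0, chromLen - len))
    end <- start + len
    siteMid <- rep(NA_real_, nA + nB + nC)
    ab <- seq_len(nA + nB)
    siteMid[ab] <- floor(start[ab] + stats::runif(nA + nB) * len[ab])
    mid <- floor((start + end) / 2)
    fragDist <- abs(mid - siteMid)
    frag <- data.frame(id = seq_along(grp), group = grp,
                       chrom = paste0("chrS", chrom),
                       start = start, end = end,
                       siteMid = siteMid, fragDist = fragDist)

    aIdx <- which(grp == "A"); bIdx <- which(grp == "B")
    cIdx <- which(grp == "C")
    aOrd <- aIdx[order(fragDist[aIdx])]
    bOrd <- bIdx[order(fragDist[bIdx])]
    aSmall <- aOrd[1:40]; aLarge <- aOrd[41:52]
    bSmall <- bOrd[1:40]; bLarge <- bOrd[41:52]

    setOne <- expand.grid(frag1 = aSmall, frag2 = bSmall)
    lA <- sample(aSmall, 12L)
    lB <- sample(bSmall, 12L)
    aSide <- c(lA, aLarge)
    bSide <- c(lB, bLarge)
    setTwo <- rbind(expand.grid(frag1 = aSide, frag2 = cIdx),
                    expand.grid(frag1 = bSide, frag2 = cIdx),
                    expand.grid(frag1 = aLarge, frag2 = bLarge))
    pairs <- rbind(cbind(setOne, set = 1L), cbind(setTwo, set = 2L))
    pairs$gold <- pairs$frag1 %in% aLarge & pairs$frag2 %in% bLarge

    tfbs <- GRanges(frag$chrom[aIdx],
                    IRanges(siteMid[aIdx] + 1L, width = 1L))
    tss <- GRanges(frag$chrom[bIdx],
                   IRanges(siteMid[bIdx] + 1L, width = 1L))
    list(fragments = frag, pairs = pairs,
         aSmall = aSmall, aLarge = aLarge,
         bSmall = bSmall, bLarge = bLarge, lA = lA, lB = lB,
         tfbs = GenomicRanges::sort(tfbs), tss = GenomicRanges::sort(tss))
}

#' Sampling probabilities and designated truth of one simulated dataset
#'
#' Dataset one: pair set one is split into a true-high half (the pairs
#' joining 20 random of the 40 A-side fragments with 20 random of the 40
#' B-side fragments, plus the pairs joining the complementary 20 with the
#' complementary 20) and a true-low half; the sampling-weight ratio of
#' true-high : true-low : set-two (false) pairs is 6 : 3 : 1.
#'
#' Dataset two perturbs dataset one: one high-set A fragment (f1) has all
#' 40 of its set-one pairs doubled (category 2), a second (f2) has its 20
#' high pairs halved (category 0), a third (f3) has all 40 of its pairs
#' set to the false weight (category 3); 10 random gold pairs are tripled
#' (category 4). Everything else keeps its dataset-one weight: unperturbed
#' set-one pairs are category 1, remaining set-two pairs category 5.
#' Weights are renormalized to sum to one.
#'
#' The random choices (high/low split, f1-f3, the 10 gold pairs) are made
#' on the first call and returned so both datasets share them: pass the
#' result of the dataset-one call as \code{design} when building dataset
#' two.
#'
#' @param library result of [buildLibrary()].
#' @param dataset 1 or 2.
#' @param design for \code{dataset = 2}, the value returned by the
#'   \code{dataset = 1} call (shared random design choices).
#' @return List with \code{prob} (per-pair sampling probabilities, summing
#'   to one), \code{weight} (the unnormalized weights), \code{truth}
#'   (per-pair joint category 0-5), \code{trueInSample} (designated
#'   true-pair indicator for this dataset), and the design choices
#'   (\code{highA, highB, f1, f2, f3, cat4Pairs}).
#' @export
samplingProbs <- function(library, dataset = 1, design = NULL) {
    pairs <- library$pairs
    n <- nrow(pairs)
    if (is.null(design)) {
        highA <- sample(library$aSmall, 20L)
        highB <- sample(library$bSmall, 20L)
        f123 <- sample(highA, 3L)
        cat4Pairs <- sample(which(pairs$gold), 10L)
        design <- list(highA = highA, highB = highB,
                       f1 = f123[1], f2 = f123[2], f3 = f123[3],
                       cat4Pairs = cat4Pairs)
    }
    design <- design[c("highA", "highB", "f1", "f2", "f3", "cat4Pairs")]
    lowA <- setdiff(library$aSmall, design$highA)
    lowB <- setdiff(library$bSmall, design$highB)
    isHigh <- (pairs$frag1 %in% design$highA &
               pairs$frag2 %in% design$highB) |
              (pairs$frag1 %in% lowA & pairs$frag2 %in% lowB)
    w <- ifelse(pairs$set == 1L, ifelse(isHigh, 6, 3), 1)

    truth <- ifelse(pairs$set == 1L, 1L, 5L)
    if (dataset == 2) {
        s1 <- pairs$set == 1L
        i1 <- s1 & pairs$frag1 == design$f1            # x2, category 2
        i2 <- s1 & pairs$frag1 == design$f2 &
              pairs$frag2 %in% design$highB            # x0.5, category 0
        i3 <- s1 & pairs$frag1 == design$f3            # false, category 3
        w[i1] <- 2 * w[i1]
        w[i2] <- w[i2] / 2
        w[i3] <- 1
        w[design$cat4Pairs] <- 3 * w[design$cat4Pairs] # category 4
        truth[i1] <- 2L; truth[i2] <- 0L; truth[i3] <- 3L
        truth[design$cat4Pairs] <- 4L
        trueInSample <- s1 & !i3
        trueInSample[design$cat4Pairs] <- TRUE
    } else {
        # joint truth labels are defined by the dataset-two design but
        # the per-sample designation for dataset one is simply set one
        trueInSample <- pairs$set == 1L
    }
    c(design,
      list(prob = w / sum(w), weight = w, truth = truth,
           trueInSample = trueInSample, dataset = dataset))
}

#' Retention probability of a sampled fragment pair
#'
#' A sampled pair contributes a usable inter-fragment ligation product
#' when the random grouping of the four fragment ends is inter-fragment
#' (2 of the 3 equally likely pairings of four ends) and at least one of
#' the two ligations succeeds:
#' \code{rho = (2/3) (1 - (1 - p)^2)}.
#'
#' @param ligationP per-ligation success probability.
#' @return The retention probability rho.
#' @examples
#' ligationRetention(0.8)  # 0.64
#' @export
ligationRetention <- function(ligationP) {
    stopifnot(ligationP > 0, ligationP <= 1)
    (2 / 3) * (1 - (1 - ligationP)^2)
}

#' Draw one dataset of fragment-pair counts
#'
#' \code{nDraws} pairs are sampled multinomially from the pair library
#' with the given probabilities; each draw is then independently retained
#' with probability [ligationRetention()] (count-level emulation of the
#' ligation and read-recovery losses); retained draws are summed into
#' per-pair counts.
#'
#' @param library result of [buildLibrary()].
#' @param probs result of [samplingProbs()].
#' @param nDraws number of sampled pairs (default 50,000).
#' @param ligationP ligation success probability (default 0.8).
#' @return Integer vector of per-pair counts (one per library pair).
#' @export
simulateCounts <- function(library, probs, nDraws = 50000L,
                           ligationP = 0.8) {
    p <- probs$prob
    if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
    if (nDraws <= 0) stop("nDraws must be positive")
    draws <- as.integer(stats::rmultinom(1L, nDraws, p))
    rho <- ligationRetention(ligationP)
    stats::rbinom(length(draws), draws, rho)
}

#' Simulate the full two-dataset study with ground truth
#'
#' Builds the fragment and pair libraries, the two datasets' sampling
#' probabilities (dataset two sharing dataset one's random design), and
#' one count vector per dataset; assembles everything into a
#' \linkS4class{PairCounts} (dataset one = sample one), the TFBS/TSS
#' annotation tracks needed for the distance covariate, and the per-pair
#' truth labels.
#'
#' @param seed optional integer seed; the whole object is deterministic
#'   given the seed.
#' @param nDraws sampled pairs per dataset (default 50,000).
#' @param ligationP ligation success probability (default 0.8).
#' @return List of class \code{"chiaSim"}: \code{pairs}
#'   (\linkS4class{PairCounts} over all 4,912 library pairs),
#'   \code{truth} (joint category 0-5 per pair), \code{trueInSample}
#'   (n x 2 logical, designated-true per dataset), \code{tfbs},
#'   \code{tss}, \code{library}, \code{probs1}, \code{probs2}.
#' @export
makeJointDataset <- function(seed = NULL, nDraws = 50000L,
                             ligationP = 0.8) {
    if (!is.null(seed)) set.seed(seed)
    lib <- buildLibrary()
    p1 <- samplingProbs(lib, dataset = 1)
    p2 <- samplingProbs(lib, dataset = 2, design = p1)
    x1 <- simulateCounts(lib, p1, nDraws, ligationP)
    x2 <- simulateCounts(lib, p2, nDraws, ligationP)
    fr <- lib$fragments
    g <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
    a1 <- g[lib$pairs$frag1]
    a2 <- g[lib$pairs$frag2]
    structure(list(
        pairs = PairCounts(a1, a2, cbind(x1, x2)),
        truth = p2$truth,
        trueInSample = cbind(p1$trueInSample, p2$trueInSample),
        tfbs = lib$tfbs, tss = lib$tss,
        library = lib, probs1 = p1, probs2 = p2),
        class = "chiaSim")
}

#' Write the simulated study to disk
#'
#' Emits BEDPE-with-counts for the joint count table, BED tracks for the
#' TFBS and TSS sites, and a truth TSV (pair_id, category, true_in_one,
#' true_in_two).
#'
#' @param sim result of [makeJointDataset()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of file paths.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        pairs = file.path(dir, paste0(prefix, "_pairs.bedpe")),
        tfbs = file.path(dir, paste0(prefix, "_tfbs.bed")),
        tss = file.path(dir, paste0(prefix, "_tss.bed")),
        truth = file.path(dir, paste0(prefix, "_truth.tsv")))
    writePairCounts(sim$pairs, paths["pairs"])
    writeAnnotation(sim$tfbs, paths["tfbs"])
    writeAnnotation(sim$tss, paths["tss"])
    utils::write.table(
        data.frame(pair_id = pairIds(sim$pairs), category = sim$truth,
                   true_in_one = as.integer(sim$trueInSample[, 1]),
                   true_in_two = as.integer(sim$trueInSample[, 2])),
        paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
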