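#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
NULL

#' PairCounts: fragment pairs with per-sample ChIA-PET counts
#'
#' Container for a table of fragment pairs. Each pair joins two genomic
#' intervals (anchors) and carries one non-negative read-pair count per
#' sample. Coordinates follow the BED/BEDPE convention: 0-based start,
#' exclusive end.
#'
#' @slot anchor1,anchor2 \linkS4class{GRanges} of equal length, the two
#'   fragments of each pair. Self-loops (identical anchors) are invalid.
#' @slot counts integer matrix with one row per pair and two columns
#'   (\code{x1}, \code{x2}), the counts in sample one and sample two.
#' @slot pairId integer vector of unique pair identifiers.
#'
#' @seealso [readPairCounts()], [normalizeCounts()], [screenPairs()]
#' @export
setClass("PairCounts",
    representation(
        anchor1 = "GRanges",
        anchor2 = "GRanges",
        counts  = "matrix",
        pairId  = "integer"
    )
)

setValidity("PairCounts", function(object) {
    n <- length(object@anchor1)
    msg <- character()
    if (length(object@anchor2) != n)
        msg <- c(msg, "anchor1 and anchor2 must have equal length")
    if (nrow(object@counts) != n || ncol(object@counts) != 2L)
        msg <- c(msg, "counts must be an n x 2 matrix")
    if (length(object@pairId) != n)
        msg <- c(msg, "pairId must have one entry per pair")
    if (anyDuplicated(object@pairId))
        msg <- c(msg, "pairId must be unique")
    if (n > 0L) {
        if (any(object@counts < 0))
            msg <- c(msg, "counts must be non-negative")
        same <- as.character(seqnames(object@anchor1)) ==
                as.character(seqnames(object@anchor2)) &
                start(object@anchor1) == start(object@anchor2) &
                end(object@anchor1) == end(object@anchor2)
        if (any(same))
            msg <- c(msg, "self-loop pairs (identical anchors) are invalid")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PairCounts object
#'
#' @param anchor1,anchor2 \linkS4class{GRanges} of the two fragments per pair.
#' @param counts n x 2 matrix (or data.frame) of non-negative integer counts.
#' @param pairId optional integer identifiers; defaults to row order.
#' @return A \linkS4class{PairCounts} object.
#' @examples
#' a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
#' a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5100))
#' PairCounts(a1, a2, cbind(3L, 2L))
#' @export
PairCounts <- function(anchor1, anchor2, counts, pairId = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    colnames(counts) <- c("x1", "x2")
    if (is.null(pairId)) pairId <- seq_len(length(anchor1))
    new("PairCounts", anchor1 = anchor1, anchor2 = anchor2,
        counts = counts, pairId = as.integer(pairId))
}

#' @describeIn PairCounts-class number of pairs
#' @param x,object a \code{PairCounts} object
#' @export
setMethod("length", "PairCounts", function(x) length(x@anchor1))

#' Accessors for PairCounts
#'
#' \code{pairCounts} returns the n x 2 count matrix; \code{anchorOne} and
#' \code{anchorTwo} the anchor \code{GRanges}; \code{pairIds} the pair
#' identifiers.
#'
#' @param x a \linkS4class{PairCounts} object
#' @return See the description of each accessor.
#' @export
pairCounts <- function(x) x@counts

#' @rdname pairCounts
#' @export
anchorOne <- function(x) x@anchor1

#' @rdname pairCounts
#' @export
anchorTwo <- function(x) x@anchor2

#' @rdname pairCounts
#' @export
pairIds <- function(x) x@pairId

#' @export
setMethod("[", "PairCounts", function(x, i, j, ..., drop = FALSE) {
    if (is.logical(i)) i <- which(i)
    new("PairCounts", anchor1 = x@anchor1[i], anchor2 = x@anchor2[i],
        counts = x@counts[i, , drop = FALSE], pairId = x@pairId[i])
})

#' @export
setMethod("show", "PairCounts", function(object) {
    cat("PairCounts with", length(object), "fragment pairs\n")
    tot <- colSums(object@counts)
    cat("  total counts: sample one =", tot[1], ", sample two =", tot[2], "\n")
    if (length(object) > 0) {
        cat("  first pair: ",
            as.character(seqnames(object@anchor1))[1], ":",
            start(object@anchor1)[1] - 1L, "-", end(object@anchor1)[1],
            " / ",
            as.character(seqnames(object@anchor2))[1], ":",
            start(object@anchor2)[1] - 1L, "-", end(object@anchor2)[1],
            "  x = (", object@counts[1, 1], ", ", object@counts[1, 2], ")\n",
            sep = "")
    }
})

#' ChainResult: posterior summaries of an MCMC fit
#'
#' @slot model character, one of \code{"onestep"}, \code{"threecomp"},
#'   \code{"mcdist"}.
#' @slot pairId integer ids of the pairs that were fit.
#' @slot categoryPosterior matrix of post-burn-in frequencies of the latent
#'   category indicator; one row per pair, one column per category (6, 3 or
#'   2 columns). Rows sum to one.
#' @slot paramDraws matrix of thinned posterior draws of the model
#'   parameters (one named column per parameter).
#' @slot acceptanceRates named numeric, Metropolis-Hastings acceptance
#'   fraction per parameter.
#' @slot mapLabels integer maximum-a-posteriori category per pair (ties
#'   broken toward the smaller index).
#' @export
setClass("ChainResult",
    representation(
        model             = "character",
        pairId            = "integer",
        categoryPosterior = "matrix",
        paramDraws        = "matrix",
        acceptanceRates   = "numeric",
        mapLabels         = "integer"
    )
)

setValidity("ChainResult", function(object) {
    msg <- character()
    cp <- object@categoryPosterior
    if (nrow(cp) != length(object@pairId))
        msg <- c(msg, "one posterior row per pair required")
    if (nrow(cp) > 0 && any(abs(rowSums(cp) - 1) > 1e-9))
        msg <- c(msg, "posterior rows must sum to 1")
    ar <- object@acceptanceRates[!is.na(object@acceptanceRates)]
    if (length(ar) && (any(ar < 0) || any(ar > 1)))
        msg <- c(msg, "acceptance rates must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "ChainResult", function(object) {
    cat("ChainResult [", object@model, "] for ",
        nrow(object@categoryPosterior), " pairs, ",
        ncol(object@categoryPosterior), " categories\n", sep = "")
    cat("  stored parameter draws:", nrow(object@paramDraws), "x",
        ncol(object@paramDraws), "\n")
    cat("  MAP label counts:\n")
    print(table(factor(object@mapLabels,
        levels = seq_len(ncol(object@categoryPosterior)) - 1L)))
})

#' Accessors for ChainResult
#'
#' @param x a \linkS4class{ChainResult}
#' @return \code{categoryPosterior}: matrix of per-pair posterior category
#'   probabilities; \code{paramDraws}: thinned parameter draws;
#'   \code{acceptanceRates}: per-parameter MH acceptance fractions;
#'   \code{mapLabels}: MAP category per pair.
#' @export
categoryPosterior <- function(x) x@categoryPosterior

#' @rdname categoryPosterior
#' @export
paramDraws <- function(x) x@paramDraws

#' @rdname categoryPosterior
#' @export
acceptanceRates <- function(x) x@acceptanceRates

#' @rdname categoryPosterior
#' @export
mapLabels <- function(x) x@mapLabels
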