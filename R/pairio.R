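#' Read a BEDPE-with-counts table of fragment pairs
#'
#' Reads a tab-separated file with at least eight columns
#' (chrom1, start1, end1, chrom2, start2, end2, count1, count2) into a
#' \linkS4class{PairCounts} object. Coordinates are 0-based half-open
#' (BEDPE). Pair identifiers are generated from row order.
#'
#' @param path path to the file.
#' @param header logical; skip one header line (default \code{FALSE}).
#' @return A \linkS4class{PairCounts} object. Malformed rows (negative
#'   counts, start >= end, non-integer counts) raise an error naming the
#'   offending line. Duplicate interval pairs are allowed but trigger a
#'   warning; an empty file returns a zero-length object with a warning.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t0\t100\tchr1\t5000\t5100\t3\t2", f)
#' readPairCounts(f)
#' @export
readPairCounts <- function(path, header = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- tryCatch(
        utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, fill = FALSE),
        error = function(e) {
            if (grepl("no lines available", conditionMessage(e)))
                return(NULL)
            stop("failed to parse ", path, ": ", conditionMessage(e))
        })
    if (is.null(tab) || nrow(tab) == 0L) {
        warning("empty pair-count file: ", path)
        return(PairCounts(GRanges(), GRanges(),
                          matrix(integer(), 0, 2), integer()))
    }
    if (ncol(tab) < 8L)
        stop("expected >= 8 columns (BEDPE + two counts), got ", ncol(tab))
    lineno <- seq_len(nrow(tab)) + as.integer(header)
    cnt1 <- suppressWarnings(as.numeric(tab[[7]]))
    cnt2 <- suppressWarnings(as.numeric(tab[[8]]))
    bad <- which(is.na(cnt1) | is.na(cnt2) |
                 cnt1 != round(cnt1) | cnt2 != round(cnt2))
    if (length(bad))
        stop("non-integer count at line ", lineno[bad[1]])
    bad <- which(cnt1 < 0 | cnt2 < 0)
    if (length(bad))
        stop("negative count at line ", lineno[bad[1]])
    bad <- which(tab[[2]] >= tab[[3]] | tab[[5]] >= tab[[6]] |
                 tab[[2]] < 0 | tab[[5]] < 0)
    if (length(bad))
        stop("invalid interval (start >= end or start < 0) at line ",
             lineno[bad[1]])
    a1 <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
    a2 <- GRanges(tab[[4]], IRanges(tab[[5]] + 1L, tab[[6]]))
    key <- paste(tab[[1]], tab[[2]], tab[[3]], tab[[4]], tab[[5]], tab[[6]])
    if (anyDuplicated(key))
        warning(sum(duplicated(key)), " duplicate interval pair(s) in ", path)
    PairCounts(a1, a2, cbind(as.integer(cnt1), as.integer(cnt2)))
}

#' Write a PairCounts table as BEDPE-with-counts
#'
#' Inverse of [readPairCounts()]: emits 8 tab-separated columns, 0-based
#' half-open coordinates, no header.
#'
#' @param x a \linkS4class{PairCounts} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePairCounts <- function(x, path) {
    df <- data.frame(
        chrom1 = as.character(seqnames(x@anchor1)),
        start1 = start(x@anchor1) - 1L, end1 = end(x@anchor1),
        chrom2 = as.character(seqnames(x@anchor2)),
        start2 = start(x@anchor2) - 1L, end2 = end(x@anchor2),
        x1 = x@counts[, 1], x2 = x@counts[, 2])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an annotation track of TFBS or TSS sites
#'
#' Loads a BED3+ file of site locations into a sorted \linkS4class{GRanges}.
#' TSS may be zero-length points encoded as \code{start = end - 1}. The
#' track kind is stored in \code{metadata(x)$kind}.
#'
#' @param path BED file path.
#' @param kind \code{"TFBS"} or \code{"TSS"}.
#' @return \linkS4class{GRanges} sorted by (chrom, start). An empty file is
#'   an error: nearest-site distances would be undefined.
#' @export
readAnnotation <- function(path, kind = c("TFBS", "TSS")) {
    kind <- match.arg(kind)
    if (!file.exists(path)) stop("file not found: ", path)
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                       stop("failed to parse BED ", path, ": ",
                            conditionMessage(e)))
    if (length(gr) == 0L)
        stop("empty annotation track: ", path,
             " (distance would be undefined)")
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    metadata(gr)$kind <- kind
    gr
}

#' Write an annotation track as BED3
#'
#' @param gr a \linkS4class{GRanges} of sites.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotation <- function(gr, path) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Classification table of a fitted model
#'
#' Converts a \linkS4class{ChainResult} into the on-disk classification
#' layout: \code{pair_id}, posterior columns \code{p0..p5} (three-category
#' and two-category results are padded with zeros so the layout is
#' uniform), and \code{map_category}.
#'
#' @param result a \linkS4class{ChainResult}, or a matrix of posteriors.
#' @param pairId pair ids when \code{result} is a bare matrix.
#' @return A \code{data.frame}.
#' @export
classificationTable <- function(result, pairId = NULL) {
    if (is(result, "ChainResult")) {
        post <- result@categoryPosterior
        pairId <- result@pairId
        map <- result@mapLabels
    } else {
        post <- as.matrix(result)
        if (is.null(pairId)) pairId <- seq_len(nrow(post))
        map <- max.col(-(-post), ties.method = "first") - 1L
    }
    if (ncol(post) < 6L) {
        pad <- matrix(0, nrow(post), 6L - ncol(post))
        post <- cbind(post, pad)
    }
    colnames(post) <- paste0("p", 0:5)
    data.frame(pair_id = pairId, post, map_category = map,
               check.names = FALSE)
}

#' Write / read classification records
#'
#' The TSV has a header line \code{pair_id p0..p5 map_category}; posteriors
#' are written with six decimals and round-trip losslessly at that
#' precision. Each posterior row must sum to one within 1e-9 and
#' \code{map_category} must attain the row maximum.
#'
#' @param records a \code{data.frame} as produced by
#'   [classificationTable()].
#' @param path output path.
#' @return \code{writeClassifications} invisibly returns \code{path};
#'   \code{readClassifications} returns the \code{data.frame}.
#' @export
writeClassifications <- function(records, path) {
    pc <- paste0("p", 0:5)
    stopifnot(all(c("pair_id", pc, "map_category") %in% names(records)))
    post <- as.matrix(records[, pc])
    if (nrow(post) > 0) {
        if (any(post < 0) || any(abs(rowSums(post) - 1) > 1e-9))
            stop("posteriors must be non-negative and sum to 1")
        mx <- apply(post, 1L, max)
        hit <- post[cbind(seq_len(nrow(post)),
                          records$map_category + 1L)]
        if (any(abs(hit - mx) > 1e-12))
            stop("map_category must attain the maximum posterior entry")
    }
    out <- records
    out[pc] <- lapply(records[pc], function(p) sprintf("%.6f", p))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeClassifications
#' @export
readClassifications <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}
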