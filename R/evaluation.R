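#' Confusion matrix of classified categories
#'
#' Exact cross-tabulation; rows are the actual categories, columns the
#' classified ones.
#'
#' @param actual,predicted equal-length integer label vectors.
#' @param labels category levels (default 0:5).
#' @return Integer matrix with labeled dimnames.
#' @export
confusionMatrix <- function(actual, predicted, labels = 0:5) {
    if (length(actual) != length(predicted))
        stop("label vectors must have equal length")
    m <- table(factor(actual, levels = labels),
               factor(predicted, levels = labels),
               dnn = c("actual", "classified"))
    unclass(as.matrix(m))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \code{(p_o - p_e) / (1 - p_e)} with
#' \code{p_o} the observed agreement (trace over total) and \code{p_e}
#' the chance agreement implied by the marginals. Unweighted. For the
#' degenerate single-category table (\code{p_e = 1}), kappa is defined as
#' 1 when agreement is perfect and 0 otherwise.
#'
#' @param m a square confusion matrix (see [confusionMatrix()]).
#' @return Kappa in [-1, 1].
#' @examples
#' cohenKappa(matrix(c(3, 1, 1, 3), 2))  # 0.5
#' @export
cohenKappa <- function(m) {
    m <- as.matrix(m)
    total <- sum(m)
    if (total <= 0) stop("empty table")
    po <- sum(diag(m)) / total
    pe <- sum(rowSums(m) * colSums(m)) / total^2
    if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
    (po - pe) / (1 - pe)
}

#' Per-sample true-pair designation implied by a joint category
#'
#' A pair is true in sample one iff its category is in \{0, 1, 2, 3\} and
#' true in sample two iff its category is in \{0, 1, 2, 4\} (category 3 is
#' a loop present only in sample one, category 4 only in sample two,
#' category 5 in neither).
#'
#' @param category integer categories 0-5.
#' @param sample 1 or 2.
#' @return Logical vector.
#' @export
categoryToSampleTruth <- function(category, sample = 1) {
    if (sample == 1) category %in% c(0L, 1L, 2L, 3L)
    else category %in% c(0L, 1L, 2L, 4L)
}

#' Type-I error and power of a true/false-pair classifier
#'
#' Type-I error is the fraction of actual false pairs called true; power
#' the fraction of actual true pairs called true. When there is no actual
#' false (or true) pair the corresponding rate is \code{NaN}.
#'
#' @param actualTrue,predictedTrue equal-length logical vectors.
#' @return List with \code{type1} and \code{power}, both in [0, 1].
#' @export
binaryPerf <- function(actualTrue, predictedTrue) {
    if (length(actualTrue) != length(predictedTrue))
        stop("label vectors must have equal length")
    nF <- sum(!actualTrue)
    nT <- sum(actualTrue)
    list(type1 = if (nF > 0) sum(predictedTrue & !actualTrue) / nF else NaN,
         power = if (nT > 0) sum(predictedTrue & actualTrue) / nT else NaN)
}

# lag-autocorrelation effective sample size of one chain
.essOne <- function(v) {
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    ac <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[-1]
    # initial positive sequence: sum consecutive pairs while positive
    s <- 0
    k <- 1
    while (k < length(ac)) {
        pair <- ac[k] + ac[k + 1]
        if (pair < 0) break
        s <- s + pair
        k <- k + 2
    }
    max(1, n / (1 + 2 * s))
}

#' MCMC convergence diagnostics
#'
#' Potential scale reduction factor (the between/within-chain variance
#' ratio of Gelman and Rubin) and an autocorrelation-based effective
#' sample size, per parameter. With a single chain only the effective
#' size is available.
#'
#' @param chains list of numeric matrices (draws x parameters) with equal
#'   dimensions, one per chain.
#' @return \code{data.frame} with columns \code{parameter}, \code{psrf}
#'   (NA for a single chain) and \code{ess} (summed over chains).
#' @export
chainDiagnostics <- function(chains) {
    if (is.matrix(chains)) chains <- list(chains)
    m <- length(chains)
    dims <- vapply(chains, dim, integer(2))
    if (m > 1 && any(dims != dims[, 1])) stop("chains must match in shape")
    nIter <- dims[1, 1]
    pn <- colnames(chains[[1]])
    if (is.null(pn)) pn <- paste0("par", seq_len(dims[2, 1]))
    psrf <- rep(NA_real_, length(pn))
    ess <- numeric(length(pn))
    for (j in seq_along(pn)) {
        draws <- vapply(chains, function(ch) ch[, j], numeric(nIter))
        draws <- matrix(draws, nrow = nIter)
        ess[j] <- sum(apply(draws, 2, .essOne))
        if (m > 1) {
            means <- colMeans(draws)
            W <- mean(apply(draws, 2, stats::var))
            B <- nIter * stats::var(means)
            if (W <= 0) {
                psrf[j] <- 1
            } else {
                varPlus <- (nIter - 1) / nIter * W + B / nIter
                psrf[j] <- sqrt(varPlus / W)
            }
        }
    }
    data.frame(parameter = pn, psrf = psrf, ess = ess)
}

#' Evaluation report of a classification against truth
#'
#' Joins a classification table with a truth table by pair id and writes a
#' TSV report: the 6 x 6 confusion grid, Cohen's kappa, and per-sample
#' type-I error / power of the implied true/false calls.
#'
#' @param classification \code{data.frame} from [classificationTable()]
#'   (or a path read with [readClassifications()]).
#' @param truth \code{data.frame} with \code{pair_id} and \code{category}
#'   columns (the simulator's truth TSV layout).
#' @param path optional output path for the report TSV.
#' @return List with \code{confusion}, \code{kappa}, \code{perf} (2-row
#'   \code{data.frame}: sample, type1, power).
#' @export
evaluateClassification <- function(classification, truth, path = NULL) {
    idx <- match(classification$pair_id, truth$pair_id)
    if (anyNA(idx)) stop("pair ids in classification not found in truth")
    act <- truth$category[idx]
    pred <- classification$map_category
    cm <- confusionMatrix(act, pred)
    kap <- cohenKappa(cm)
    perf <- do.call(rbind, lapply(1:2, function(s) {
        bp <- binaryPerf(categoryToSampleTruth(act, s),
                         categoryToSampleTruth(pred, s))
        data.frame(sample = s, type1 = bp$type1, power = bp$power)
    }))
    if (!is.null(path)) {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines("# confusion (rows = actual 0..5, cols = classified)",
                   con)
        utils::write.table(cm, con, sep = "\t", quote = FALSE,
                           col.names = NA)
        writeLines(sprintf("kappa\t%.6f", kap), con)
        utils::write.table(perf, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    list(confusion = cm, kappa = kap, perf = perf)
}
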