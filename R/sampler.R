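#' Chain configuration
#'
#' Settings of the Metropolis-within-Gibbs samplers. The reduced-scale
#' defaults (tens of thousands of sweeps, single chain) are sized for a
#' few thousand pairs on one CPU; production analyses of real libraries
#' use millions of sweeps, which the same configuration accommodates.
#'
#' @param nIter total sweeps; every sweep updates all latent indicators,
#'   all mixture weights, all intensities, the gamma hyperparameters and
#'   the Dirichlet/beta scale.
#' @param burnIn discarded sweeps (must be < \code{nIter}).
#' @param seed optional RNG seed applied by the run functions.
#' @param T count threshold tied to the truncation of the likelihoods.
#' @param proposalSd log-scale random-walk standard deviation for
#'   intensities and gamma shape/rate parameters.
#' @param etaHalfwidth half-width of the reflected uniform proposal for
#'   the prior scale eta; \code{NULL} (default) sets it to
#'   \code{3 * eta0 / sqrt(n)} around the data-driven initial value
#'   \code{eta0} (the posterior scale of a concentration parameter
#'   shrinks like \code{1/sqrt(n)}), fixed before sampling.
#' @param thin keep every \code{thin}-th parameter draw (category
#'   indicators are tallied every sweep).
#' @param C upper bound of the uniform hyperpriors on gamma shapes/rates.
#' @param D upper bound of the uniform prior on the three-component
#'   model's Dirichlet scale.
#' @param E upper bound of the uniform prior on the One-Step and
#'   two-component models' prior scale (large, to let the scale bridge the
#'   different units of marginal counts and distances).
#' @param chains number of chains (used by [cmdFit()] for the
#'   between-chain diagnostic; the run functions fit one chain each).
#' @return A list of class \code{"chainConfig"}.
#' @export
chainConfig <- function(nIter = 40000L, burnIn = 15000L, seed = NULL,
                        T = 2L, proposalSd = 0.1, etaHalfwidth = NULL,
                        thin = 10L, C = 1000, D = 1000, E = 1e6,
                        chains = 1L) {
    stopifnot(burnIn < nIter, proposalSd > 0, C > 0, D > 0, E > 0, T >= 1)
    structure(list(nIter = as.integer(nIter), burnIn = as.integer(burnIn),
                   seed = seed, T = as.integer(T), proposalSd = proposalSd,
                   etaHalfwidth = etaHalfwidth, thin = as.integer(thin),
                   C = C, D = D, E = E, chains = as.integer(chains)),
              class = "chainConfig")
}

.sub0 <- function(v) ifelse(v == 0, 0.5, v)

# n x 5 covariate base of the One-Step Dirichlet prior (columns 0..4;
# the false-pair parameter alpha5 is the constant 1, not eta-scaled)
.alphaBaseOnestep <- function(features) {
    M <- .sub0(features$mc1 + features$mc2)
    sDn <- features$dmcDn / M
    sUp <- features$dmcUp / M
    sEq <- pmax(1 - sDn - sUp, 0) + 1e-8
    rmin <- pmin(features$r1, features$r2)
    cbind(a0 = .sub0(rmin * sDn), a1 = .sub0(rmin * sEq),
          a2 = .sub0(rmin * sUp), a3 = .sub0(features$r1 * sDn),
          a4 = .sub0(features$r2 * sUp))
}

#' Per-pair Dirichlet parameters of the One-Step weight prior
#'
#' Maps each pair's covariates to the six Dirichlet parameters of its
#' mixture-weight prior. With \code{M = mc1 + mc2}, directional shares
#' \code{sDn = dmcDn/M}, \code{sUp = dmcUp/M},
#' \code{sEq = max(1 - sDn - sUp, 0)} and \code{rmin = min(r1, r2)}:
#' \code{alpha0 = eta rmin sDn}, \code{alpha1 = eta rmin sEq},
#' \code{alpha2 = eta rmin sUp}, \code{alpha3 = eta r1 sDn},
#' \code{alpha4 = eta r2 sUp}, \code{alpha5 = 1}; exact zeros are replaced
#' by 0.5 before scaling. The construction encodes two monotonicities: a
#' larger marginal-count/distance ratio in a sample makes that sample's
#' true-pair categories more likely a priori, and a larger between-sample
#' marginal-count difference makes the differential categories more
#' likely, in the direction of the difference.
#'
#' @param features a feature table from [pairFeatures()] (or one row's
#'   worth of covariates as a list).
#' @param eta positive scale hyperparameter.
#' @return n x 6 matrix of positive Dirichlet parameters.
#' @export
alphaOnestep <- function(features, eta = 1) {
    if (eta <= 0) stop("eta must be positive")
    base <- .alphaBaseOnestep(features)
    cbind(eta * base, a5 = rep(1, nrow(base)))
}

.alphaBaseThreecomp <- function(features) {
    cbind(a0 = .sub0(features$dmcDn),
          a1 = .sub0(pmin(features$mc1, features$mc2)),
          a2 = .sub0(features$dmcUp))
}

#' Per-pair Dirichlet parameters of the three-component weight prior
#'
#' \code{alpha0 = eta dmcDn}, \code{alpha1 = eta min(mc1, mc2)},
#' \code{alpha2 = eta dmcUp} (zeros replaced by 0.5 before scaling): the
#' larger the marginal-count difference, the more likely a differential
#' category, in its direction; scaling eta changes the concentration but
#' not the prior mean.
#'
#' @inheritParams alphaOnestep
#' @return n x 3 matrix of positive Dirichlet parameters.
#' @export
alphaThreecomp <- function(features, eta = 1) {
    if (eta <= 0) stop("eta must be positive")
    eta * .alphaBaseThreecomp(features)
}

#' Beta prior of the per-pair true-pair weight (two-component model)
#'
#' \code{alpha = eta * r_j} (zero replaced by 0.5), \code{beta = 1}: the
#' prior mean \code{alpha/(alpha + 1)} of the true-pair weight is
#' non-decreasing in the marginal-count/distance ratio.
#'
#' @param features feature table.
#' @param sample 1 or 2 (selects \code{r1} or \code{r2}).
#' @param eta positive scale.
#' @return n x 2 matrix with columns \code{alpha}, \code{beta}.
#' @export
betaWeightMcdist <- function(features, sample = 1, eta = 1) {
    r <- if (sample == 1) features$r1 else features$r2
    cbind(alpha = eta * .sub0(r), beta = rep(1, length(r)))
}

#' Full-conditional draw of a latent category indicator
#'
#' \code{P(z = k)} is proportional to \code{pi_k} times the component
#' likelihood of category \code{k}.
#'
#' @param x1,x2 scalar counts.
#' @param pi mixture-weight vector on the simplex.
#' @param params model parameters ([onestepParams()] or
#'   [threecompParams()]).
#' @param model \code{"onestep"} or \code{"threecomp"}.
#' @param T truncation threshold.
#' @return List with \code{prob} (normalized full-conditional
#'   probabilities) and \code{category} (one draw).
#' @export
updateZ <- function(x1, x2, pi, params,
                    model = c("onestep", "threecomp"), T = 2L) {
    model <- match.arg(model)
    K <- length(pi)
    ll <- vapply(seq_len(K) - 1L, function(k)
        componentLoglik(model, k, x1, x2, params, T), numeric(1))
    lw <- log(pi) + ll
    if (all(!is.finite(lw)))
        stop("all components have zero full-conditional probability")
    w <- exp(lw - max(lw[is.finite(lw)]))
    w[!is.finite(w)] <- 0
    prob <- w / sum(w)
    list(prob = prob,
         category = sample.int(K, 1L, prob = prob) - 1L)
}

#' Conjugate Dirichlet update of a pair's mixture weights
#'
#' Draws from \code{Dirichlet(alpha + one-hot(z))}, the exact full
#' conditional given one categorical observation.
#'
#' @param z observed category (0-based).
#' @param alpha positive Dirichlet parameter vector.
#' @return One draw on the simplex.
#' @export
updatePi <- function(z, alpha) {
    if (any(alpha <= 0)) stop("alpha must be positive")
    a <- alpha
    a[z + 1L] <- a[z + 1L] + 1
    g <- stats::rgamma(length(a), shape = a, rate = 1)
    g / sum(g)
}

#' One Metropolis-Hastings update
#'
#' Log-normal random walk (\code{proposal = current * exp(N(0, sd^2))},
#' with the \code{proposed/current} Hastings factor from the change of
#' variables) for positive parameters, or a uniform window proposal with
#' reflection at 0 and \code{upper} for bounded scales. Proposals on which
#' \code{targetLogDensity} is \code{-Inf} (constraint or bound violations)
#' are rejected.
#'
#' @param current current value.
#' @param targetLogDensity function of one argument returning the
#'   unnormalized log target.
#' @param type \code{"lognormal"} or \code{"uniform"}.
#' @param proposalSd log-scale sd of the random walk.
#' @param halfwidth half-width of the uniform window.
#' @param upper reflection bound for the uniform proposal.
#' @return List with \code{value} and \code{accepted}.
#' @export
mhUpdate <- function(current, targetLogDensity,
                     type = c("lognormal", "uniform"),
                     proposalSd = 0.1, halfwidth = 1, upper = Inf) {
    type <- match.arg(type)
    if (type == "lognormal") {
        prop <- current * exp(stats::rnorm(1, 0, proposalSd))
        lacc <- targetLogDensity(prop) - targetLogDensity(current) +
            log(prop / current)
    } else {
        prop <- current + stats::runif(1, -halfwidth, halfwidth)
        for (i in 1:64) {
            if (prop < 0) { prop <- -prop; next }
            if (prop > upper) { prop <- 2 * upper - prop; next }
            break
        }
        lacc <- targetLogDensity(prop) - targetLogDensity(current)
    }
    if (is.finite(lacc) && log(stats::runif(1)) < lacc ||
        identical(lacc, Inf))
        list(value = prop, accepted = TRUE)
    else
        list(value = current, accepted = FALSE)
}

# method-of-moments initialization on count strata: false intensity from
# the lower half of the counts, true from the upper half, jittered so the
# order restrictions hold strictly
.initIntensities <- function(x1, x2) {
    strat <- function(v) {
        med <- stats::median(v)
        f <- mean(v[v <= med])
        t <- mean(v[v > med])
        if (!is.finite(t)) t <- f * 3
        f <- max(f, 0.2)
        t <- max(t, 1.5 * f)
        c(f = f, t = t)
    }
    s1 <- strat(x1); s2 <- strat(x2)
    lF1 <- s1["f"]; lF2 <- s2["f"]
    t1 <- s1["t"]; t2 <- s2["t"]
    l02 <- max(0.9 * t2, 1.1 * lF2)
    l01 <- max(1.1 * t1, 1.05 * l02)
    l21 <- max(0.9 * t1, 1.1 * lF1)
    l22 <- max(1.1 * t2, 1.05 * l21)
    lam <- c(lam0_1 = l01, lam0_2 = l02, lam1 = (t1 + t2) / 2,
             lam2_1 = l21, lam2_2 = l22, lam3 = t1, lam4 = t2,
             lamF1 = lF1, lamF2 = lF2)
    unname(lam)
}

.gammaMomInit <- function(vals, C) {
    m <- mean(vals)
    c(a = min(2, C / 2), b = min(2 / m, C / 2))
}

.etaInit <- function(base, bound) {
    e <- 1 / stats::median(pmax(rowSums(as.matrix(base)), 1e-12))
    min(max(e, 1e-8), bound / 2)
}

.alignFeatures <- function(x, features) {
    idx <- match(pairIds(x), features$pairId)
    if (anyNA(idx))
        stop("features missing for some pair ids")
    features[idx, , drop = FALSE]
}

.onestepParNames <- c("lam0_1", "lam0_2", "lam1", "lam2_1", "lam2_2",
                      "lam3", "lam4", "lamF1", "lamF2",
                      "a_T", "b_T", "a_F", "b_F", "eta")

#' Fit the One-Step six-component model
#'
#' Joint Bayesian classification of all pairs into the six categories by a
#' six-component mixture of jointly truncated bivariate Poisson laws, with
#' per-pair Dirichlet weight priors built from marginal counts and
#' TFBS/TSS distances. A full MCMC sweep updates every latent indicator,
#' every pair's weights (conjugate Dirichlet), the nine intensities and
#' four gamma hyperparameters (log-normal random-walk MH) and the prior
#' scale eta (reflected uniform MH). Category posteriors are the
#' post-burn-in indicator frequencies.
#'
#' @param x a \linkS4class{PairCounts} screened with
#'   \code{screenPairs(mode = "joint_max")} at the configuration's
#'   \code{T}.
#' @param features feature table from [pairFeatures()] covering
#'   \code{pairIds(x)}.
#' @param config a [chainConfig()].
#' @param weights \code{"covariate"} for the per-pair informative priors,
#'   \code{"uninformative"} for a single shared weight vector with a flat
#'   Dirichlet prior (the ablation that demonstrates the value of the
#'   covariates).
#' @return A \linkS4class{ChainResult} with six posterior columns.
#' @export
runOnestep <- function(x, features, config = chainConfig(),
                       weights = c("covariate", "uninformative")) {
    weights <- match.arg(weights)
    cnt <- pairCounts(x)
    if (any(pmax(cnt[, 1], cnt[, 2]) < config$T))
        stop("input must be screened joint_max at T = ", config$T)
    if (!is.null(config$seed)) set.seed(config$seed)
    feats <- .alignFeatures(x, features)
    base <- .alphaBaseOnestep(feats)
    lam <- .initIntensities(cnt[, 1], cnt[, 2])
    hypT <- .gammaMomInit(lam[1:7], config$C)
    hypF <- .gammaMomInit(lam[8:9], config$C)
    eta0 <- .etaInit(base, config$E)
    etaHw <- if (is.null(config$etaHalfwidth))
        max(eta0 * 3 / sqrt(length(x)), 1e-8) else config$etaHalfwidth
    fit <- cpp_run_onestep(cnt, config$T, base, 1.0,
                           weights == "covariate", lam,
                           hypT["a"], hypT["b"], hypF["a"], hypF["b"],
                           eta0, config$nIter, config$burnIn, config$thin,
                           config$proposalSd, etaHw, config$C, config$E)
    colnames(fit$draws) <- .onestepParNames
    names(fit$acceptance) <- .onestepParNames
    post <- fit$posterior
    colnames(post) <- paste0("p", 0:5)
    new("ChainResult", model = "onestep", pairId = pairIds(x),
        categoryPosterior = post, paramDraws = fit$draws,
        acceptanceRates = fit$acceptance,
        mapLabels = classifyMap(post))
}

.threecompParNames <- c("lam0_1", "lam0_2", "lam1", "lam2_1", "lam2_2",
                        "a", "b", "eta")

#' Fit the three-component differential mixture (Two-Step, step two)
#'
#' Classifies pairs that are true in both samples into decreased / same /
#' increased intensity (categories 0/1/2) with a mixture of products of
#' per-sample T-truncated Poisson laws and per-pair Dirichlet priors from
#' the marginal-count differences.
#'
#' @param x a \linkS4class{PairCounts} screened with
#'   \code{screenPairs(mode = "both_min")} at \code{T} (at least 3 pairs).
#' @inheritParams runOnestep
#' @return A \linkS4class{ChainResult} with three posterior columns.
#' @export
runThreecomp <- function(x, features, config = chainConfig(),
                         weights = c("covariate", "uninformative")) {
    weights <- match.arg(weights)
    cnt <- pairCounts(x)
    if (length(x) < 3L) stop("need at least 3 pairs")
    if (any(pmin(cnt[, 1], cnt[, 2]) < config$T))
        stop("input must be screened both_min at T = ", config$T)
    if (!is.null(config$seed)) set.seed(config$seed)
    feats <- .alignFeatures(x, features)
    base <- .alphaBaseThreecomp(feats)
    lam9 <- .initIntensities(cnt[, 1], cnt[, 2])
    lam <- lam9[1:5]
    hyp <- .gammaMomInit(lam, config$C)
    eta0 <- .etaInit(base, config$D)
    etaHw <- if (is.null(config$etaHalfwidth))
        max(eta0 * 3 / sqrt(length(x)), 1e-8) else config$etaHalfwidth
    fit <- cpp_run_threecomp(cnt, config$T, base,
                             weights == "covariate", lam,
                             hyp["a"], hyp["b"], eta0,
                             config$nIter, config$burnIn, config$thin,
                             config$proposalSd, etaHw, config$C, config$D)
    colnames(fit$draws) <- .threecompParNames
    names(fit$acceptance) <- .threecompParNames
    post <- fit$posterior
    colnames(post) <- paste0("p", 0:2)
    new("ChainResult", model = "threecomp", pairId = pairIds(x),
        categoryPosterior = post, paramDraws = fit$draws,
        acceptanceRates = fit$acceptance,
        mapLabels = classifyMap(post))
}

.mcdistParNames <- c("lamT", "lamF", "a", "b", "eta")

#' Fit the per-sample two-component true/false-pair model
#'
#' Two-component T-truncated Poisson mixture on one sample's counts with a
#' per-pair beta-distributed true-pair weight whose prior mean grows with
#' the marginal-count/distance ratio. A pair is called true when its
#' posterior true-pair probability exceeds 0.5.
#'
#' @param x a \linkS4class{PairCounts}; only pairs with the selected
#'   sample's count at least \code{T} may be supplied.
#' @param features feature table.
#' @param sample 1 or 2, the sample whose counts are modeled.
#' @param config a [chainConfig()].
#' @return A \linkS4class{ChainResult} with two posterior columns
#'   (\code{false}, \code{true}); \code{mapLabels} is 1 for called-true.
#' @export
runMcdist <- function(x, features, sample = 1, config = chainConfig()) {
    cnt <- pairCounts(x)[, sample]
    if (any(cnt < config$T))
        stop("all counts in sample ", sample, " must be >= T")
    if (!is.null(config$seed)) set.seed(config$seed)
    feats <- .alignFeatures(x, features)
    rbase <- .sub0(if (sample == 1) feats$r1 else feats$r2)
    med <- stats::median(cnt)
    lamF <- max(mean(cnt[cnt <= med]), 0.2)
    lamT <- mean(cnt[cnt > med])
    if (!is.finite(lamT)) lamT <- 3 * lamF  # degenerate: no upper stratum
    lamT <- max(lamT, 1.5 * lamF)
    hyp <- .gammaMomInit(c(lamT, lamF), config$C)
    eta0 <- min(max(1 / stats::median(rbase), 1e-8), config$E / 2)
    etaHw <- if (is.null(config$etaHalfwidth))
        max(eta0 * 3 / sqrt(length(cnt)), 1e-8) else config$etaHalfwidth
    fit <- cpp_run_mcdist(as.integer(cnt), config$T, rbase,
                          lamT, lamF, hyp["a"], hyp["b"], eta0,
                          config$nIter, config$burnIn, config$thin,
                          config$proposalSd, etaHw, config$C, config$E)
    colnames(fit$draws) <- .mcdistParNames
    names(fit$acceptance) <- .mcdistParNames
    post <- cbind(false = 1 - fit$posteriorTrue, true = fit$posteriorTrue)
    new("ChainResult", model = "mcdist", pairId = pairIds(x),
        categoryPosterior = post, paramDraws = fit$draws,
        acceptanceRates = fit$acceptance,
        mapLabels = as.integer(fit$posteriorTrue > 0.5))
}

#' Run the Two-Step pipeline
#'
#' Step one fits the two-component true/false model separately on each
#' sample's counts (pairs whose count in a sample is below \code{T} are
#' false in that sample by the screening convention). Pairs false in both
#' samples become category 5; true only in sample one, category 3; true
#' only in sample two, category 4. Pairs true in both samples go to step
#' two, the three-component differential mixture, which assigns categories
#' 0/1/2. Step-1-decided pairs get posterior 1 in their category.
#'
#' @param x a \linkS4class{PairCounts} screened joint_max at \code{T}
#'   (every pair reaches \code{T} in at least one sample).
#' @param features feature table covering \code{pairIds(x)}.
#' @param config a [chainConfig()]; the same iteration settings are used
#'   for the step-one fits and the step-two fit.
#' @param weights weight-prior mode passed to [runThreecomp()].
#' @return List with \code{classification} (a [classificationTable()]
#'   \code{data.frame} over all pairs), \code{step1} (the two
#'   \linkS4class{ChainResult}s), \code{calledTrue} (n x 2 logical), and
#'   \code{threecomp} (the step-two \linkS4class{ChainResult}, or NULL if
#'   fewer than 3 pairs were true in both samples).
#' @export
runTwostep <- function(x, features, config = chainConfig(),
                       weights = c("covariate", "uninformative")) {
    weights <- match.arg(weights)
    cnt <- pairCounts(x)
    n <- length(x)
    if (!is.null(config$seed)) set.seed(config$seed)
    calledTrue <- matrix(FALSE, n, 2)
    step1 <- vector("list", 2)
    for (s in 1:2) {
        idx <- which(cnt[, s] >= config$T)
        if (length(idx)) {
            sub <- x[idx]
            cfg <- config
            cfg$seed <- NULL  # continue the active RNG stream
            step1[[s]] <- runMcdist(sub, features, sample = s, config = cfg)
            calledTrue[idx, s] <- mapLabels(step1[[s]]) == 1L
        }
    }
    post <- matrix(0, n, 6, dimnames = list(NULL, paste0("p", 0:5)))
    both <- calledTrue[, 1] & calledTrue[, 2]
    post[!calledTrue[, 1] & !calledTrue[, 2], 6] <- 1  # category 5
    post[calledTrue[, 1] & !calledTrue[, 2], 4] <- 1   # category 3
    post[!calledTrue[, 1] & calledTrue[, 2], 5] <- 1   # category 4
    tc <- NULL
    if (sum(both) >= 3L) {
        cfg <- config
        cfg$seed <- NULL
        tc <- runThreecomp(x[both], features, config = cfg,
                           weights = weights)
        post[both, 1:3] <- categoryPosterior(tc)
    } else if (any(both)) {
        post[both, 2] <- 1  # too few for a mixture: same intensity
    }
    list(classification = classificationTable(post, pairId = pairIds(x)),
         step1 = step1, calledTrue = calledTrue, threecomp = tc)
}

#' MAP category labels
#'
#' Argmax of the posterior category probabilities, ties broken toward the
#' smaller category index.
#'
#' @param result a \linkS4class{ChainResult} or a posterior matrix.
#' @return Integer labels (0-based).
#' @export
classifyMap <- function(result) {
    post <- if (is(result, "ChainResult")) categoryPosterior(result)
            else as.matrix(result)
    max.col(post, ties.method = "first") - 1L
}
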