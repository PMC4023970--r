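#' Left-truncated Poisson log pmf
#'
#' Log probability of a Poisson count conditional on being at least
#' \code{T}: \code{log[ Pois(x; lambda) / P(Pois(lambda) >= T) ]} for
#' \code{x >= T} and \code{-Inf} below the truncation point. The tail
#' probability is computed from the Poisson CDF (regularized incomplete
#' gamma under the hood), never by summation.
#'
#' @param x integer count(s).
#' @param lambda positive rate(s).
#' @param T integer truncation threshold, >= 1.
#' @return Log probabilities (vectorized).
#' @examples
#' tpoisLogPmf(2, 1, 2)  # log((exp(-1)/2) / (1 - 2*exp(-1)))
#' @export
tpoisLogPmf <- function(x, lambda, T = 2L) {
    if (any(lambda <= 0)) stop("lambda must be positive")
    if (T < 1) stop("T must be >= 1")
    out <- stats::dpois(x, lambda, log = TRUE) -
        stats::ppois(T - 1, lambda, lower.tail = FALSE, log.p = TRUE)
    out[x < T] <- -Inf
    out
}

#' Jointly truncated bivariate Poisson log pmf
#'
#' Log probability of two independent Poisson counts conditional on at
#' least one of them reaching \code{T}:
#' \code{log[ Pois(x1; l1) Pois(x2; l2) / (1 - F(T-1; l1) F(T-1; l2)) ]}
#' for \code{max(x1, x2) >= T}, \code{-Inf} otherwise. This is the
#' component law of the One-Step model, whose support matches the
#' \code{"joint_max"} screening rule.
#'
#' @param x1,x2 integer counts.
#' @param lambda1,lambda2 positive rates.
#' @param T integer threshold >= 1.
#' @return Log probabilities (vectorized).
#' @export
jointTruncLogPmf <- function(x1, x2, lambda1, lambda2, T = 2L) {
    if (any(lambda1 <= 0) || any(lambda2 <= 0))
        stop("rates must be positive")
    if (T < 1) stop("T must be >= 1")
    lf1 <- stats::ppois(T - 1, lambda1, log.p = TRUE)
    lf2 <- stats::ppois(T - 1, lambda2, log.p = TRUE)
    out <- stats::dpois(x1, lambda1, log = TRUE) +
        stats::dpois(x2, lambda2, log = TRUE) -
        log1p(-exp(lf1 + lf2))
    out[pmax(x1, x2) < T] <- -Inf
    out
}

#' Model parameter constructors
#'
#' Named parameter lists for the three mixture models.
#' \code{onestepParams}: nine interaction intensities (per-category true
#' intensities \code{lam0_1, lam0_2, lam1, lam2_1, lam2_2, lam3, lam4} and
#' per-sample false-pair intensities \code{lamF1, lamF2}), gamma
#' shape/rate hyperparameters for the true (\code{a_T, b_T}) and false
#' (\code{a_F, b_F}) intensities, and the Dirichlet scale \code{eta}.
#' \code{threecompParams}: the five true intensities of the differential
#' (second-step) mixture with one gamma prior (\code{a, b}) and scale
#' \code{eta}. \code{mcdistParams}: the true/false intensities of the
#' per-sample two-component model with gamma prior and beta-prior scale.
#'
#' @param lam0_1,lam0_2,lam1,lam2_1,lam2_2,lam3,lam4,lamF1,lamF2
#'   interaction intensities (positive).
#' @param a_T,b_T,a_F,b_F,a,b gamma shape/rate hyperparameters.
#' @param eta Dirichlet (or beta) prior scale.
#' @param lamT,lamF two-component true/false intensities.
#' @return A named list with class attribute used by [constraintsOk()] and
#'   [componentLoglik()].
#' @export
onestepParams <- function(lam0_1, lam0_2, lam1, lam2_1, lam2_2,
                          lam3, lam4, lamF1, lamF2,
                          a_T = 1, b_T = 1, a_F = 1, b_F = 1, eta = 1) {
    structure(list(lam0_1 = lam0_1, lam0_2 = lam0_2, lam1 = lam1,
                   lam2_1 = lam2_1, lam2_2 = lam2_2, lam3 = lam3,
                   lam4 = lam4, lamF1 = lamF1, lamF2 = lamF2,
                   a_T = a_T, b_T = b_T, a_F = a_F, b_F = b_F, eta = eta),
              model = "onestep")
}

#' @rdname onestepParams
#' @export
threecompParams <- function(lam0_1, lam0_2, lam1, lam2_1, lam2_2,
                            a = 1, b = 1, eta = 1) {
    structure(list(lam0_1 = lam0_1, lam0_2 = lam0_2, lam1 = lam1,
                   lam2_1 = lam2_1, lam2_2 = lam2_2,
                   a = a, b = b, eta = eta),
              model = "threecomp")
}

#' @rdname onestepParams
#' @export
mcdistParams <- function(lamT, lamF, a = 1, b = 1, eta = 1) {
    structure(list(lamT = lamT, lamF = lamF, a = a, b = b, eta = eta),
              model = "mcdist")
}

# per-category (sample one, sample two) rate pairs
.onestepRates <- function(p, k) {
    switch(as.character(k),
        "0" = c(p$lam0_1, p$lam0_2),
        "1" = c(p$lam1,   p$lam1),
        "2" = c(p$lam2_1, p$lam2_2),
        "3" = c(p$lam3,   p$lamF2),
        "4" = c(p$lamF1,  p$lam4),
        "5" = c(p$lamF1,  p$lamF2),
        stop("invalid category ", k))
}

.threecompRates <- function(p, k) {
    switch(as.character(k),
        "0" = c(p$lam0_1, p$lam0_2),
        "1" = c(p$lam1,   p$lam1),
        "2" = c(p$lam2_1, p$lam2_2),
        stop("invalid category ", k))
}

#' Component log-likelihood of a mixture category
#'
#' For the One-Step model, category \code{k} in 0..5 uses the jointly
#' truncated bivariate law with per-category rate pairs
#' (\code{(lam0_1, lam0_2)}, \code{(lam1, lam1)}, \code{(lam2_1, lam2_2)},
#' \code{(lam3, lamF2)}, \code{(lamF1, lam4)}, \code{(lamF1, lamF2)}).
#' For the three-component model, category \code{k} in 0..2 uses the
#' product of two per-sample \code{T}-truncated Poisson laws.
#'
#' @param model \code{"onestep"} or \code{"threecomp"}.
#' @param k category index.
#' @param x1,x2 counts.
#' @param params parameter list from [onestepParams()] /
#'   [threecompParams()].
#' @param T truncation threshold.
#' @return Log likelihood (vectorized over counts).
#' @export
componentLoglik <- function(model = c("onestep", "threecomp"), k,
                            x1, x2, params, T = 2L) {
    model <- match.arg(model)
    if (model == "onestep") {
        r <- .onestepRates(params, k)
        jointTruncLogPmf(x1, x2, r[1], r[2], T)
    } else {
        r <- .threecompRates(params, k)
        tpoisLogPmf(x1, r[1], T) + tpoisLogPmf(x2, r[2], T)
    }
}

#' Identifiability constraints of the mixture parameters
#'
#' The components are tied to the categories by order restrictions on the
#' intensities: every true intensity strictly exceeds the corresponding
#' sample's false intensity (interaction raises the ligation frequency),
#' \code{lam0_1 > lam0_2} (category 0 is a decrease) and
#' \code{lam2_1 < lam2_2} (category 2 is an increase). For the
#' two-component model, \code{lamT > lamF > 0}. The restrictions are
#' strict, with no minimal gap; MCMC proposals violating them receive
#' prior density zero.
#'
#' @param params a parameter list from [onestepParams()],
#'   [threecompParams()] or [mcdistParams()].
#' @param model model name; defaults to the constructor's tag.
#' @return \code{TRUE} iff all invariants hold.
#' @export
constraintsOk <- function(params,
                          model = attr(params, "model")) {
    p <- params
    if (is.null(model)) stop("model not specified")
    pos <- function(v) all(is.finite(unlist(v))) && all(unlist(v) > 0)
    switch(model,
        onestep = {
            lams <- p[c("lam0_1", "lam0_2", "lam1", "lam2_1", "lam2_2",
                        "lam3", "lam4", "lamF1", "lamF2")]
            pos(lams) &&
                p$lam0_1 > p$lamF1 && p$lam1 > p$lamF1 &&
                p$lam2_1 > p$lamF1 && p$lam3 > p$lamF1 &&
                p$lam0_2 > p$lamF2 && p$lam1 > p$lamF2 &&
                p$lam2_2 > p$lamF2 && p$lam4 > p$lamF2 &&
                p$lam0_1 > p$lam0_2 && p$lam2_1 < p$lam2_2
        },
        threecomp = {
            lams <- p[c("lam0_1", "lam0_2", "lam1", "lam2_1", "lam2_2")]
            pos(lams) && p$lam0_1 > p$lam0_2 && p$lam2_1 < p$lam2_2
        },
        mcdist = pos(p[c("lamT", "lamF")]) && p$lamT > p$lamF,
        stop("unknown model: ", model))
}
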