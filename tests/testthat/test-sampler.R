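# unit tests for the prior construction and the elementary MCMC moves

test_that("One-Step Dirichlet parameters obey the covariate contract", {
    feat <- function(mc1, mc2, dist)
        priorCovariates(mc1, mc2, dist)
    # symmetry: equal ratios and balanced differences
    a <- alphaOnestep(feat(10, 10, 20), eta = 3)
    expect_equal(unname(a[1, "a3"]), unname(a[1, "a4"]))
    expect_equal(unname(a[1, "a0"]), unname(a[1, "a2"]))
    expect_equal(unname(a[1, "a5"]), 1)
    expect_true(all(a > 0))

    # increasing r1 (smaller dist in sample one only is impossible; use
    # larger mc1 with dist fixed -- r1 grows, then check alpha3's share)
    shares <- sapply(seq(10, 200, by = 10), function(m1) {
        aa <- alphaOnestep(feat(m1, 10, 50), eta = 2)
        aa[1, "a3"] / sum(aa[1, ])
    })
    expect_true(all(diff(shares) > -1e-12))

    # increasing mc1 - mc2 with distance fixed: the "sample-one-higher"
    # categories gain prior mass, the "sample-two-higher" ones lose it
    dn <- sapply(seq(0, 80, by = 8), function(d) {
        aa <- alphaOnestep(feat(100 + d, 100, 50), eta = 2)
        c(up = unname((aa[1, "a0"] + aa[1, "a3"]) / sum(aa[1, ])),
          down = unname((aa[1, "a2"] + aa[1, "a4"]) / sum(aa[1, ])))
    })
    expect_true(all(diff(dn["up", ]) > -1e-12))
    expect_true(all(diff(dn["down", ]) < 1e-12))
    expect_error(alphaOnestep(feat(1, 1, 1), eta = 0), "positive")
})

test_that("three-component Dirichlet parameters follow the defaults", {
    f <- priorCovariates(10, 4, 100)
    a <- alphaThreecomp(f, eta = 2)
    expect_equal(unname(a[1, "a0"] / a[1, "a2"]), 6 / 0.5)
    fEq <- priorCovariates(7, 7, 100)
    aEq <- alphaThreecomp(fEq, eta = 2)
    expect_equal(unname(aEq[1, "a0"]), 2 * 0.5)   # eta * substituted 0.5
    expect_equal(unname(aEq[1, "a0"]), unname(aEq[1, "a2"]))
    # doubling eta scales the vector, leaving the Dirichlet mean fixed
    a2 <- alphaThreecomp(f, eta = 4)
    expect_equal(unname(a2[1, ]), unname(2 * a[1, ]))
    expect_equal(unname(a2[1, ] / sum(a2[1, ])), unname(a[1, ] / sum(a[1, ])))
})

test_that("two-component beta weight prior is monotone in r", {
    f0 <- priorCovariates(0, 0, 10)        # r substituted to 0.5
    b0 <- betaWeightMcdist(f0, sample = 1, eta = 3)
    expect_equal(unname(b0[1, "alpha"]), 3 * 0.5)
    expect_equal(unname(b0[1, "beta"]), 1)
    f1 <- priorCovariates(10, 10, 10)      # r = 1
    f2 <- priorCovariates(20, 20, 10)      # r = 2
    m <- function(b) b[1, "alpha"] / (b[1, "alpha"] + b[1, "beta"])
    expect_lt(m(betaWeightMcdist(f1, 1, 2)), m(betaWeightMcdist(f2, 1, 2)))
    # eta * r = 1 gives the uniform weight prior
    bu <- betaWeightMcdist(f1, 1, eta = 1)
    expect_equal(unname(bu[1, ]), c(1, 1))
})

test_that("latent-category full conditional matches enumeration", {
    p3 <- threecompParams(lam0_1 = 4, lam0_2 = 1.5, lam1 = 3,
                          lam2_1 = 2, lam2_2 = 5)
    x1 <- 5; x2 <- 2
    tp <- function(x, lam) dpois(x, lam, log = TRUE) -
        ppois(1, lam, lower.tail = FALSE, log.p = TRUE)
    ll <- c(tp(5, 4) + tp(2, 1.5), tp(5, 3) + tp(2, 3), tp(5, 2) + tp(2, 5))
    pi <- c(0.2, 0.5, 0.3)
    oracle <- pi * exp(ll) / sum(pi * exp(ll))
    set.seed(1)
    z <- updateZ(x1, x2, pi, p3, model = "threecomp")
    expect_equal(z$prob, oracle, tolerance = 1e-12)
    expect_true(z$category %in% 0:2)
    # a zero weight forces zero probability
    z0 <- updateZ(x1, x2, c(0, 0.5, 0.5), p3, model = "threecomp")
    expect_equal(z0$prob[1], 0)
    # equal weights and equal likelihoods give the uniform conditional
    pSym <- threecompParams(lam0_1 = 3 + 1e-9, lam0_2 = 3, lam1 = 3,
                            lam2_1 = 3, lam2_2 = 3 + 1e-9)
    zu <- updateZ(4, 4, rep(1 / 3, 3), pSym, model = "threecomp")
    expect_equal(zu$prob, rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("weight update is the exact conjugate Dirichlet", {
    set.seed(7)
    alpha <- c(1, 1, 1)
    draws <- t(replicate(1e5, updatePi(2L, alpha)))
    target <- c(1, 1, 2) / 4
    se <- sqrt(target * (1 - target) / (sum(alpha) + 1 + 1)) / sqrt(1e5)
    expect_true(all(abs(colMeans(draws) - target) < 3 * se + 1e-4))
    expect_equal(length(updatePi(0L, rep(2, 6))), 6L)
    expect_error(updatePi(1L, c(1, 0, 1)), "positive")
})

test_that("Metropolis-Hastings step targets a known gamma density", {
    set.seed(11)
    target <- function(v) dgamma(v, shape = 3, rate = 2, log = TRUE)
    cur <- 1
    out <- numeric(20000)
    for (i in seq_along(out)) {
        st <- mhUpdate(cur, target, type = "lognormal", proposalSd = 0.5)
        cur <- st$value
        out[i] <- cur
    }
    expect_equal(mean(out[-(1:2000)]), 1.5, tolerance = 0.08)
    # constraint violations are rejected outright
    bounded <- function(v) if (v > 2) -Inf else 0
    st <- mhUpdate(5, bounded, type = "lognormal", proposalSd = 1e-6)
    expect_false(st$accepted)
    # uniform window respects the reflection bounds
    set.seed(2)
    vals <- replicate(200, mhUpdate(0.5, function(v) 0, type = "uniform",
                                    halfwidth = 2, upper = 1)$value)
    expect_true(all(vals >= 0 & vals <= 1))
})

test_that("MAP classification breaks ties toward the smaller category", {
    expect_equal(classifyMap(rbind(c(0.1, 0.7, 0.2, 0, 0, 0))), 1L)
    expect_equal(classifyMap(rbind(c(0.5, 0.5, 0, 0, 0, 0))), 0L)
    expect_equal(classifyMap(rbind(c(0, 0, 0, 0, 0, 1))), 5L)
})
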