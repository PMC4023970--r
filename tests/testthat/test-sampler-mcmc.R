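# chain-level behavior: reproducibility, constraint satisfaction, and
# parameter/label recovery on data generated from the models themselves

test_that("One-Step chain recovers well-separated categories and rates", {
    set.seed(99)
    n <- 600
    lam <- list(c(52, 20), c(32, 32), c(20, 52),
                c(32, 2), c(2, 32), c(2, 2))
    z <- sample(0:5, n, replace = TRUE,
                prob = c(0.12, 0.25, 0.12, 0.12, 0.12, 0.27))
    X <- matrix(0L, n, 2)
    for (k in 0:5) {
        idx <- which(z == k)
        if (length(idx))
            X[idx, ] <- rJointTrunc(length(idx), lam[[k + 1]][1],
                                    lam[[k + 1]][2])
    }
    pc <- makePairs(X[, 1], X[, 2])
    feats <- neutralFeatures(pc)
    cfg <- chainConfig(nIter = 12000, burnIn = 4000, seed = 5)
    fit <- runOnestep(pc, feats, cfg)

    expect_gte(mean(mapLabels(fit) == z), 0.9)
    expect_equal(rowSums(categoryPosterior(fit)), rep(1, n),
                 tolerance = 1e-12)

    # posterior intensity means within 15% of the generating values
    post <- colMeans(paramDraws(fit))
    truthLam <- c(lam0_1 = 52, lam0_2 = 20, lam1 = 32, lam2_1 = 20,
                  lam2_2 = 52, lam3 = 32, lam4 = 32, lamF1 = 2, lamF2 = 2)
    expect_true(all(abs(post[names(truthLam)] - truthLam) /
                        truthLam < 0.15))

    # identifiability constraints hold in every stored draw
    d <- paramDraws(fit)
    expect_true(all(d[, "lam0_1"] > d[, "lam0_2"]))
    expect_true(all(d[, "lam2_1"] < d[, "lam2_2"]))
    expect_true(all(d[, c("lam0_1", "lam1", "lam2_1", "lam3")] >
                        d[, "lamF1"]))
    expect_true(all(d[, c("lam0_2", "lam1", "lam2_2", "lam4")] >
                        d[, "lamF2"]))
    okAll <- vapply(seq_len(nrow(d)), function(i)
        constraintsOk(do.call(onestepParams, as.list(d[i, 1:13]))),
        logical(1))
    expect_true(all(okAll))
})

test_that("One-Step chain is reproducible given the seed", {
    set.seed(3)
    X <- rJointTrunc(80, 12, 12)
    pc <- makePairs(X[, 1], X[, 2])
    feats <- neutralFeatures(pc)
    cfg <- chainConfig(nIter = 2000, burnIn = 500, seed = 77)
    f1 <- runOnestep(pc, feats, cfg)
    f2 <- runOnestep(pc, feats, cfg)
    expect_identical(categoryPosterior(f1), categoryPosterior(f2))
    expect_identical(paramDraws(f1), paramDraws(f2))
})

test_that("three-component chain separates the differential categories", {
    set.seed(17)
    n <- 360
    lam <- list(c(45, 10), c(24, 24), c(10, 45))
    z <- sample(0:2, n, replace = TRUE)
    X <- matrix(0L, n, 2)
    for (k in 0:2) {
        idx <- which(z == k)
        X[idx, ] <- rBothTrunc(length(idx), lam[[k + 1]][1],
                               lam[[k + 1]][2])
    }
    pc <- makePairs(X[, 1], X[, 2])
    feats <- neutralFeatures(pc)
    fit <- runThreecomp(pc, feats,
                        chainConfig(nIter = 12000, burnIn = 4000,
                                    seed = 9))
    expect_gte(mean(mapLabels(fit) == z), 0.9)
    d <- paramDraws(fit)
    expect_true(all(d[, "lam0_1"] > d[, "lam0_2"]))
    expect_true(all(d[, "lam2_1"] < d[, "lam2_2"]))
    expect_error(runThreecomp(pc[1:2], feats,
                              chainConfig(nIter = 100, burnIn = 10)),
                 "at least 3")
})

test_that("two-component chain recovers separated count clusters", {
    set.seed(23)
    nT <- 120; nF <- 200
    x <- c(sample(30:40, nT, replace = TRUE),
           sample(2:3, nF, replace = TRUE))
    pc <- makePairs(x, rep(2L, nT + nF))
    feats <- neutralFeatures(pc)
    fit <- runMcdist(pc, feats, sample = 1,
                     config = chainConfig(nIter = 6000, burnIn = 2000,
                                          seed = 4))
    truthTrue <- c(rep(TRUE, nT), rep(FALSE, nF))
    expect_gte(mean((mapLabels(fit) == 1L) == truthTrue), 0.98)
    # with identical covariates the posterior is monotone in the count
    pt <- categoryPosterior(fit)[, "true"]
    expect_true(all(pt[seq_len(nT)] > 0.5))
    # reproducibility
    fit2 <- runMcdist(pc, feats, sample = 1,
                      config = chainConfig(nIter = 6000, burnIn = 2000,
                                           seed = 4))
    expect_identical(categoryPosterior(fit), categoryPosterior(fit2))
})

test_that("two-component posterior is monotone in r when counts tie", {
    set.seed(31)
    n <- 60
    x <- rep(5L, n)
    r <- seq(0.01, 3, length.out = n)
    pc <- makePairs(x, rep(2L, n))
    feats <- cbind(S4Vectors::DataFrame(pairId = pairIds(pc)),
                   priorCovariates(r * 100, r * 100, 100))
    fit <- runMcdist(pc, feats, sample = 1,
                     config = chainConfig(nIter = 8000, burnIn = 3000,
                                          seed = 12))
    pt <- categoryPosterior(fit)[, "true"]
    # smoothed monotone trend: upper third vs lower third
    expect_gt(mean(pt[41:60]), mean(pt[1:20]))
})

test_that("Two-Step pipeline routes step-one calls into categories", {
    set.seed(41)
    nTT <- 40; nTF <- 12; nFF <- 30
    x1 <- c(sample(25:35, nTT, TRUE), sample(25:35, nTF, TRUE),
            sample(2:3, nFF, TRUE))
    x2 <- c(sample(25:35, nTT, TRUE), sample(0:1, nTF, TRUE),
            sample(2:3, nFF, TRUE))
    pc <- makePairs(x1, x2)
    feats <- neutralFeatures(pc)
    ts <- runTwostep(pc, feats,
                     chainConfig(nIter = 5000, burnIn = 1500, seed = 6))
    cls <- ts$classification
    # pairs below T in sample two are false there: category 3 with a
    # one-hot posterior
    tfRows <- cls[nTT + seq_len(nTF), ]
    expect_true(all(tfRows$map_category == 3L))
    expect_true(all(tfRows$p3 == 1))
    # false/false pairs are category 5 at probability one
    ffRows <- cls[nTT + nTF + seq_len(nFF), ]
    expect_true(all(ffRows$map_category %in% c(3L, 4L, 5L)))
    expect_gte(mean(ffRows$map_category == 5L), 0.9)
    # true/true pairs are decided by the three-component step only
    ttRows <- cls[seq_len(nTT), ]
    expect_true(all(ttRows$map_category %in% 0:2))
    expect_true(all(abs(rowSums(as.matrix(
        cls[paste0("p", 0:5)])) - 1) < 1e-9))
})
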