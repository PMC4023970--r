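test_that("confusion matrix is an exact cross-tabulation", {
    a <- c(0, 1, 2, 5, 5, 3)
    expect_equal(diag(confusionMatrix(a, a)), c(1, 1, 1, 1, 0, 2),
                 ignore_attr = TRUE)
    m <- confusionMatrix(rep(5, 4), rep(4, 4))
    expect_equal(sum(m), 4)
    expect_equal(m["5", "4"], 4, ignore_attr = TRUE)
    # row sums conserve the actual category totals
    set.seed(1)
    act <- sample(0:5, 300, TRUE); pred <- sample(0:5, 300, TRUE)
    cm <- confusionMatrix(act, pred)
    expect_equal(rowSums(cm), as.vector(table(factor(act, levels = 0:5))),
                 ignore_attr = TRUE)
    expect_error(confusionMatrix(1:3, 1:4), "equal length")
})

test_that("Cohen's kappa matches hand values and the degenerate rule", {
    expect_equal(cohenKappa(diag(c(5, 3, 9))), 1)
    expect_equal(cohenKappa(matrix(c(1, 1, 1, 1), 2)), 0)
    expect_equal(cohenKappa(matrix(c(3, 1, 1, 3), 2)), 0.5)
    # single-category degenerate table
    expect_equal(cohenKappa(matrix(c(7, 0, 0, 0), 2)), 1)
    expect_equal(cohenKappa(matrix(c(0, 7, 0, 0), 2, byrow = TRUE)), 0)
})

test_that("Cohen's kappa agrees with an independent implementation", {
    skip_if_not_installed("e1071")
    set.seed(2)
    for (rep in 1:100) {
        k <- sample(2:6, 1)
        m <- matrix(rpois(k * k, 4), k)
        if (sum(m) == 0) m[1, 1] <- 1
        expect_equal(cohenKappa(m),
                     e1071::classAgreement(m)$kappa, tolerance = 1e-12)
    }
})

test_that("category-to-sample truth mapping follows the design table", {
    expect_equal(categoryToSampleTruth(0:5, 1),
                 c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_equal(categoryToSampleTruth(0:5, 2),
                 c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
})

test_that("type-I error and power are the designed proportions", {
    bp <- binaryPerf(c(TRUE, TRUE, FALSE, FALSE),
                     c(TRUE, FALSE, TRUE, FALSE))
    expect_equal(bp$power, 0.5)
    expect_equal(bp$type1, 0.5)
    allRight <- binaryPerf(c(TRUE, FALSE), c(TRUE, FALSE))
    expect_equal(allRight$power, 1)
    expect_equal(allRight$type1, 0)
    expect_true(is.nan(binaryPerf(c(TRUE, TRUE), c(TRUE, TRUE))$type1))
    # random predictions at rate q give type1 ~ power ~ q
    set.seed(3)
    truth <- rep(c(TRUE, FALSE), 5000)
    pred <- runif(10000) < 0.3
    bp <- binaryPerf(truth, pred)
    expect_lt(abs(bp$power - 0.3), 0.03)
    expect_lt(abs(bp$type1 - 0.3), 0.03)
})

test_that("binary rates and the confusion grid tell one story", {
    set.seed(4)
    act <- sample(0:5, 400, TRUE)
    pred <- sample(0:5, 400, TRUE)
    cm <- confusionMatrix(act, pred)
    for (s in 1:2) {
        tcats <- if (s == 1) c(0, 1, 2, 3) else c(0, 1, 2, 4)
        rows <- as.character(tcats); cols <- as.character(tcats)
        bp <- binaryPerf(categoryToSampleTruth(act, s),
                         categoryToSampleTruth(pred, s))
        expect_equal(bp$power,
                     sum(cm[rows, cols]) / sum(cm[rows, ]))
        expect_equal(bp$type1,
                     sum(cm[!rownames(cm) %in% rows, cols]) /
                         sum(cm[!rownames(cm) %in% rows, ]))
    }
})

test_that("convergence diagnostics behave on known chains", {
    set.seed(5)
    ch <- matrix(rnorm(4000), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
    # identical chains: no between-chain variance
    d2 <- chainDiagnostics(list(ch, ch))
    expect_true(all(d2$psrf <= 1 + 1e-8))
    # chains from the same stationary law
    chains <- lapply(1:3, function(i)
        matrix(rnorm(10000), ncol = 1, dimnames = list(NULL, "a")))
    d3 <- chainDiagnostics(chains)
    expect_lt(d3$psrf, 1.1)
    # independent draws: effective size near nominal (summed over chains)
    expect_gt(d3$ess, 0.5 * 30000)
    expect_lt(d3$ess, 1.6 * 30000)
    # single chain: PSRF unavailable
    d1 <- chainDiagnostics(list(ch))
    expect_true(all(is.na(d1$psrf)))
    expect_true(all(d1$ess > 0))
})

test_that("PSRF agrees with the reference implementation", {
    skip_if_not_installed("coda")
    set.seed(6)
    chains <- lapply(1:3, function(i)
        matrix(rnorm(3000, mean = i * 0.1), ncol = 1,
               dimnames = list(NULL, "a")))
    ours <- chainDiagnostics(chains)$psrf
    ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                             autoburnin = FALSE)$psrf[1, 1]
    expect_equal(ours, ref, tolerance = 0.02)
})

test_that("evaluation report joins classification and truth by id", {
    post <- diag(6)[c(1, 2, 6, 6), ]
    cls <- classificationTable(post, pairId = c(11L, 12L, 13L, 14L))
    truth <- data.frame(pair_id = c(14L, 13L, 12L, 11L),
                        category = c(5L, 5L, 1L, 0L))
    res <- evaluateClassification(cls, truth)
    expect_equal(res$kappa, 1)
    expect_equal(res$perf$power, c(1, 1))
    truthBad <- data.frame(pair_id = 1:4, category = rep(0L, 4))
    expect_error(evaluateClassification(cls, truthBad), "not found")
})
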