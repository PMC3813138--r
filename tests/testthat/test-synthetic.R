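test_that("generation is reproducible from the seed", {
    spec <- syntheticSpec(30, 6, blockSizes = c(3L, 3L),
                          withinBlockCorr = 0.4, activeTerms = c(1, 4),
                          trueCoefficients = c(1, -2), noiseSd = 0.3,
                          seed = 123)
    a <- generateTable(spec)
    b <- generateTable(spec)
    expect_identical(descriptorMatrix(a$table), descriptorMatrix(b$table))
    expect_identical(activityValues(a$table), activityValues(b$table))
})

test_that("noiseless generation is an exact linear identity", {
    spec <- syntheticSpec(40, 5, activeTerms = c(2, 5),
                          trueCoefficients = c(1.5, -0.7),
                          trueIntercept = 2, noiseSd = 0, seed = 7)
    out <- generateTable(spec)
    fit <- fitOLS(out$table, c("D002", "D005"), loo = FALSE)
    st <- fitStats(fit)
    expect_equal(st@r2, 1, tolerance = 1e-12)
    expect_equal(unname(coef(fit)), c(2, 1.5, -0.7), tolerance = 1e-8)
    expect_equal(out$truth@attainableR2, 1)
})

test_that("realized correlations follow the block-exchangeable design", {
    spec <- syntheticSpec(500, 10, blockSizes = rep(5L, 2),
                          withinBlockCorr = 0.6, activeTerms = 1L,
                          trueCoefficients = 1, noiseSd = 1, seed = 31)
    X <- generateTable(spec)$truth@design
    C <- cor(X)
    within <- c(C[1, 2], C[2, 3], C[6, 7], C[9, 10])
    across <- c(C[1, 6], C[2, 9], C[5, 10], C[3, 8])
    expect_true(all(abs(within - 0.6) < 0.1))
    expect_true(all(abs(across) < 0.1))
})

test_that("OLS on the true terms attains the recorded attainable R2", {
    devs <- vapply(1:20, function(s) {
        out <- generateTable(subsetRecoverySpec(seed = s))
        terms <- sprintf("D%03d", out$truth@spec@activeTerms)
        fitStats(fitOLS(out$table, terms, loo = FALSE))@r2 -
            out$truth@attainableR2
    }, numeric(1))
    expect_lt(max(abs(devs)), 0.05)
    ## and the benchmark noise level indeed targets R2 of about 0.9
    expect_lt(abs(mean(devs)), 0.03)
})

test_that("q2 of the true model never exceeds its r2", {
    for (s in 1:5) {
        out <- generateTable(subsetRecoverySpec(seed = s, nSamples = 60))
        terms <- sprintf("D%03d", out$truth@spec@activeTerms)
        st <- fitStats(fitOLS(out$table, terms, loo = TRUE))
        expect_lte(st@q2, st@r2)
    }
})

test_that("invalid specs are rejected", {
    expect_error(syntheticSpec(20, 4, blockSizes = c(3L, 3L),
                               activeTerms = 1, trueCoefficients = 1),
                 "sum to nDescriptors")
    expect_error(syntheticSpec(20, 4, withinBlockCorr = 1,
                               activeTerms = 1, trueCoefficients = 1),
                 "positive definiteness")
    expect_error(syntheticSpec(20, 4, activeTerms = c(1, 9),
                               trueCoefficients = c(1, 1)),
                 "in range")
})

test_that("raising the noise level does not improve mean GFA recovery", {
    ## scaled-down grid: 8 seeds per noise level, n = 120
    rate <- function(noiseSd) {
        hits <- 0L
        for (s in 1:8) {
            spec <- subsetRecoverySpec(seed = s, nSamples = 120)
            spec@noiseSd <- noiseSd
            out <- generateTable(spec)
            cfg <- gfaConfig(populationSize = 150, smoothingD = 4,
                             minTerms = 3, maxTerms = 8,
                             generationsMax = 40, convergenceWindow = 8,
                             seed = s)
            top <- topModel(gfaSearch(out$table, cfg))
            truth <- sort(sprintf("D%03d", spec@activeTerms))
            hits <- hits + identical(top@termSet, truth)
        }
        hits / 8
    }
    rates <- vapply(c(0.3, 0.64, 2.5), rate, numeric(1))
    expect_true(all(diff(rates) <= 1e-12 + 0.125))  # allow one-seed jitter
    expect_gte(rates[1], rates[3])
})
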