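test_that("OLS coefficients match the normal-equations oracle", {
    ## the 4-point hand instance
    tab <- DescriptorTable(matrix(0:3, 4, dimnames = list(NULL, "x")),
                           pIC50Obs = c(1.1, 2.9, 5.2, 6.8))
    fit <- fitOLS(tab, "x", loo = FALSE)
    oracle <- normalEquationsOracle(descriptorMatrix(tab),
                                    activityValues(tab))
    expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-10)

    ## random instances, n <= 30, p <= 5
    for (seed in 1:12) {
        set.seed(seed)
        n <- sample(10:30, 1)
        p <- sample(1:5, 1)
        tab <- randomTable(n, p, seed = seed + 100)
        fit <- fitOLS(tab, descriptorNames(tab), loo = FALSE)
        oracle <- normalEquationsOracle(descriptorMatrix(tab),
                                        activityValues(tab))
        expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-8)
    }
})

test_that("a perfect single-term fit gives r2 = 1 and sse = 0", {
    set.seed(5)
    y <- rnorm(10)
    tab <- DescriptorTable(matrix(y, dimnames = list(NULL, "self")),
                           pIC50Obs = y)
    fit <- fitOLS(tab, "self", loo = FALSE)
    expect_equal(fitStats(fit)@r2, 1)
    expect_equal(fitStats(fit)@sse, 0, tolerance = 1e-20)
    expect_equal(fitStats(fit)@fStat, Inf)
})

test_that("closed-form statistics match hand-derived values", {
    expect_equal(adjustedR2(0.882, 59, 11), 1 - 0.118 * 58 / 47)
    expect_equal(round(adjustedR2(0.882, 59, 11), 3), 0.854)
    expect_equal(adjustedR2(1.0, 59, 11), 1.0)
    expect_equal(adjustedR2(0.750, 59, 8), 0.710, tolerance = 1e-3)
    expect_error(adjustedR2(0.5, 10, 9), "domain error")

    expect_equal(fStatistic(0.882, 59, 11), 31.94, tolerance = 1e-3)
    expect_equal(fStatistic(0, 59, 11), 0)
    expect_equal(fStatistic(0.5, 12, 2), 4.5)
    expect_identical(fStatistic(1, 12, 2), Inf)

    expect_equal(friedmanLOF(0, 50, 5, 6, 0.5), 0)
    expect_equal(friedmanLOF(2.0, 50, 5, 6, 0.5), 2 / (50 * (1 - 8 / 50)^2))
    expect_equal(round(friedmanLOF(2.0, 50, 5, 6, 0.5), 4), 0.0567)
    expect_equal(round(friedmanLOF(1.0, 10, 0, 1, 0.5), 4), 0.1108)
    expect_error(friedmanLOF(1.0, 8, 5, 6, 0.5), "degenerate penalty")
})

test_that("explicit leave-one-out q2 equals the hat-matrix shortcut", {
    for (seed in c(2, 9, 31)) {
        tab <- randomTable(10, 3, seed = seed)
        q2 <- looQ2(tab, descriptorNames(tab))
        y <- activityValues(tab)
        pressOracle <- hatMatrixPress(descriptorMatrix(tab), y)
        expect_equal(q2, 1 - pressOracle / sum((y - mean(y))^2),
                     tolerance = 1e-10)
    }
})

test_that("noiseless linear data give q2 = 1", {
    tab <- randomTable(15, 3, seed = 4, noiseSd = 0)
    expect_equal(looQ2(tab, descriptorNames(tab)), 1, tolerance = 1e-10)
})

test_that("q2 <= r2 and r2_adj <= r2 on randomized fits", {
    for (seed in 1:10) {
        set.seed(seed)
        tab <- randomTable(sample(15:40, 1), sample(2:5, 1),
                           seed = seed + 50, noiseSd = runif(1, 0.2, 2))
        fit <- fitOLS(tab, descriptorNames(tab), loo = TRUE)
        st <- fitStats(fit)
        expect_lte(st@q2, st@r2)
        expect_gte(st@press, st@sse)
        expect_lt(st@r2adj, st@r2)  # equality only at r2 = 1
    }
})

test_that("standardized coefficients are scale-invariant and reduce to raw
           coefficients on unit-variance data", {
    tab <- randomTable(40, 4, seed = 77)
    fit <- fitOLS(tab, descriptorNames(tab), loo = FALSE)
    std <- standardizedCoefficients(qsarModel(fit), tab)
    expect_equal(std, stdCoefficients(fit))

    ## doubling a column leaves its standardized coefficient unchanged
    m <- descriptorMatrix(tab)
    m[, 2] <- 2 * m[, 2]
    tab2 <- DescriptorTable(m, pIC50Obs = activityValues(tab))
    fit2 <- fitOLS(tab2, descriptorNames(tab2), loo = FALSE)
    expect_equal(stdCoefficients(fit2), std, tolerance = 1e-10)

    ## pre-standardized descriptors and response: standardized == raw
    ms <- scale(descriptorMatrix(tab))
    ys <- drop(scale(activityValues(tab)))
    attr(ms, "scaled:center") <- attr(ms, "scaled:scale") <- NULL
    tabS <- DescriptorTable(ms, pIC50Obs = ys)
    fitS <- fitOLS(tabS, descriptorNames(tabS), loo = FALSE)
    expect_equal(stdCoefficients(fitS), qsarModel(fitS)@coefficients,
                 tolerance = 1e-10)
})

test_that("fitted values are invariant under affine descriptor rescaling", {
    tab <- randomTable(30, 4, seed = 11)
    fit <- fitOLS(tab, descriptorNames(tab), loo = FALSE)
    m <- descriptorMatrix(tab)
    m[, 3] <- 5 * m[, 3] - 7
    tab2 <- DescriptorTable(m, pIC50Obs = activityValues(tab))
    fit2 <- fitOLS(tab2, descriptorNames(tab2), loo = FALSE)
    expect_equal(fitted(fit2), fitted(fit), tolerance = 1e-8)
})

test_that("F statistic agrees with the SSE/SSR decomposition form", {
    for (seed in 1:5) {
        tab <- randomTable(25, 3, seed = seed + 7)
        st <- fitStats(fitOLS(tab, descriptorNames(tab), loo = FALSE))
        ssr <- st@sst - st@sse
        expect_equal(st@fStat,
                     (ssr / st@k) / (st@sse / (st@n - st@k - 1)),
                     tolerance = 1e-8)
    }
})

test_that("singular and undersized designs raise informative errors", {
    m <- cbind(a = rnorm(10), b = 1:10)
    m <- cbind(m, c = m[, "a"] + 2 * m[, "b"])
    tab <- DescriptorTable(m, pIC50Obs = rnorm(10))
    expect_error(fitOLS(tab, c("a", "b", "c")), "singular design")
    small <- randomTable(4, 3, seed = 1)
    expect_error(fitOLS(small, descriptorNames(small)), "insufficient data")
    expect_error(fitOLS(randomTable(10, 2, seed = 1), "nope"),
                 "unknown descriptor")
})

test_that("fixed-equation evaluation is pure arithmetic", {
    mod <- fixedModel(2.5, c(A = 0, B = 0))
    expect_equal(unname(predict(mod, c(A = 9, B = -4))), 2.5)

    ## the published 8-descriptor equation on ligand 25, against an inlined
    ## hand dot product of the printed coefficients with the printed row
    t2 <- hdm2Table("table2")
    r25 <- descriptorMatrix(t2)["25", ]
    hand <- 14.568 + 0.388 * r25[["LogD"]] -
        0.166 * r25[["Num_RotatableBonds"]] -
        0.670 * r25[["Num_StereoAtoms"]] + 0.00278 * r25[["V_DIST_equ"]] -
        1.446 * r25[["CHI_1"]] - 0.0471 * r25[["Dipole_X"]] +
        0.230 * r25[["Shadow_Xlength"]] - 0.0328 * r25[["Shadow_XZ"]]
    got <- predict(hdm2Equation("ds"), t2["25"])
    expect_equal(unname(got), hand, tolerance = 1e-12)
    expect_equal(round(unname(got), 3), 2.885)

    expect_error(predict(fixedModel(0, c(Zz = 1)), t2["25"]), "Zz")
})

test_that("importance ranking sorts by |standardized coefficient| with
           lexicographic ties", {
    expect_identical(rankImportance(c(solo = -3)), "solo")
    expect_identical(rankImportance(c(b = -2, a = 2)), c("a", "b"))
    expect_identical(rankImportance(c(x = 0.1, y = -5, z = 2)),
                     c("y", "z", "x"))
    expect_error(rankImportance(numeric(0)), "non-empty")
})
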