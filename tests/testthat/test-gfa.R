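poolABCD <- c("a", "b", "c", "d", "e", "f")

test_that("crossover of identical parents returns the parents", {
    set.seed(1)
    for (i in 1:20) {
        p <- sort(sample(poolABCD, 3))
        kids <- gfaCrossover(p, p, poolABCD, 1, 6)
        expect_identical(kids[[1]], p)
        expect_identical(kids[[2]], p)
    }
})

test_that("crossover of disjoint two-term parents is a tail swap", {
    ## split at 1 gives {a,d}/{c,b}; split at 2 returns the parents
    seen <- character()
    for (seed in 1:40) {
        set.seed(seed)
        kids <- gfaCrossover(c("a", "b"), c("c", "d"), poolABCD, 1, 6)
        key <- paste(kids[[1]], collapse = "")
        expect_true(key %in% c("ad", "ab"))
        if (key == "ad")
            expect_identical(kids[[2]], c("b", "c"))
        else
            expect_identical(kids[[2]], c("c", "d"))
        seen <- c(seen, key)
    }
    expect_setequal(unique(seen), c("ad", "ab"))
})

test_that("crossover repair keeps offspring within the size bounds", {
    a <- c("a", "b", "c", "d")
    b <- c("a", "b", "c", "e")
    set.seed(3)
    for (i in 1:200) {
        kids <- gfaCrossover(a, b, poolABCD, 2, 4)
        for (kid in kids) {
            expect_gte(length(kid), 2)
            expect_lte(length(kid), 4)
            expect_false(anyDuplicated(kid) > 0)
        }
    }
})

test_that("mutation respects rate, bounds and move feasibility", {
    set.seed(7)
    base <- c("a", "b", "c")
    expect_identical(gfaMutate(base, poolABCD, 1, 6, rate = 0), base)

    ## at maxTerms, "add" is infeasible: size never grows
    for (i in 1:1000) {
        out <- gfaMutate(base, poolABCD, 1, 3, rate = 1)
        expect_lte(length(out), 3)
    }
    ## pool == term set: only remove (or no-op at minTerms)
    for (i in 1:1000) {
        out <- gfaMutate(base, base, 1, 3, rate = 1)
        expect_true(length(out) %in% c(2, 3))
        expect_true(all(out %in% base))
    }
    expect_identical(gfaMutate(base, base, 3, 3, rate = 1), base)
})

test_that("gfaSearch is deterministic given config and seed", {
    tab <- randomTable(40, 8, seed = 5, coefs = c(1, -1, rep(0, 6)))
    cfg <- gfaConfig(populationSize = 40, minTerms = 1, maxTerms = 4,
                     generationsMax = 15, convergenceWindow = 5, seed = 11)
    r1 <- gfaSearch(tab, cfg)
    r2 <- gfaSearch(tab, cfg)
    expect_identical(lapply(individuals(r1), slot, "termSet"),
                     lapply(individuals(r2), slot, "termSet"))
    expect_identical(searchLog(r1), searchLog(r2))
})

test_that("elitism makes the best LOF non-increasing across generations", {
    tab <- randomTable(40, 10, seed = 6, coefs = c(1, -1, 0.5, rep(0, 7)))
    cfg <- gfaConfig(populationSize = 60, minTerms = 1, maxTerms = 5,
                     generationsMax = 25, convergenceWindow = 8, seed = 2)
    res <- gfaSearch(tab, cfg)
    expect_true(all(diff(searchLog(res)$bestLOF) <= 1e-12))
    ## ranked output is sorted by fitness
    fits <- vapply(individuals(res), slot, numeric(1), "fitness")
    expect_true(all(diff(fits) >= -1e-12))
})

test_that("a single-descriptor pool yields the only possible equation", {
    tab <- randomTable(20, 3, seed = 9)
    cfg <- gfaConfig(populationSize = 10, minTerms = 1, maxTerms = 1,
                     generationsMax = 3, convergenceWindow = 2, seed = 1)
    res <- gfaSearch(tab, cfg, pool = "X02")
    expect_length(individuals(res), 1L)
    top <- topModel(res)
    expect_identical(top@termSet, "X02")
    expect_equal(top@fitness,
                 fitStats(fitOLS(tab, "X02", loo = FALSE))@lof)
})

test_that("cached fitness is coherent: recomputing an individual's LOF from
           its term set gives its stored fitness", {
    tab <- randomTable(30, 6, seed = 13)
    cfg <- gfaConfig(populationSize = 30, minTerms = 2, maxTerms = 4,
                     generationsMax = 10, convergenceWindow = 4, seed = 3)
    res <- gfaSearch(tab, cfg)
    for (ind in individuals(res)[1:min(5, length(individuals(res)))])
        expect_equal(ind@fitness,
                     fitStats(fitOLS(tab, ind@termSet, loo = FALSE))@lof,
                     tolerance = 1e-12)
})

test_that("the best searched LOF never beats the exhaustive optimum and
           usually equals it on a small pool", {
    tab <- hdm2Table("table2")
    pool <- descriptorNames(tab)
    brute <- enumerateBestLOF(tab, pool, 2, 3)
    hits <- 0L
    for (seed in 1:20) {
        cfg <- gfaConfig(populationSize = 80, minTerms = 2, maxTerms = 3,
                         generationsMax = 25, convergenceWindow = 6,
                         seed = seed)
        best <- topModel(gfaSearch(tab, cfg))
        expect_gte(best@fitness, brute$lof - 1e-12)
        if (abs(best@fitness - brute$lof) < 1e-10) hits <- hits + 1L
    }
    expect_gte(hits, 18L)  # >= 90% of seeded runs
})

test_that("the full model is a feasible individual, so the best LOF cannot
           exceed its LOF", {
    tab <- hdm2Table("table3")
    full <- fitStats(fitOLS(tab, descriptorNames(tab), loo = FALSE))@lof
    cfg <- gfaConfig(populationSize = 100, minTerms = 3, maxTerms = 11,
                     generationsMax = 20, convergenceWindow = 5, seed = 4)
    res <- gfaSearch(tab, cfg)
    expect_lte(topModel(res)@fitness, full + 1e-12)
})

test_that("G/PLS mode runs and regularises candidate equations", {
    tab <- randomTable(30, 8, seed = 17, coefs = c(1, -1, rep(0, 6)))
    cfg <- gfaConfig(populationSize = 30, minTerms = 2, maxTerms = 4,
                     generationsMax = 8, convergenceWindow = 3,
                     fittingMode = "pls", plsComponents = 2, seed = 5)
    res <- gfaSearch(tab, cfg)
    top <- topModel(res)
    expect_identical(top@model@provenance, "pls")
    expect_lte(top@model@nComponents, 2L)
})

test_that("infeasible configurations error out", {
    tab <- randomTable(20, 3, seed = 1)
    expect_error(gfaConfig(populationSize = 1), "populationSize")
    expect_error(gfaConfig(minTerms = 5, maxTerms = 3), "minTerms")
    expect_error(gfaSearch(tab, gfaConfig(populationSize = 10),
                           pool = c("X01", "ghost")),
                 "unknown descriptor")
})
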