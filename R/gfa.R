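#' Construct a GFA search configuration
#'
#' Defaults follow common GFA practice: a population of 1000 equations scored
#' by Friedman LOF at smoothing factor 0.5, evolved by single-point crossover
#' (rate 0.9), low-rate mutation (0.1), tournament selection of size 2 and
#' elitism of 1, until the per-descriptor usage histogram of the population is
#' unchanged for \code{convergenceWindow} consecutive generations (usage
#' becoming constant under further crossover is the classical GFA stopping
#' signal) or \code{generationsMax} is reached.
#'
#' @param populationSize,smoothingD,minTerms,maxTerms,generationsMax
#'   see \linkS4class{GFAConfig}.
#' @param crossoverRate,mutationRate,fittingMode,plsComponents,seed,convergenceWindow
#'   see \linkS4class{GFAConfig}.
#' @return a validated \linkS4class{GFAConfig}.
#' @export
gfaConfig <- function(populationSize = 1000L, smoothingD = 0.5,
                      minTerms = 3L, maxTerms = 12L,
                      generationsMax = 500L,
                      crossoverRate = 0.9, mutationRate = 0.1,
                      fittingMode = c("ols", "pls"), plsComponents = 4L,
                      seed = 1L, convergenceWindow = 50L) {
    new("GFAConfig",
        populationSize = as.integer(populationSize),
        smoothingD = smoothingD,
        minTerms = as.integer(minTerms), maxTerms = as.integer(maxTerms),
        generationsMax = as.integer(generationsMax),
        crossoverRate = crossoverRate, mutationRate = mutationRate,
        fittingMode = match.arg(fittingMode),
        plsComponents = as.integer(plsComponents),
        seed = as.integer(seed),
        convergenceWindow = as.integer(convergenceWindow))
}

## canonical key of a term set (sets are kept sorted throughout the search)
.termKey <- function(terms) paste(terms, collapse = "\r")

## repair a term set to the [minTerms, maxTerms] bounds by random
## trimming / padding from the pool
.repairTerms <- function(terms, pool, minTerms, maxTerms) {
    terms <- unique(terms)
    if (length(terms) > maxTerms)
        terms <- sample(terms, maxTerms)
    if (length(terms) < minTerms) {
        avail <- setdiff(pool, terms)
        need <- min(minTerms - length(terms), length(avail))
        if (need > 0)
            terms <- c(terms, sample(avail, need))
    }
    sort(terms)
}

#' Single-point crossover of two term sets
#'
#' Each parent's (sorted) term list is split at a common random point; the
#' offspring swap tails, are deduplicated and repaired to the size bounds by
#' random trimming/padding from the descriptor pool.  Identical parents yield
#' identical offspring.  Consumes the R random number stream.
#'
#' @param a,b character vectors: the parents' term sets.
#' @param pool full descriptor pool for repair padding.
#' @param minTerms,maxTerms size bounds.
#' @return list of two repaired offspring term sets.
#' @export
gfaCrossover <- function(a, b, pool, minTerms, maxTerms) {
    la <- length(a)
    lb <- length(b)
    s <- sample.int(min(la, lb), 1L)
    c1 <- c(a[seq_len(s)], if (s < lb) b[seq.int(s + 1L, lb)])
    c2 <- c(b[seq_len(s)], if (s < la) a[seq.int(s + 1L, la)])
    list(.repairTerms(c1, pool, minTerms, maxTerms),
         .repairTerms(c2, pool, minTerms, maxTerms))
}

#' Mutate a term set
#'
#' With probability \code{rate} applies one move drawn uniformly among the
#' feasible ones: add a pool descriptor (if below \code{maxTerms} and one is
#' available), remove a term (if above \code{minTerms}), or swap a term for a
#' pool descriptor.  When no move is feasible the set is returned unchanged.
#' Consumes the R random number stream.
#'
#' @param terms character vector: the term set.
#' @param pool full descriptor pool.
#' @param minTerms,maxTerms size bounds.
#' @param rate mutation probability.
#' @return the (possibly) mutated, sorted term set.
#' @export
gfaMutate <- function(terms, pool, minTerms, maxTerms, rate) {
    if (rate <= 0 || stats::runif(1) >= rate)
        return(sort(terms))
    avail <- setdiff(pool, terms)
    moves <- c(
        if (length(terms) < maxTerms && length(avail)) "add",
        if (length(terms) > minTerms) "remove",
        if (length(avail) && length(terms)) "swap")
    if (!length(moves))
        return(sort(terms))
    move <- if (length(moves) == 1L) moves else sample(moves, 1L)
    terms <- switch(move,
        add = c(terms, sample(avail, 1L)),
        remove = terms[-sample.int(length(terms), 1L)],
        swap = c(terms[-sample.int(length(terms), 1L)], sample(avail, 1L)))
    sort(terms)
}

## fast fitness evaluation (LOF; Inf for singular candidates), memoised
.gfaEvaluator <- function(table, config) {
    tr <- trainingSet(table)
    Xall <- tr@descriptors
    y <- tr@pIC50Obs
    n <- length(y)
    d <- config@smoothingD
    cache <- new.env(parent = emptyenv(), hash = TRUE)
    function(terms) {
        key <- .termKey(terms)
        hit <- cache[[key]]
        if (!is.null(hit))
            return(hit)
        k <- length(terms)
        lof <- Inf
        if (n > k + 1L && (k + d * (k + 1L)) < n) {
            X <- cbind(1, Xall[, terms, drop = FALSE])
            if (config@fittingMode == "ols") {
                fit <- stats::lm.fit(X, y)
                if (fit$rank == ncol(X)) {
                    sse <- sum(fit$residuals^2)
                    lof <- friedmanLOF(sse, n, k, k + 1L, d)
                }
            } else {
                sol <- tryCatch(
                    .plsSolve(X[, -1L, drop = FALSE], y,
                              min(config@plsComponents, k)),
                    error = function(e) NULL)
                if (!is.null(sol)) {
                    pred <- sol$intercept +
                        drop(Xall[, terms, drop = FALSE] %*% sol$coefficients)
                    sse <- sum((y - pred)^2)
                    lof <- friedmanLOF(sse, n, k, k + 1L, d)
                }
            }
        }
        cache[[key]] <- lof
        lof
    }
}

## deterministic ranking: fitness, then fewer terms, then lexicographic names
.gfaOrder <- function(fitness, termSets) {
    keys <- vapply(termSets, .termKey, character(1))
    order(fitness, lengths(termSets), keys)
}

## 32-bit polynomial hash of the descriptor-usage histogram (for the log)
.usageHash <- function(usage) {
    h <- 0
    for (v in usage)
        h <- (h * 131 + v) %% 2147483647
    sprintf("%08x", h)
}

#' Genetic function approximation search
#'
#' Evolves a population of linear-term equations (descriptor subsets) scored
#' by Friedman lack-of-fit on the training subset of \code{table}.  Each
#' candidate is fitted by OLS (or by NIPALS PLS when
#' \code{fittingMode = "pls"}, i.e. G/PLS); singular candidates receive
#' infinite fitness rather than aborting the run, so collinear pools are
#' searched robustly.  Selection is a size-2 tournament with elitism of 1,
#' which makes the best fitness monotone non-increasing over generations.
#' The run terminates when the population's per-descriptor usage histogram
#' has been unchanged for \code{convergenceWindow} consecutive generations,
#' or at \code{generationsMax}.  The whole search is reproducible from
#' \code{config@seed} (the caller's RNG state is saved and restored).
#'
#' @param table a \linkS4class{DescriptorTable} with a non-empty training
#'   subset.
#' @param config a \linkS4class{GFAConfig}.
#' @param pool descriptor pool to search (default: the full schema).
#' @param logConnection optional connection (or \code{""} for stdout) to
#'   which a one-line-per-generation search log is written.
#'
#' @return a \linkS4class{GFAResult}: the final population ranked by
#'   ascending LOF (singular individuals dropped).
#' @examples
#' spec <- subsetRecoverySpec(seed = 7)
#' tab <- generateTable(spec)$table
#' res <- gfaSearch(tab, gfaConfig(populationSize = 200, maxTerms = 8,
#'                                 generationsMax = 40, seed = 7,
#'                                 convergenceWindow = 10))
#' topModel(res)
#' @export
gfaSearch <- function(table, config = gfaConfig(),
                      pool = descriptorNames(table), logConnection = NULL) {
    stopifnot(is(table, "DescriptorTable"), is(config, "GFAConfig"))
    pool <- sort(unique(as.character(pool)))
    missing <- setdiff(pool, table@schema)
    if (length(missing))
        stop("unknown descriptor(s) in pool: ",
             paste(missing, collapse = ", "))
    n <- nTraining(table)
    if (n < 3L)
        stop("insufficient data: need at least 3 training records")
    maxT <- min(config@maxTerms, length(pool), n - 2L)
    minT <- min(config@minTerms, maxT)
    if (minT < 1L || minT > length(pool))
        stop("config error: infeasible term bounds for this pool")

    ## reproducibility without clobbering the caller's RNG
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        oldSeed <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed(config@seed)

    evalLOF <- .gfaEvaluator(table, config)
    popSize <- config@populationSize
    population <- replicate(popSize, {
        size <- if (minT == maxT) minT else
            sample(seq.int(minT, maxT), 1L)
        sort(sample(pool, size))
    }, simplify = FALSE)
    fitness <- vapply(population, evalLOF, numeric(1))

    tournament <- function() {
        i <- sample.int(popSize, 2L, replace = TRUE)
        o <- .gfaOrder(fitness[i], population[i])[1L]
        population[[i[o]]]
    }
    usageOf <- function(pop) {
        u <- integer(length(pool))
        names(u) <- pool
        tab <- table(unlist(pop))
        u[names(tab)] <- as.integer(tab)
        u
    }

    logLines <- character(0)
    emit <- function(gen, fit, usage) {
        line <- sprintf("generation %d: bestLOF=%.6g medianLOF=%.6g usage=%s",
                        gen, min(fit), stats::median(fit), .usageHash(usage))
        if (!is.null(logConnection))
            writeLines(line, logConnection)
        logLines <<- c(logLines, line)
        data.frame(generation = gen, bestLOF = min(fit),
                   medianLOF = stats::median(fit),
                   usageHash = .usageHash(usage),
                   stringsAsFactors = FALSE)
    }

    usage <- usageOf(population)
    logDf <- emit(0L, fitness, usage)
    stable <- 0L
    gen <- 0L
    converged <- FALSE
    while (gen < config@generationsMax) {
        gen <- gen + 1L
        elite <- population[[.gfaOrder(fitness, population)[1L]]]
        newPop <- vector("list", popSize)
        newPop[[1L]] <- elite
        filled <- 1L
        while (filled < popSize) {
            p1 <- tournament()
            p2 <- tournament()
            kids <- if (stats::runif(1) < config@crossoverRate)
                gfaCrossover(p1, p2, pool, minT, maxT)
            else
                list(p1, p2)
            for (kid in kids) {
                if (filled >= popSize) break
                filled <- filled + 1L
                newPop[[filled]] <- gfaMutate(kid, pool, minT, maxT,
                                              config@mutationRate)
            }
        }
        population <- newPop
        fitness <- vapply(population, evalLOF, numeric(1))
        newUsage <- usageOf(population)
        stable <- if (identical(newUsage, usage)) stable + 1L else 0L
        usage <- newUsage
        logDf <- rbind(logDf, emit(gen, fitness, usage))
        if (stable >= config@convergenceWindow) {
            converged <- TRUE
            break
        }
    }

    ord <- .gfaOrder(fitness, population)
    ord <- ord[is.finite(fitness[ord])]
    if (!length(ord))
        stop("search failure: every candidate model was singular")
    ## unique term sets, ranked
    keys <- vapply(population[ord], .termKey, character(1))
    ord <- ord[!duplicated(keys)]
    indiv <- lapply(ord, function(i) {
        terms <- population[[i]]
        fit <- if (config@fittingMode == "ols")
            fitOLS(table, terms, smoothingD = config@smoothingD, loo = FALSE)
        else
            fitPLS(table, terms,
                   nComponents = min(config@plsComponents, length(terms)),
                   smoothingD = config@smoothingD)
        new("GFAIndividual", termSet = terms, model = fit@model,
            stats = fit@stats, fitness = fit@stats@lof)
    })
    new("GFAResult", individuals = indiv, config = config, log = logDf,
        generations = gen, converged = converged)
}

#' @describeIn GFAResult ranked list of \linkS4class{GFAIndividual}
#' @param x a \code{GFAResult}.
#' @export
setMethod("individuals", "GFAResult", function(x) x@individuals)

#' @describeIn GFAResult the best individual
#' @export
setMethod("topModel", "GFAResult", function(x) x@individuals[[1L]])

#' @describeIn GFAResult per-generation search log as a data frame
#' @export
setMethod("searchLog", "GFAResult", function(x) x@log)

#' Summarise a GFA result as a data frame
#'
#' @param x a \linkS4class{GFAResult}.
#' @param row.names,optional,... S3 compatibility; unused.
#' @return data frame with one row per ranked equation: terms, LOF, R2,
#'   adjusted R2 and F.
#' @export
as.data.frame.GFAResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
    do.call(rbind, lapply(seq_along(x@individuals), function(i) {
        ind <- x@individuals[[i]]
        data.frame(rank = i,
                   terms = paste(ind@termSet, collapse = "+"),
                   nTerms = length(ind@termSet),
                   lof = ind@fitness,
                   r2 = ind@stats@r2,
                   r2adj = ind@stats@r2adj,
                   fStat = ind@stats@fStat,
                   stringsAsFactors = FALSE)
    }))
}

setMethod("show", "GFAIndividual", function(object) {
    cat(sprintf("GFAIndividual (%d terms, LOF = %.4f): %s\n",
                length(object@termSet), object@fitness,
                paste(object@termSet, collapse = ", ")))
})

setMethod("show", "GFAResult", function(object) {
    cat(sprintf("GFAResult: %d ranked equation(s), %d generation(s)%s\n",
                length(object@individuals), object@generations,
                if (object@converged) " (usage converged)" else ""))
    for (i in seq_len(min(5L, length(object@individuals))))
        show(object@individuals[[i]])
})
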