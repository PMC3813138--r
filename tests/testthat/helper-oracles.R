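## Independent oracles and fixture builders shared across the suite.

## Closed-form normal-equations solve: (X'X)^{-1} X'y with an explicit
## intercept column.  Deliberately a different algorithm (Cholesky-backed
## solve of the Gram system) from the QR route used by the package.
normalEquationsOracle <- function(X, y) {
    Xi <- cbind(1, X)
    drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

## Hat-matrix PRESS identity for OLS: sum((e_i / (1 - h_ii))^2).
hatMatrixPress <- function(X, y) {
    Xi <- cbind(1, X)
    H <- Xi %*% solve(crossprod(Xi), t(Xi))
    e <- y - H %*% y
    sum((e / (1 - diag(H)))^2)
}

## Random dense descriptor table with a linear response.
randomTable <- function(n, p, seed, coefs = NULL, noiseSd = 0.5,
                        intercept = 0.5) {
    set.seed(seed)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("X%02d", seq_len(p))))
    if (is.null(coefs))
        coefs <- rnorm(p)
    y <- intercept + drop(X %*% coefs) + rnorm(n, sd = noiseSd)
    DescriptorTable(X, pIC50Obs = y, name = "random")
}

## Exhaustive best-subset search by Friedman LOF over all admissible sizes.
enumerateBestLOF <- function(table, pool, minTerms, maxTerms, d = 0.5) {
    best <- Inf
    bestSet <- NULL
    tr <- trainingSet(table)
    y <- activityValues(tr)
    for (k in seq.int(minTerms, maxTerms)) {
        for (idx in utils::combn(length(pool), k, simplify = FALSE)) {
            terms <- pool[idx]
            X <- cbind(1, descriptorMatrix(tr)[, terms, drop = FALSE])
            fit <- stats::lm.fit(X, y)
            if (fit$rank < ncol(X)) next
            lof <- sum(fit$residuals^2) /
                (length(y) * (1 - (k + d * (k + 1)) / length(y))^2)
            if (lof < best) {
                best <- lof
                bestSet <- sort(terms)
            }
        }
    }
    list(lof = best, terms = bestSet)
}
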