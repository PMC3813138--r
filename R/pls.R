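## NIPALS partial least squares for a single response.
## X and y must already be centered and unit-scaled; returns the regression
## vector in the scaled space plus the weight/loading structure.
.nipals <- function(X, y, nComponents) {
    p <- ncol(X)
    E <- X
    f <- y
    W <- P <- matrix(0, p, nComponents)
    q <- numeric(nComponents)
    for (a in seq_len(nComponents)) {
        w <- drop(crossprod(E, f))
        wn <- sqrt(sum(w^2))
        if (wn < 1e-12)
            stop("component-count error: response exhausted after ",
                 a - 1L, " component(s)")
        w <- w / wn
        tvec <- drop(E %*% w)
        tt <- sum(tvec^2)
        if (tt < 1e-12)
            stop("component-count error: degenerate score at component ", a)
        pvec <- drop(crossprod(E, tvec)) / tt
        qa <- sum(f * tvec) / tt
        E <- E - tcrossprod(tvec, pvec)
        f <- f - tvec * qa
        W[, a] <- w
        P[, a] <- pvec
        q[a] <- qa
    }
    ## regression vector: B = W (P'W)^{-1} q
    B <- drop(W %*% solve(crossprod(P, W), q))
    list(B = B, W = W, P = P, q = q)
}

## Core PLS solve on a raw design bundle: autoscale, extract components,
## back-transform to the original descriptor scale.
.plsSolve <- function(Xraw, y, nComponents) {
    xm <- colMeans(Xraw)
    xs <- apply(Xraw, 2L, stats::sd)
    if (any(xs == 0))
        stop("degenerate descriptor (zero variance): ",
             paste(colnames(Xraw)[xs == 0], collapse = ", "))
    ym <- mean(y)
    ys <- stats::sd(y)
    if (ys == 0)
        stop("degenerate response (zero variance)")
    Xs <- scale(Xraw, center = xm, scale = xs)
    ysc <- (y - ym) / ys
    rk <- qr(Xs)$rank
    if (nComponents > rk)
        stop(sprintf("component-count error: %d components requested, rank is %d",
                     nComponents, rk))
    nip <- .nipals(Xs, ysc, nComponents)
    b <- ys * nip$B / xs
    names(b) <- colnames(Xraw)
    list(coefficients = b, intercept = ym - sum(b * xm))
}

#' Fit a partial-least-squares QSAR equation
#'
#' Single-response PLS by NIPALS: components are extracted sequentially to
#' maximise covariance with the response on centered, unit-scaled data
#' (autoscaling, the standard QSAR preprocessing), then collapsed to an
#' equivalent \linkS4class{LinearModel} on the original descriptor scale.
#' With \code{nComponents} equal to the design rank the fit coincides with
#' OLS; fewer components give a regularised fit, which is how G/PLS tempers
#' equations selected by the genetic search.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param terms descriptor names to use.
#' @param nComponents latent-variable count; default \code{min(4, length(terms))}.
#' @param smoothingD Friedman LOF smoothing factor for the statistics.
#' @param loo compute q2 by explicit leave-one-out PLS refits (default
#'   \code{FALSE}).
#'
#' @return a \linkS4class{QSARFit} whose model has provenance \code{"pls"}.
#' @export
fitPLS <- function(table, terms, nComponents = min(4L, length(terms)),
                   smoothingD = 0.5, loo = FALSE) {
    d <- .designMatrix(table, terms)
    k <- length(d$terms)
    nComponents <- as.integer(nComponents)
    if (nComponents < 1L)
        stop("component-count error: need at least one component")
    if (d$n <= k + 1L)
        stop(sprintf("insufficient data: n = %d training records for %d terms",
                     d$n, k))
    Xraw <- d$X[, -1L, drop = FALSE]
    sol <- .plsSolve(Xraw, d$y, nComponents)
    model <- new("LinearModel", intercept = sol$intercept,
                 coefficients = sol$coefficients, provenance = "pls",
                 nComponents = nComponents)
    fitted <- stats::setNames(
        sol$intercept + drop(Xraw %*% sol$coefficients), d$ids)
    press <- NA_real_
    if (loo) {
        press <- 0
        for (i in seq_len(d$n)) {
            si <- .plsSolve(Xraw[-i, , drop = FALSE], d$y[-i], nComponents)
            press <- press +
                (d$y[i] - si$intercept - sum(Xraw[i, ] * si$coefficients))^2
        }
    }
    .makeFit(model, d, fitted, press, smoothingD, table@tableName,
             nComponents = nComponents)
}
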