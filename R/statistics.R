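#' Adjusted R-squared
#'
#' \code{1 - (1 - r2) * (n - 1) / (n - k - 1)}: penalises the coefficient of
#' determination for the number of fitted terms.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param k number of non-intercept terms.
#' @export
adjustedR2 <- function(r2, n, k) {
    if (n <= k + 1)
        stop("domain error: need n > k + 1")
    1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Overall F statistic of a regression from its R-squared
#'
#' \code{(r2 / k) / ((1 - r2) / (n - k - 1))} on (k, n - k - 1) degrees of
#' freedom.  A saturated fit (r2 = 1) yields \code{Inf}.
#'
#' @inheritParams adjustedR2
#' @export
fStatistic <- function(r2, n, k) {
    if (n <= k + 1)
        stop("domain error: need n > k + 1")
    if (r2 < 0 || r2 > 1)
        stop("domain error: r2 must lie in [0, 1]")
    if (r2 == 1)
        return(Inf)
    (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Friedman lack-of-fit score
#'
#' The parsimony-penalised error used as GFA fitness:
#' \code{LOF = SSE / (n * (1 - (c + d * p) / n)^2)}, where \code{c} is the
#' number of non-intercept basis functions, \code{p} the total number of
#' estimated parameters (\code{c + 1} for linear models with intercept) and
#' \code{d} the smoothing factor controlling model size (default 0.5).
#' Larger equations inflate the denominator penalty, so LOF resists the
#' over-fitting that plain SSE invites when descriptors outnumber compounds.
#'
#' @param sse residual sum of squares.
#' @param n number of observations.
#' @param c number of non-intercept basis functions.
#' @param p total number of estimated parameters.
#' @param d smoothing factor.
#' @export
friedmanLOF <- function(sse, n, c, p, d = 0.5) {
    if (sse < 0)
        stop("domain error: sse must be non-negative")
    pen <- (c + d * p) / n
    if (pen >= 1)
        stop("degenerate penalty: c + d*p must be smaller than n")
    sse / (n * (1 - pen)^2)
}

#' Leave-one-out cross-validated q-squared
#'
#' Each training record is predicted by the OLS model refitted to the other
#' n - 1 records; \code{q2 = 1 - PRESS / SST} with SST taken about the
#' full-sample mean (the standard QSAR convention).
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param terms descriptor names of the model.
#' @return q2 as a single number.
#' @examples
#' tab <- hdm2Table("table3")
#' looQ2(tab, descriptorNames(tab))
#' @export
looQ2 <- function(table, terms) {
    d <- .designMatrix(table, terms)
    if (d$n <= length(d$terms) + 2L)
        stop("insufficient data: need n > k + 2 for leave-one-out")
    .checkFullRank(d$X, d$terms)
    press <- .pressExplicit(d$X, d$y)
    1 - press / sum((d$y - mean(d$y))^2)
}

#' Standardized regression coefficients
#'
#' Rescales each slope by sd(descriptor)/sd(response) (n - 1 sample standard
#' deviations), putting coefficients on a common scale so their absolute
#' values rank descriptor importance.
#'
#' @param model a \linkS4class{LinearModel}.
#' @param table the \linkS4class{DescriptorTable} supplying the sample
#'   standard deviations (training subset).
#' @return named numeric vector, one entry per model term.
#' @export
standardizedCoefficients <- function(model, table) {
    stopifnot(is(model, "LinearModel"), is(table, "DescriptorTable"))
    nm <- names(model@coefficients)
    missing <- setdiff(nm, table@schema)
    if (length(missing))
        stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
    tr <- trainingSet(table)
    if (length(tr) < 2L)
        stop("insufficient data: need at least 2 training records")
    xsd <- apply(tr@descriptors[, nm, drop = FALSE], 2L, stats::sd)
    if (any(xsd == 0))
        stop("degenerate descriptor (zero variance): ",
             paste(nm[xsd == 0], collapse = ", "))
    ysd <- stats::sd(tr@pIC50Obs)
    if (ysd == 0)
        stop("degenerate response (zero variance)")
    model@coefficients * xsd / ysd
}

#' Rank descriptors by importance
#'
#' Sorts names by decreasing absolute standardized coefficient; ties are
#' broken lexicographically so the ranking is deterministic.
#'
#' @param stdCoefficients named numeric vector of standardized coefficients.
#' @return character vector of names, most important first.
#' @export
rankImportance <- function(stdCoefficients) {
    if (!length(stdCoefficients) || is.null(names(stdCoefficients)))
        stop("a non-empty named vector is required")
    nm <- names(stdCoefficients)
    nm[order(-abs(stdCoefficients), nm)]
}

#' Format the one-line statistics block of a fit
#'
#' Fixed-width summary in the conventional reporting order
#' N, LOF, R2, R2_adj, R2_cv, F; values rounded to 3 decimals for display
#' only (all statistics are stored at full precision).
#'
#' @param stats a \linkS4class{FitStats}.
#' @return a single string.
#' @export
formatStatsLine <- function(stats) {
    stopifnot(is(stats, "FitStats"))
    f3 <- function(x) if (is.na(x)) "   NA" else sprintf("%.3f", x)
    sprintf("N = %d, LOF = %s, R2 = %s, R2_adj = %s, R2_cv = %s, F = %s",
            stats@n, f3(stats@lof), f3(stats@r2), f3(stats@r2adj),
            f3(stats@q2), f3(stats@fStat))
}
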