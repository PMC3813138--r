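## Design-matrix assembly shared by OLS, PLS and LOO routines.
## Returns the intercept-augmented matrix X, response y and term names for the
## training subset of `table`, with explicit errors for every degenerate case.
.designMatrix <- function(table, terms) {
    stopifnot(is(table, "DescriptorTable"))
    terms <- as.character(terms)
    if (!length(terms))
        stop("at least one descriptor term is required")
    if (anyDuplicated(terms))
        stop("duplicate terms: ",
             paste(unique(terms[duplicated(terms)]), collapse = ", "))
    missing <- setdiff(terms, table@schema)
    if (length(missing))
        stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
    tr <- trainingSet(table)
    n <- length(tr)
    if (n == 0L)
        stop("insufficient data: table has no records with observed activity")
    X <- cbind(`(Intercept)` = 1, tr@descriptors[, terms, drop = FALSE])
    list(X = X, y = tr@pIC50Obs, ids = tr@ligandIds, terms = terms, n = n)
}

## Rank/conditioning guard: errors on rank deficiency (naming the collinear
## columns via QR pivoting) or an ill-conditioned design (relative condition
## number above 1e10).
.checkFullRank <- function(X, terms) {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        culprit <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
        stop("singular design: collinear term(s): ",
             paste(culprit, collapse = ", "))
    }
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > 1e10)
        stop("singular design: condition number exceeds 1e10 for terms: ",
             paste(terms, collapse = ", "))
    qrX
}

#' Fit an ordinary-least-squares QSAR equation
#'
#' Fits \code{pIC50 ~ intercept + terms} on the training subset (records with
#' an observed activity) and populates the full statistic suite: R-squared,
#' adjusted R-squared, F, Friedman lack-of-fit, standardized coefficients
#' and, when \code{loo = TRUE}, the leave-one-out cross-validated q-squared.
#'
#' @param table a \linkS4class{DescriptorTable}.
#' @param terms character vector of descriptor names to use as linear terms.
#' @param smoothingD Friedman LOF smoothing factor d (default 0.5).
#' @param loo compute PRESS/q2 by explicit leave-one-out refits (default
#'   \code{TRUE}).
#'
#' @return a \linkS4class{QSARFit}.
#' @examples
#' tab <- hdm2Table("table3")
#' fit <- fitOLS(tab, descriptorNames(tab))
#' fitStats(fit)
#' @export
fitOLS <- function(table, terms, smoothingD = 0.5, loo = TRUE) {
    d <- .designMatrix(table, terms)
    k <- length(d$terms)
    if (d$n <= k + 1L)
        stop(sprintf("insufficient data: n = %d training records for %d terms",
                     d$n, k))
    .checkFullRank(d$X, d$terms)
    ls <- stats::lm.fit(d$X, d$y)
    beta <- ls$coefficients
    model <- new("LinearModel", intercept = beta[[1L]],
                 coefficients = beta[-1L], provenance = "ols")
    fitted <- stats::setNames(drop(d$X %*% beta), d$ids)
    press <- if (loo) .pressExplicit(d$X, d$y) else NA_real_
    .makeFit(model, d, fitted, press, smoothingD, table@tableName)
}

## Explicit leave-one-out PRESS: refit on each n-1 subset and predict the
## held-out record.  (The hat-matrix identity is used only as a test oracle.)
.pressExplicit <- function(X, y) {
    n <- nrow(X)
    if (n <= ncol(X) + 1L)
        stop("insufficient data for leave-one-out: need n > k + 2")
    press <- 0
    for (i in seq_len(n)) {
        fit <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
        if (any(is.na(fit$coefficients)))
            stop("fold singularity leaving out record ", rownames(X)[i] %||% i)
        press <- press + (y[i] - sum(X[i, ] * fit$coefficients))^2
    }
    press
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Assemble a QSARFit from a fitted model + design bundle.
.makeFit <- function(model, d, fitted, press, smoothingD, tableName,
                     nComponents = NA_integer_) {
    y <- d$y
    n <- d$n
    k <- length(d$terms)
    sse <- sum((y - fitted)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    xsd <- apply(d$X[, -1L, drop = FALSE], 2L, stats::sd)
    ysd <- stats::sd(y)
    if (any(xsd == 0))
        stop("degenerate descriptor (zero variance): ",
             paste(d$terms[xsd == 0], collapse = ", "))
    stats <- new("FitStats",
        n = as.integer(n), k = as.integer(k),
        sse = sse, sst = sst, press = press,
        r2 = r2,
        r2adj = adjustedR2(r2, n, k),
        q2 = if (is.na(press)) NA_real_ else 1 - press / sst,
        fStat = fStatistic(r2, n, k),
        lof = friedmanLOF(sse, n, c = k, p = k + 1L, d = smoothingD),
        smoothingD = smoothingD,
        stdCoefficients = model@coefficients * xsd / ysd)
    new("QSARFit", model = model, stats = stats,
        fittedValues = fitted, terms = d$terms, tableName = tableName)
}

#' Build a LinearModel from fixed (e.g. published) coefficients
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector of descriptor coefficients.
#' @return a \linkS4class{LinearModel} with provenance \code{"fixed"}.
#' @export
fixedModel <- function(intercept, coefficients) {
    new("LinearModel", intercept = intercept,
        coefficients = coefficients, provenance = "fixed")
}

#' Evaluate a linear QSAR equation on new records
#'
#' Pure arithmetic: \code{intercept + sum(coefficient * descriptor)} for each
#' record; no refitting.  Every coefficient name must be present among the
#' record's descriptors.
#'
#' @param object a \linkS4class{LinearModel}.
#' @param newdata a \linkS4class{DescriptorTable} or a data frame / named
#'   numeric vector carrying the model's descriptor names.
#' @param ... ignored.
#' @return named numeric vector of predictions.
#' @export
setMethod("predict", "LinearModel", function(object, newdata, ...) {
    nm <- names(object@coefficients)
    if (is(newdata, "DescriptorTable")) {
        missing <- setdiff(nm, newdata@schema)
        if (length(missing))
            stop("evaluation error: record lacks descriptor(s): ",
                 paste(missing, collapse = ", "))
        X <- newdata@descriptors[, nm, drop = FALSE]
        ids <- newdata@ligandIds
    } else {
        if (is.numeric(newdata) && !is.matrix(newdata))
            newdata <- as.data.frame(as.list(newdata))
        missing <- setdiff(nm, colnames(newdata))
        if (length(missing))
            stop("evaluation error: record lacks descriptor(s): ",
                 paste(missing, collapse = ", "))
        X <- as.matrix(newdata[, nm, drop = FALSE])
        ids <- rownames(newdata)
    }
    stats::setNames(object@intercept + drop(X %*% object@coefficients),
                    ids %||% NULL)
})

#' @describeIn QSARFit predict with the fitted model (see
#'   \code{predict,LinearModel-method})
#' @param object,newdata,... as for \code{predict,LinearModel-method}.
#' @export
setMethod("predict", "QSARFit", function(object, newdata, ...) {
    predict(object@model, newdata, ...)
})

#' @describeIn QSARFit the fitted \linkS4class{LinearModel}
#' @param x a \code{QSARFit}.
#' @export
setMethod("qsarModel", "QSARFit", function(x) x@model)

#' @describeIn QSARFit the \linkS4class{FitStats}
#' @export
setMethod("fitStats", "QSARFit", function(x) x@stats)

#' @describeIn QSARFit in-sample fitted values, named by ligand id
#' @export
setMethod("fitted", "QSARFit", function(object) object@fittedValues)

#' @describeIn QSARFit intercept-first coefficient vector
#' @export
setMethod("coef", "QSARFit", function(object) {
    c(`(Intercept)` = object@model@intercept, object@model@coefficients)
})

#' @describeIn FitStats standardized coefficients stored in the statistics
#' @param x a \code{FitStats} (or \code{QSARFit}).
#' @export
setMethod("stdCoefficients", "FitStats", function(x) x@stdCoefficients)

#' @export
#' @describeIn QSARFit standardized coefficients of the fit
setMethod("stdCoefficients", "QSARFit", function(x) x@stats@stdCoefficients)

setMethod("show", "LinearModel", function(object) {
    prov <- if (object@provenance == "pls")
        sprintf("pls(%d)", object@nComponents) else object@provenance
    cat(sprintf("LinearModel [%s] with %d term(s)\n", prov,
                length(object@coefficients)))
    cat("  pIC50 =", format(object@intercept, digits = 6))
    for (nm in names(object@coefficients)) {
        b <- object@coefficients[[nm]]
        cat(sprintf(" %s %s*%s", if (b >= 0) "+" else "-",
                    format(abs(b), digits = 6), nm))
    }
    cat("\n")
})

setMethod("show", "FitStats", function(object) {
    cat(formatStatsLine(object), "\n")
})

setMethod("show", "QSARFit", function(object) {
    cat(sprintf("QSARFit on '%s'\n", object@tableName))
    show(object@model)
    cat(" ", formatStatsLine(object@stats), "\n")
})
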