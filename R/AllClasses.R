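#' DescriptorTable: a descriptor/activity table for QSAR fitting
#'
#' An ordered collection of ligand records sharing one descriptor schema:
#' an n x p numeric descriptor matrix, ligand identifiers, and (optionally)
#' observed activity on the pIC50 scale.  Rows with an observed activity form
#' the training subset; rows without one are prediction-only (e.g. newly
#' designed compounds).  Tables transcribed from published work may also carry
#' the published predicted activities and residuals, which are cross-checked
#' against the observed values at validation time.
#'
#' @slot schema ordered character vector of descriptor names.
#' @slot descriptors numeric matrix, one row per ligand, columns = schema.
#' @slot ligandIds character vector of unique ligand identifiers.
#' @slot pIC50Obs numeric vector of observed pIC50 (millimolar scale);
#'   \code{NA} marks prediction-only records.
#' @slot pIC50PredPrinted numeric vector of published predicted pIC50, or
#'   \code{NA}; used only for transcription checks and reporting.
#' @slot residualPrinted numeric vector of published residuals, or \code{NA}.
#' @slot tableName short name of the table (e.g. \code{"table2"}).
#'
#' @export
setClass("DescriptorTable",
    slots = c(
        schema = "character",
        descriptors = "matrix",
        ligandIds = "character",
        pIC50Obs = "numeric",
        pIC50PredPrinted = "numeric",
        residualPrinted = "numeric",
        tableName = "character"
    )
)

setValidity("DescriptorTable", function(object) {
    msg <- character()
    n <- length(object@ligandIds)
    if (!is.numeric(object@descriptors))
        msg <- c(msg, "descriptor matrix must be numeric")
    if (nrow(object@descriptors) != n)
        msg <- c(msg, "descriptor matrix rows must match number of ligand ids")
    if (!identical(colnames(object@descriptors), object@schema))
        msg <- c(msg, "descriptor matrix column names must equal the schema")
    if (anyDuplicated(object@schema))
        msg <- c(msg, "duplicate descriptor names in schema")
    if (anyDuplicated(object@ligandIds))
        msg <- c(msg, sprintf("duplicate ligand ids: %s",
            paste(unique(object@ligandIds[duplicated(object@ligandIds)]),
                  collapse = ", ")))
    if (anyNA(object@descriptors))
        msg <- c(msg, "missing descriptor values are not allowed")
    for (s in c("pIC50Obs", "pIC50PredPrinted", "residualPrinted"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("%s length must match number of records", s))
    if (length(object@tableName) != 1L)
        msg <- c(msg, "tableName must be a single string")
    ## transcription cross-check: obs - pred = residual to half a printed ulp
    have <- !is.na(object@pIC50Obs) & !is.na(object@pIC50PredPrinted) &
        !is.na(object@residualPrinted)
    if (any(have)) {
        dev <- abs(object@pIC50Obs[have] - object@pIC50PredPrinted[have] -
                   object@residualPrinted[have])
        if (any(dev > 0.002 + 1e-12))
            msg <- c(msg, sprintf(
                "obs - pred != residual (within 0.002) for ligand(s): %s",
                paste(object@ligandIds[have][dev > 0.002 + 1e-12],
                      collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' LinearModel: an intercept plus named descriptor coefficients
#'
#' The common currency of all fitting routes: ordinary least squares, partial
#' least squares (collapsed to its equivalent regression vector) and fixed
#' published equations.  Evaluation is pure arithmetic on any record carrying
#' every coefficient name.
#'
#' @slot intercept numeric scalar.
#' @slot coefficients named numeric vector, one entry per descriptor term.
#' @slot provenance one of \code{"ols"}, \code{"pls"}, \code{"fixed"}.
#' @slot nComponents integer; latent-variable count for PLS models,
#'   \code{NA} otherwise.
#'
#' @export
setClass("LinearModel",
    slots = c(
        intercept = "numeric",
        coefficients = "numeric",
        provenance = "character",
        nComponents = "integer"
    ),
    prototype = prototype(nComponents = NA_integer_)
)

setValidity("LinearModel", function(object) {
    msg <- character()
    if (length(object@intercept) != 1L || is.na(object@intercept))
        msg <- c(msg, "intercept must be a single non-missing number")
    if (is.null(names(object@coefficients)) ||
        anyDuplicated(names(object@coefficients)))
        msg <- c(msg, "coefficients must have unique names")
    if (!object@provenance %in% c("ols", "pls", "fixed"))
        msg <- c(msg, "provenance must be 'ols', 'pls' or 'fixed'")
    if (object@provenance == "pls" &&
        (is.na(object@nComponents) || object@nComponents < 1L))
        msg <- c(msg, "PLS models must record a positive component count")
    if (length(msg)) msg else TRUE
})

#' FitStats: the statistic suite for one fitted QSAR equation
#'
#' Carries sums of squares and every derived statistic used to judge a model:
#' R-squared, adjusted R-squared, the overall F statistic, Friedman
#' lack-of-fit, leave-one-out q-squared (when computed) and standardized
#' coefficients for descriptor-importance ranking.
#'
#' @slot n number of training records.
#' @slot k number of non-intercept terms.
#' @slot sse,sst residual and total sums of squares.
#' @slot press leave-one-out predicted residual sum of squares (\code{NA}
#'   unless cross-validation was run).
#' @slot r2,r2adj,q2 coefficient of determination, its adjusted form, and the
#'   LOO cross-validated form 1 - PRESS/SST.
#' @slot fStat overall F statistic on (k, n - k - 1) degrees of freedom.
#' @slot lof Friedman lack-of-fit at smoothing factor \code{smoothingD}.
#' @slot smoothingD smoothing factor d used in the LOF penalty.
#' @slot stdCoefficients named numeric vector of standardized coefficients.
#'
#' @export
setClass("FitStats",
    slots = c(
        n = "integer", k = "integer",
        sse = "numeric", sst = "numeric", press = "numeric",
        r2 = "numeric", r2adj = "numeric", q2 = "numeric",
        fStat = "numeric", lof = "numeric", smoothingD = "numeric",
        stdCoefficients = "numeric"
    )
)

setValidity("FitStats", function(object) {
    msg <- character()
    if (object@sse < -1e-8 || object@sst < 0)
        msg <- c(msg, "sums of squares must be non-negative")
    if (!is.na(object@press) && object@press < 0)
        msg <- c(msg, "PRESS must be non-negative")
    if (object@lof < 0)
        msg <- c(msg, "LOF must be non-negative")
    if (length(msg)) msg else TRUE
})

#' QSARFit: a fitted model together with its statistics and fitted values
#'
#' @slot model the \linkS4class{LinearModel}.
#' @slot stats the \linkS4class{FitStats}.
#' @slot fittedValues named numeric vector of in-sample predictions for the
#'   training subset.
#' @slot terms descriptor terms of the model, in fitting order.
#' @slot tableName name of the table the model was fitted on.
#'
#' @export
setClass("QSARFit",
    slots = c(
        model = "LinearModel",
        stats = "FitStats",
        fittedValues = "numeric",
        terms = "character",
        tableName = "character"
    )
)

#' GFAConfig: hyperparameters of the genetic function approximation search
#'
#' @slot populationSize number of candidate equations per generation.
#' @slot smoothingD Friedman LOF smoothing factor d.
#' @slot minTerms,maxTerms bounds on equation size (non-intercept terms).
#' @slot generationsMax hard cap on generations.
#' @slot crossoverRate,mutationRate per-offspring operator probabilities.
#' @slot fittingMode \code{"ols"} or \code{"pls"} (G/PLS).
#' @slot plsComponents latent-variable count for G/PLS individuals (capped at
#'   the equation size).
#' @slot seed integer seed; the whole run is reproducible from it.
#' @slot convergenceWindow number of consecutive generations with an
#'   unchanged descriptor-usage histogram that triggers termination.
#'
#' @export
setClass("GFAConfig",
    slots = c(
        populationSize = "integer", smoothingD = "numeric",
        minTerms = "integer", maxTerms = "integer",
        generationsMax = "integer",
        crossoverRate = "numeric", mutationRate = "numeric",
        fittingMode = "character", plsComponents = "integer",
        seed = "integer", convergenceWindow = "integer"
    )
)

setValidity("GFAConfig", function(object) {
    msg <- character()
    if (object@populationSize < 2L)
        msg <- c(msg, "populationSize must be at least 2")
    if (object@minTerms < 1L || object@minTerms > object@maxTerms)
        msg <- c(msg, "need 1 <= minTerms <= maxTerms")
    if (object@crossoverRate < 0 || object@crossoverRate > 1 ||
        object@mutationRate < 0 || object@mutationRate > 1)
        msg <- c(msg, "rates must lie in [0, 1]")
    if (!object@fittingMode %in% c("ols", "pls"))
        msg <- c(msg, "fittingMode must be 'ols' or 'pls'")
    if (object@smoothingD < 0)
        msg <- c(msg, "smoothingD must be non-negative")
    if (object@generationsMax < 1L || object@convergenceWindow < 1L)
        msg <- c(msg, "generationsMax and convergenceWindow must be positive")
    if (length(msg)) msg else TRUE
})

#' GFAIndividual: one candidate equation in the GFA population
#'
#' @slot termSet descriptor subset (ordered, no duplicates).
#' @slot model fitted \linkS4class{LinearModel} for the subset.
#' @slot stats \linkS4class{FitStats} of the fit.
#' @slot fitness Friedman LOF of the fit (lower is better; \code{Inf} for
#'   singular candidates).
#'
#' @export
setClass("GFAIndividual",
    slots = c(
        termSet = "character",
        model = "LinearModel",
        stats = "FitStats",
        fitness = "numeric"
    )
)

#' GFAResult: the final ranked population of a GFA run
#'
#' @slot individuals list of \linkS4class{GFAIndividual}, sorted by ascending
#'   lack-of-fit (ties: fewer terms, then lexicographic term names).
#' @slot config the \linkS4class{GFAConfig} of the run.
#' @slot log per-generation data frame: best and median LOF and a hash of the
#'   descriptor-usage histogram.
#' @slot generations number of generations actually run.
#' @slot converged whether the usage histogram stabilised before the cap.
#'
#' @export
setClass("GFAResult",
    slots = c(
        individuals = "list",
        config = "GFAConfig",
        log = "data.frame",
        generations = "integer",
        converged = "logical"
    )
)

#' SyntheticSpec: parameters of the synthetic descriptor-table generator
#'
#' Descriptors are drawn from a zero-mean Gaussian with block-exchangeable
#' correlation (a common within-block correlation, zero across blocks); the
#' response is a sparse linear signal plus Gaussian noise.
#'
#' @slot nSamples,nDescriptors table dimensions.
#' @slot blockSizes sizes of the correlated blocks (must sum to
#'   \code{nDescriptors}).
#' @slot withinBlockCorr common correlation within a block, in [0, 1).
#' @slot activeTerms indices of the truly active descriptors.
#' @slot trueCoefficients coefficients of the active descriptors.
#' @slot trueIntercept intercept of the true model.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot seed integer seed.
#'
#' @export
setClass("SyntheticSpec",
    slots = c(
        nSamples = "integer", nDescriptors = "integer",
        blockSizes = "integer", withinBlockCorr = "numeric",
        activeTerms = "integer", trueCoefficients = "numeric",
        trueIntercept = "numeric", noiseSd = "numeric", seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (sum(object@blockSizes) != object@nDescriptors)
        msg <- c(msg, "blockSizes must sum to nDescriptors")
    if (any(object@blockSizes < 1L))
        msg <- c(msg, "block sizes must be positive")
    if (object@withinBlockCorr < 0 || object@withinBlockCorr >= 1)
        msg <- c(msg,
            "withinBlockCorr must lie in [0, 1) (positive definiteness)")
    if (anyDuplicated(object@activeTerms) ||
        any(object@activeTerms < 1L) ||
        any(object@activeTerms > object@nDescriptors))
        msg <- c(msg, "activeTerms must be distinct indices in range")
    if (length(object@trueCoefficients) != length(object@activeTerms))
        msg <- c(msg, "one true coefficient per active term required")
    if (object@noiseSd < 0)
        msg <- c(msg, "noiseSd must be non-negative")
    if (object@nSamples < 3L)
        msg <- c(msg, "nSamples must be at least 3")
    if (length(msg)) msg else TRUE
})

#' SyntheticTruth: the realized ground truth of a generated table
#'
#' @slot spec the generating \linkS4class{SyntheticSpec}.
#' @slot design the realized n x p descriptor matrix.
#' @slot response the realized response vector.
#' @slot attainableR2 variance of the realized signal over variance of signal
#'   plus noise variance: the R-squared an oracle knowing the true terms can
#'   expect on this sample.
#'
#' @export
setClass("SyntheticTruth",
    slots = c(
        spec = "SyntheticSpec",
        design = "matrix",
        response = "numeric",
        attainableR2 = "numeric"
    )
)
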