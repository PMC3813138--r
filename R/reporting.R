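## Resolve a table argument that may be a path or a DescriptorTable.
.resolveTable <- function(table, schema = NULL) {
    if (is(table, "DescriptorTable"))
        return(list(table = table, checksum = NA_character_))
    list(table = readDescriptorTable(table, schema = schema),
         checksum = unname(tools::md5sum(table)))
}

#' Fit a QSAR equation and write a model report
#'
#' Runs \code{\link{fitOLS}} (or \code{\link{fitPLS}}) on the given table and
#' terms and writes three files to \code{outDir}: \code{<prefix>.json} (the
#' full report: coefficients, statistics, standardized coefficients,
#' importance ranking, per-ligand observed/predicted/residual table and the
#' input checksum when the table came from a file), \code{<prefix>.txt} (the
#' one-line statistics block) and \code{<prefix>_predictions.csv}
#' (per-ligand table, 3-decimal presentation).
#'
#' @param table a \linkS4class{DescriptorTable} or CSV path.
#' @param terms descriptor names; default: the table's full schema.
#' @param mode \code{"ols"} or \code{"pls"}.
#' @param nComponents PLS component count (mode \code{"pls"}).
#' @param smoothingD Friedman LOF smoothing factor.
#' @param loo whether to run leave-one-out cross-validation.
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the \linkS4class{QSARFit}, invisibly; the report paths are in
#'   \code{attr(, "files")}.
#' @export
runFit <- function(table, terms = NULL, mode = c("ols", "pls"),
                   nComponents = 4L, smoothingD = 0.5, loo = TRUE,
                   outDir = ".", prefix = "fit") {
    mode <- match.arg(mode)
    res <- .resolveTable(table)
    tab <- res$table
    if (is.null(terms))
        terms <- descriptorNames(tab)
    fit <- if (mode == "ols")
        fitOLS(tab, terms, smoothingD = smoothingD, loo = loo)
    else
        fitPLS(tab, terms, nComponents = min(nComponents, length(terms)),
               smoothingD = smoothingD, loo = loo)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    st <- fit@stats
    obs <- unname(activityValues(trainingSet(tab)))
    perLigand <- data.frame(
        ligand_id = names(fit@fittedValues),
        pIC50_obs = obs,
        pIC50_pred = round(unname(fit@fittedValues), 3),
        residual = round(obs - unname(fit@fittedValues), 3),
        stringsAsFactors = FALSE, row.names = NULL)
    report <- list(
        table = tab@tableName,
        input_md5 = res$checksum,
        mode = mode,
        terms = fit@terms,
        intercept = fit@model@intercept,
        coefficients = as.list(fit@model@coefficients),
        n_components = if (mode == "pls") fit@model@nComponents else NULL,
        stats = list(n = st@n, k = st@k, sse = st@sse, sst = st@sst,
                     press = st@press, r2 = st@r2, r2_adj = st@r2adj,
                     q2 = st@q2, f = st@fStat, lof = st@lof,
                     smoothing_d = st@smoothingD),
        std_coefficients = as.list(st@stdCoefficients),
        importance = rankImportance(st@stdCoefficients),
        per_ligand = perLigand)
    files <- file.path(outDir, paste0(prefix,
        c(".json", ".txt", "_predictions.csv")))
    jsonlite::write_json(report, files[1], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "rows")
    writeLines(formatStatsLine(st), files[2])
    utils::write.csv(perLigand, files[3], row.names = FALSE, quote = FALSE)
    attr(fit, "files") <- files
    invisible(fit)
}

#' Predict activities for new compounds and write them to CSV
#'
#' @param model a \linkS4class{LinearModel} or \linkS4class{QSARFit}.
#' @param newdata a \linkS4class{DescriptorTable} or CSV path; every model
#'   term must be present in its schema.
#' @param outFile output CSV path (\code{ligand_id, pIC50_pred}; 3 decimals).
#' @return data frame of predictions, invisibly.
#' @export
runPredict <- function(model, newdata, outFile) {
    if (is(model, "QSARFit"))
        model <- model@model
    res <- .resolveTable(newdata)
    tab <- res$table
    out <- if (length(tab) == 0L)
        data.frame(ligand_id = character(0), pIC50_pred = numeric(0))
    else
        data.frame(ligand_id = ligandIds(tab),
                   pIC50_pred = round(unname(predict(model, tab)), 3),
                   stringsAsFactors = FALSE)
    utils::write.csv(out, outFile, row.names = FALSE, quote = FALSE)
    invisible(out)
}

#' Run a GFA search and write the ranked equations and search log
#'
#' Writes \code{<prefix>_equations.csv} (top \code{topN} equations with term
#' sets, LOF, R2, adjusted R2, F and, for OLS fits, LOO q2) and
#' \code{<prefix>_log.txt} (one line per generation).  Byte-identical across
#' runs with the same config and inputs.
#'
#' @param table a \linkS4class{DescriptorTable} or CSV path.
#' @param config a \linkS4class{GFAConfig}.
#' @param pool descriptor pool (default: full schema).
#' @param topN number of ranked equations to report (default 10).
#' @param outDir,prefix output location.
#' @return the \linkS4class{GFAResult}, invisibly.
#' @export
runGFA <- function(table, config = gfaConfig(), pool = NULL, topN = 10L,
                   outDir = ".", prefix = "gfa") {
    res <- .resolveTable(table)
    tab <- res$table
    if (is.null(pool))
        pool <- descriptorNames(tab)
    result <- gfaSearch(tab, config, pool = pool)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    df <- as.data.frame(result)
    df <- df[seq_len(min(topN, nrow(df))), , drop = FALSE]
    if (config@fittingMode == "ols")
        df$q2 <- vapply(df$rank, function(i)
            looQ2(tab, result@individuals[[i]]@termSet), numeric(1))
    for (col in c("lof", "r2", "r2adj", "fStat", "q2"))
        if (col %in% names(df)) df[[col]] <- round(df[[col]], 6)
    files <- file.path(outDir, paste0(prefix, c("_equations.csv", "_log.txt")))
    utils::write.csv(df, files[1], row.names = FALSE, quote = FALSE)
    writeLines(c(sprintf("input_md5=%s seed=%d", res$checksum, config@seed),
                 sprintf("%s: best=%.6g median=%.6g usage=%s",
                         paste0("generation ", result@log$generation),
                         result@log$bestLOF, result@log$medianLOF,
                         result@log$usageHash)),
               files[2])
    attr(result, "files") <- files
    invisible(result)
}

#' Generate a synthetic table and write it with its truth sidecar
#'
#' Writes \code{<prefix>.csv} in the package CSV dialect and
#' \code{<prefix>_truth.json} describing the generating parameters and the
#' realized attainable R-squared.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param outPrefix path prefix for the two files.
#' @return the \code{generateTable} result, invisibly.
#' @export
runSimulate <- function(spec, outPrefix) {
    out <- generateTable(spec)
    writeDescriptorTable(out$table, paste0(outPrefix, ".csv"))
    truth <- list(
        n_samples = spec@nSamples, n_descriptors = spec@nDescriptors,
        block_sizes = spec@blockSizes,
        within_block_corr = spec@withinBlockCorr,
        active_terms = sprintf("D%03d", spec@activeTerms),
        true_coefficients = spec@trueCoefficients,
        true_intercept = spec@trueIntercept,
        noise_sd = spec@noiseSd, seed = spec@seed,
        attainable_r2 = out$truth@attainableR2)
    jsonlite::write_json(truth, paste0(outPrefix, "_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out)
}
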