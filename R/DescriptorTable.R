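#' Construct a DescriptorTable
#'
#' @param descriptors numeric matrix or data frame of descriptor values
#'   (one row per ligand; column names are the schema).
#' @param ligandIds character vector of unique ligand identifiers; defaults
#'   to row numbers.
#' @param pIC50Obs observed activities on the pIC50 scale; \code{NA} for
#'   prediction-only records.
#' @param pIC50PredPrinted,residualPrinted previously published predicted
#'   activities and residuals (transcribed values), if any.
#' @param name short table name.
#'
#' @return a validated \linkS4class{DescriptorTable}.
#' @export
DescriptorTable <- function(descriptors, ligandIds = NULL, pIC50Obs = NULL,
                            pIC50PredPrinted = NULL, residualPrinted = NULL,
                            name = "table") {
    m <- as.matrix(descriptors)
    storage.mode(m) <- "double"
    n <- nrow(m)
    if (is.null(ligandIds))
        ligandIds <- as.character(seq_len(n))
    fill <- function(x) if (is.null(x)) rep(NA_real_, n) else as.numeric(x)
    rownames(m) <- as.character(ligandIds)
    new("DescriptorTable",
        schema = colnames(m),
        descriptors = m,
        ligandIds = as.character(ligandIds),
        pIC50Obs = fill(pIC50Obs),
        pIC50PredPrinted = fill(pIC50PredPrinted),
        residualPrinted = fill(residualPrinted),
        tableName = name)
}

## reserved (non-descriptor) column names in the CSV dialect
.reservedCols <- c("ligand_id", "pIC50_obs", "pIC50_pred", "residual")

#' Read a descriptor/activity table from CSV
#'
#' The CSV dialect has one header row, a \code{ligand_id} column (kept as
#' character so identifiers like \code{"I"} survive), any number of numeric
#' descriptor columns, and optional \code{pIC50_obs}, \code{pIC50_pred} and
#' \code{residual} columns.  Empty activity cells mean "absent" (a
#' prediction-only record), never zero.
#'
#' @param path CSV file path.
#' @param name table name; defaults to the file name without extension.
#' @param schema optional character vector; when given, the file's descriptor
#'   columns must match it exactly (an error names any missing column).
#'
#' @return a validated \linkS4class{DescriptorTable}; records keep file order.
#' @export
readDescriptorTable <- function(path, name = NULL, schema = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
    if (!"ligand_id" %in% names(df))
        stop("schema error: missing column 'ligand_id' in ", path)
    descCols <- setdiff(names(df), .reservedCols)
    if (!is.null(schema)) {
        missing <- setdiff(schema, descCols)
        if (length(missing))
            stop("schema error: missing descriptor column(s): ",
                 paste(missing, collapse = ", "))
        extra <- setdiff(descCols, schema)
        if (length(extra))
            stop("schema error: unexpected descriptor column(s): ",
                 paste(extra, collapse = ", "))
        descCols <- schema
    }
    parseNum <- function(col, required) {
        x <- df[[col]]
        x[x == ""] <- NA
        out <- suppressWarnings(as.numeric(x))
        bad <- which(!is.na(x) & is.na(out))
        if (length(bad))
            stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                         x[bad[1]], bad[1], col))
        if (required && anyNA(out))
            stop(sprintf("parse error: missing descriptor value at row %d, column '%s'",
                         which(is.na(out))[1], col))
        out
    }
    desc <- vapply(descCols, parseNum, numeric(nrow(df)), required = TRUE)
    if (nrow(df) == 1L) desc <- matrix(desc, nrow = 1L,
                                       dimnames = list(NULL, descCols))
    opt <- function(col) if (col %in% names(df)) parseNum(col, FALSE) else NULL
    DescriptorTable(desc,
        ligandIds = df$ligand_id,
        pIC50Obs = opt("pIC50_obs"),
        pIC50PredPrinted = opt("pIC50_pred"),
        residualPrinted = opt("residual"),
        name = name)
}

#' Write a descriptor table in the package CSV dialect
#'
#' Round-trips with \code{\link{readDescriptorTable}} field for field; absent
#' activities are written as empty cells.
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeDescriptorTable <- function(x, path) {
    stopifnot(is(x, "DescriptorTable"))
    df <- data.frame(ligand_id = x@ligandIds, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(x@descriptors, check.names = FALSE))
    df$pIC50_obs <- x@pIC50Obs
    df$pIC50_pred <- x@pIC50PredPrinted
    df$residual <- x@residualPrinted
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' @describeIn DescriptorTable descriptor schema (ordered names)
#' @param x a \code{DescriptorTable}.
#' @export
setMethod("descriptorNames", "DescriptorTable", function(x) x@schema)

#' @describeIn DescriptorTable ligand identifiers
#' @export
setMethod("ligandIds", "DescriptorTable", function(x) x@ligandIds)

#' @describeIn DescriptorTable the n x p numeric descriptor matrix
#' @export
setMethod("descriptorMatrix", "DescriptorTable", function(x) x@descriptors)

#' @describeIn DescriptorTable observed pIC50 values (NA = prediction-only)
#' @export
setMethod("activityValues", "DescriptorTable", function(x) {
    stats::setNames(x@pIC50Obs, x@ligandIds)
})

#' @describeIn DescriptorTable published predicted pIC50, if transcribed
#' @export
setMethod("predictedPrinted", "DescriptorTable", function(x) {
    stats::setNames(x@pIC50PredPrinted, x@ligandIds)
})

#' @describeIn DescriptorTable published residuals, if transcribed
#' @export
setMethod("residualPrinted", "DescriptorTable", function(x) {
    stats::setNames(x@residualPrinted, x@ligandIds)
})

#' @describeIn DescriptorTable table name
#' @export
setMethod("tableName", "DescriptorTable", function(x) x@tableName)

#' @describeIn DescriptorTable subset to records with an observed activity
#' @export
setMethod("trainingSet", "DescriptorTable", function(x) {
    x[!is.na(x@pIC50Obs)]
})

#' @describeIn DescriptorTable number of records with an observed activity
#' @export
setMethod("nTraining", "DescriptorTable", function(x) sum(!is.na(x@pIC50Obs)))

#' Subset a DescriptorTable by record
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param i logical, integer or character (ligand id) index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@ligandIds)
    initialize(x,
        descriptors = x@descriptors[i, , drop = FALSE],
        ligandIds = x@ligandIds[i],
        pIC50Obs = x@pIC50Obs[i],
        pIC50PredPrinted = x@pIC50PredPrinted[i],
        residualPrinted = x@residualPrinted[i])
})

#' @describeIn DescriptorTable number of records
#' @export
setMethod("length", "DescriptorTable", function(x) length(x@ligandIds))

#' Coerce a DescriptorTable to a data.frame in the CSV column layout
#'
#' @param x a \linkS4class{DescriptorTable}.
#' @param row.names,optional,... passed through for S3 compatibility; unused.
#' @export
as.data.frame.DescriptorTable <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    df <- data.frame(ligand_id = x@ligandIds, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(x@descriptors, check.names = FALSE,
                                  row.names = NULL))
    df$pIC50_obs <- x@pIC50Obs
    df$pIC50_pred <- x@pIC50PredPrinted
    df$residual <- x@residualPrinted
    rownames(df) <- NULL
    df
}

setMethod("show", "DescriptorTable", function(object) {
    cat(sprintf("DescriptorTable '%s': %d record(s) (%d training, %d prediction-only)\n",
        object@tableName, length(object@ligandIds),
        sum(!is.na(object@pIC50Obs)), sum(is.na(object@pIC50Obs))))
    cat(sprintf("  %d descriptor(s): %s\n", length(object@schema),
        paste(utils::head(object@schema, 6), collapse = ", ")))
    if (length(object@schema) > 6) cat("  ...\n")
})
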