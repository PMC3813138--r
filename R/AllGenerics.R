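#' @import methods
NULL

#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))

#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' @export
setGeneric("predictedPrinted", function(x) standardGeneric("predictedPrinted"))

#' @export
setGeneric("residualPrinted", function(x) standardGeneric("residualPrinted"))

#' @export
setGeneric("tableName", function(x) standardGeneric("tableName"))

#' @export
setGeneric("trainingSet", function(x) standardGeneric("trainingSet"))

#' @export
setGeneric("nTraining", function(x) standardGeneric("nTraining"))

#' @export
setGeneric("qsarModel", function(x) standardGeneric("qsarModel"))

#' @export
setGeneric("fitStats", function(x) standardGeneric("fitStats"))

#' @export
setGeneric("stdCoefficients", function(x) standardGeneric("stdCoefficients"))

#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @export
setGeneric("topModel", function(x) standardGeneric("topModel"))

#' @export
setGeneric("searchLog", function(x) standardGeneric("searchLog"))
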