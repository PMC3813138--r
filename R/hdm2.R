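## Descriptor schemas of the two packaged HDM2 panels
.table2Schema <- c("LogD", "Num_RotatableBonds", "Num_StereoAtoms",
                   "V_DIST_equ", "CHI_1", "Dipole_X", "Shadow_Xlength",
                   "Shadow_XZ")
.table3Schema <- c("IDE", "MATS7v", "DP09", "Mor14m", "Mor30p", "G2e",
                   "E2e", "Tp", "R5u", "BELp6", "SeaC2C3aa")

#' Load a packaged HDM2 benzodiazepinedione descriptor table
#'
#' Two published descriptor/activity panels for the same 59
#' 1,4-benzodiazepine-2,5-dione HDM2 antagonists (activities from
#' fluorescence-polarization IC50, converted to pIC50 on the millimolar
#' scale) are shipped as plain CSV:
#' \describe{
#'   \item{\code{"table2"}}{8 DS-style 2D/3D descriptors (LogD, rotatable
#'     bonds, stereo atoms, topological indices, dipole and shadow indices);
#'     59 training records.}
#'   \item{\code{"table3"}}{11 Dragon-style descriptors (information and
#'     autocorrelation indices, 3D-MoRSE, WHIM, getaway and BCUT terms plus
#'     an atom-pair count printed under the canonical name
#'     \code{SeaC2C3aa}); 59 training records plus two prediction-only rows
#'     \code{"I"} and \code{"II"}, the newly designed compounds.}
#' }
#' Both tables also carry the originally published predicted activities and
#' residuals, which are cross-checked (obs - pred = residual to within
#' 0.002) at load time.
#'
#' @param name \code{"table2"} or \code{"table3"}.
#' @return a validated \linkS4class{DescriptorTable}.
#' @examples
#' hdm2Table("table3")
#' @export
hdm2Table <- function(name = c("table2", "table3")) {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".csv"), package = "qsarGFA",
                        mustWork = TRUE)
    schema <- if (name == "table2") .table2Schema else .table3Schema
    readDescriptorTable(path, name = name, schema = schema)
}

#' The published HDM2 QSAR equations as fixed models
#'
#' Returns the published regression equation for either descriptor panel as
#' a \linkS4class{LinearModel} with provenance \code{"fixed"}, exactly as
#' printed:
#' \describe{
#'   \item{\code{"ds"}}{the 8-descriptor equation on the \code{"table2"}
#'     panel (a GFA selection refined by G/PLS).}
#'   \item{\code{"dragon"}}{the 11-descriptor equation on the
#'     \code{"table3"} panel.  Note: the published \code{BELp6} coefficient
#'     (-61.64) is inconsistent with the published fitted values (refitting
#'     from the data gives about -6.29 with all other coefficients matching
#'     to print precision), so for any quantitative use prefer
#'     \code{fitOLS(hdm2Table("table3"), descriptorNames(...))}, which is
#'     the reference form of this model.}
#' }
#'
#' @param which \code{"ds"} or \code{"dragon"}.
#' @return a \linkS4class{LinearModel}.
#' @examples
#' predict(hdm2Equation("ds"), hdm2Table("table2")["25"])
#' @export
hdm2Equation <- function(which = c("ds", "dragon")) {
    which <- match.arg(which)
    if (which == "ds")
        fixedModel(14.568, c(
            LogD = 0.388, Num_RotatableBonds = -0.166,
            Num_StereoAtoms = -0.670, V_DIST_equ = 0.00278,
            CHI_1 = -1.446, Dipole_X = -0.0471,
            Shadow_Xlength = 0.230, Shadow_XZ = -0.0328))
    else
        fixedModel(-12.276, c(
            IDE = 7.858, MATS7v = -4.855, DP09 = -1.198,
            Mor14m = -0.448, Mor30p = 1.481, G2e = -25.917,
            E2e = 1.678, Tp = 0.319, R5u = 61.575,
            BELp6 = -61.64, SeaC2C3aa = 0.272))
}
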