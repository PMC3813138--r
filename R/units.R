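#' Convert IC50 in micromolar to pIC50 on the millimolar scale
#'
#' Inhibitory potencies measured as IC50 in micromolar are converted to the
#' negative decadic logarithm of the concentration expressed in millimolar:
#' \code{pIC50 = -log10(IC50 / 1000) = 3 - log10(IC50_uM)}.  On this scale
#' 1000 uM (1 mM) maps to 0 and 1 uM maps to 3; more potent compounds get
#' larger values.
#'
#' @param ic50_uM positive IC50 value(s) in micromolar.
#' @return pIC50 value(s), millimolar scale.
#' @examples
#' ic50ToPIC50(1000)  # 0
#' ic50ToPIC50(0.42)  # 3.377
#' @export
ic50ToPIC50 <- function(ic50_uM) {
    if (!is.numeric(ic50_uM) || any(!is.finite(ic50_uM)) || any(ic50_uM <= 0))
        stop("domain error: IC50 must be positive and finite")
    3 - log10(ic50_uM)
}

#' Invert \code{\link{ic50ToPIC50}}
#'
#' @param pIC50 pIC50 value(s) on the millimolar scale.
#' @return IC50 in micromolar.
#' @export
pIC50ToIC50 <- function(pIC50) {
    if (!is.numeric(pIC50) || any(!is.finite(pIC50)))
        stop("domain error: pIC50 must be finite")
    10^(3 - pIC50)
}
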