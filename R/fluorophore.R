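#' Standard tfLC3 fluorophore models
#'
#' `egfpModel()` is pH-sensitive with its titration midpoint at pH 6.0, the
#' point below which eGFP emission is effectively quenched; `mrfpModel()` is
#' pH-resistant (constant emission).
#'
#' @param pHhalf titration midpoint, pH units.
#' @param hill cooperativity of the titration.
#' @param brightness relative brightness.
#' @return a [FluorophoreModel].
#' @export
egfpModel <- function(pHhalf = 6.0, hill = 1.0, brightness = 1.0) {
  new("FluorophoreModel", name = "eGFP", pHhalf = pHhalf, hill = hill,
      brightness = brightness, pHsensitive = TRUE)
}

#' @rdname egfpModel
#' @export
mrfpModel <- function(brightness = 1.0) {
  new("FluorophoreModel", name = "mRFP", pHhalf = NA_real_, hill = 1.0,
      brightness = brightness, pHsensitive = FALSE)
}

#' Emission fraction of a fluorophore at a given luminal pH
#'
#' For a pH-sensitive fluorophore the emitted fraction follows the logistic
#' (Henderson-Hasselbalch) titration
#' \deqn{f(pH) = 1 / (1 + 10^{h (pH_{1/2} - pH)})}
#' which is strictly increasing in pH, 0.5 at the midpoint, and saturates at
#' 0 and 1. pH-resistant fluorophores return 1 for every pH.
#'
#' @param pH luminal pH (vectorized).
#' @param model a [FluorophoreModel]; default the standard eGFP model.
#' @return emission fraction(s) in `[0, 1]`.
#' @export
egfpQuenchFactor <- function(pH, model = egfpModel()) {
  if (any(!is.finite(pH))) stop("pH must be finite")
  if (!model@pHsensitive) return(rep(1.0, length(pH)))
  1 / (1 + 10^(model@hill * (model@pHhalf - pH)))
}
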