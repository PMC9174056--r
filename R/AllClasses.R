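#' Multi-channel 2D fluorescence image
#'
#' `ChannelStack` is the container every pipeline stage consumes: a numeric
#' `ny x nx x nc` array of background-inclusive intensities (arbitrary units,
#' full scale ~1), named channels, and the pixel size in micrometres. Row
#' index is y (down), column index is x (right).
#'
#' @slot data numeric array `ny x nx x nc`.
#' @slot channels character vector of channel names (e.g. `"mRFP"`, `"eGFP"`,
#'   `"CTSD"`, `"Abeta"`, `"PLA"`, `"DAPI"`, `"ThioS"`, `"GFAP"`, `"IbaI"`).
#' @slot pixelSize physical size of one pixel in micrometres.
#' @export
setClass("ChannelStack",
  representation(data = "array", channels = "character", pixelSize = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3) return("data must be a 3D array (y, x, channel)")
    if (d[3] != length(object@channels)) {
      return("number of channels must match dim(data)[3]")
    }
    if (anyDuplicated(object@channels)) return("channel names must be unique")
    if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) {
      return("pixelSize must be a single positive number")
    }
    TRUE
  }
)

#' Synthetic field with ground truth
#'
#' A [ChannelStack] rendered by the simulator, carrying the ground truth the
#' closed-loop tests compare against: the per-vesicle table, per-neuron table,
#' a neuron label image and a PANTHOS lesion label image.
#'
#' @slot vesicles data.frame with one row per ground-truth vesicle
#'   (id, neuron_id, class, pH, x_um, y_um, radius_um, lc3_load, marker_ctsd,
#'   abeta_positive, pla_positive).
#' @slot neurons data.frame with one row per neuron (neuron_id, x_um, y_um,
#'   soma_radius_um, nucleus_radius_um, panthos_stage, n_blebs, dapi_state,
#'   and marker co-label flags).
#' @slot neuronLabels integer matrix, 0 = background.
#' @slot lesionLabels integer matrix of ground-truth PANTHOS lesion ids.
#' @slot seed integer seed the field was rendered with.
#' @slot preset name of the generating preset.
#' @export
setClass("SimulatedField",
  contains = "ChannelStack",
  representation(vesicles = "data.frame", neurons = "data.frame",
                 neuronLabels = "matrix", lesionLabels = "matrix",
                 seed = "integer", preset = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (!identical(dim(object@neuronLabels), d[1:2])) {
      return("neuronLabels must match image shape")
    }
    if (!identical(dim(object@lesionLabels), d[1:2])) {
      return("lesionLabels must match image shape")
    }
    TRUE
  }
)

#' pH-dependent fluorophore emission model
#'
#' Emission fraction follows a Henderson-Hasselbalch (logistic) titration in
#' pH for pH-sensitive fluorophores (eGFP), and is constant 1 for
#' pH-resistant ones (mRFP).
#'
#' @slot name fluorophore label.
#' @slot pHhalf titration midpoint (pH units).
#' @slot hill cooperativity (dimensionless).
#' @slot brightness relative brightness (arbitrary units).
#' @slot pHsensitive logical.
#' @export
setClass("FluorophoreModel",
  representation(name = "character", pHhalf = "numeric", hill = "numeric",
                 brightness = "numeric", pHsensitive = "logical"),
  prototype(name = "eGFP", pHhalf = 6.0, hill = 1.0, brightness = 1.0,
            pHsensitive = TRUE),
  validity = function(object) {
    if (object@hill <= 0) return("hill must be positive")
    if (object@brightness < 0) return("brightness must be non-negative")
    TRUE
  }
)
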