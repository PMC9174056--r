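#' @rdname ChannelStack-class
#' @param object,x a [ChannelStack].
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ChannelStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ChannelStack-class
#' @param channel channel name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname SimulatedField-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SimulatedField-class
#' @export
setGeneric("neuronLabels", function(x) standardGeneric("neuronLabels"))

#' @rdname SimulatedField-class
#' @export
setGeneric("lesionLabels", function(x) standardGeneric("lesionLabels"))

#' @rdname ChannelStack-class
#' @export
setMethod("channelNames", "ChannelStack", function(x) x@channels)

#' @rdname ChannelStack-class
#' @export
setMethod("pixelSize", "ChannelStack", function(x) x@pixelSize)

#' @rdname ChannelStack-class
#' @export
setMethod("getChannel", "ChannelStack", function(x, channel) {
  i <- match(channel, x@channels)
  if (is.na(i)) {
    stop("channel '", channel, "' not present; available: ",
         paste(x@channels, collapse = ", "))
  }
  x@data[, , i]
})

#' @rdname ChannelStack-class
#' @export
setMethod("dim", "ChannelStack", function(x) dim(x@data))

setMethod("show", "ChannelStack", function(object) {
  d <- dim(object@data)
  cat("ChannelStack:", d[1], "x", d[2], "px,", d[3], "channel(s)\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  pixel size:", object@pixelSize, "um  (",
      round(d[2] * object@pixelSize, 1), "x",
      round(d[1] * object@pixelSize, 1), "um )\n")
})

#' @rdname SimulatedField-class
#' @param x,object a [SimulatedField].
#' @export
setMethod("groundTruth", "SimulatedField", function(x) x@vesicles)

#' @rdname SimulatedField-class
#' @export
setMethod("neuronLabels", "SimulatedField", function(x) x@neuronLabels)

#' @rdname SimulatedField-class
#' @export
setMethod("lesionLabels", "SimulatedField", function(x) x@lesionLabels)

setMethod("show", "SimulatedField", function(object) {
  callNextMethod()
  cat("  preset:", object@preset, " seed:", object@seed, "\n")
  cat("  ground truth:", nrow(object@neurons), "neuron(s),",
      nrow(object@vesicles), "vesicle(s),",
      max(object@lesionLabels), "lesion(s)\n")
})

setMethod("show", "FluorophoreModel", function(object) {
  cat("FluorophoreModel", object@name,
      if (object@pHsensitive) {
        sprintf("(pH-sensitive, pH1/2 = %.2f, hill = %.2f)",
                object@pHhalf, object@hill)
      } else "(pH-resistant)", "\n")
})
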