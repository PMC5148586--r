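#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes. Use these instead of
#' direct slot access.
#'
#' @param object an object of one of the package's classes
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("modes", function(object) standardGeneric("modes"))
#' @rdname accessors
#' @export
setGeneric("residualSignal", function(object) standardGeneric("residualSignal"))
#' @rdname accessors
#' @export
setGeneric("nModes", function(object) standardGeneric("nModes"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("electrodePositions", function(object) standardGeneric("electrodePositions"))
#' @rdname accessors
#' @export
setGeneric("gridPositions", function(object) standardGeneric("gridPositions"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(object) standardGeneric("gainMatrix"))
#' @rdname accessors
#' @export
setGeneric("orientationMode", function(object) standardGeneric("orientationMode"))
#' @rdname accessors
#' @export
setGeneric("sourceGrid", function(object) standardGeneric("sourceGrid"))
#' @rdname accessors
#' @export
setGeneric("energyValues", function(object) standardGeneric("energyValues"))
#' @rdname accessors
#' @export
setGeneric("tValues", function(object) standardGeneric("tValues"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("tThresholds", function(object) standardGeneric("tThresholds"))

# ---- methods -------------------------------------------------------------

#' @rdname accessors
setMethod("modes", "IMFSet", function(object) object@modes)
#' @rdname accessors
setMethod("residualSignal", "IMFSet", function(object) object@residual)
#' @rdname accessors
setMethod("nModes", "IMFSet", function(object) ncol(object@modes))
#' @rdname accessors
setMethod("samplingRate", "IMFSet", function(object) object@rate)
#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@rate)
#' @rdname accessors
setMethod("samplingRate", "EEGEpochs", function(object) object@rate)
#' @rdname accessors
setMethod("channelNames", "Montage", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "EEGRecording", function(object) object@channelNames)
#' @rdname accessors
setMethod("channelNames", "EEGEpochs", function(object) object@channelNames)
#' @rdname accessors
setMethod("electrodePositions", "Montage", function(object) object@positions)
#' @rdname accessors
setMethod("gridPositions", "SourceGrid", function(object) object@positions)
#' @rdname accessors
setMethod("gridSpacing", "SourceGrid", function(object) object@spacing)
#' @rdname accessors
setMethod("regionLabels", "SourceGrid", function(object) object@regions)
#' @rdname accessors
setMethod("gainMatrix", "LeadField", function(object) object@gain)
#' @rdname accessors
setMethod("orientationMode", "LeadField", function(object) object@orientation)
#' @rdname accessors
setMethod("sourceGrid", "LeadField", function(object) object@grid)
#' @rdname accessors
setMethod("sourceGrid", "SourceMap", function(object) object@grid)
#' @rdname accessors
setMethod("sourceGrid", "StatResult", function(object) object@grid)
#' @rdname accessors
setMethod("energyValues", "SourceMap", function(object) object@energy)
#' @rdname accessors
setMethod("tValues", "StatResult", function(object) object@t)
#' @rdname accessors
setMethod("pValues", "StatResult", function(object) object@p)
#' @rdname accessors
setMethod("tThresholds", "StatResult", function(object) object@thresholds)

# ---- show methods --------------------------------------------------------

setMethod("show", "SiftConfig", function(object) {
  cat("SiftConfig: maxModes", object@maxModes, "| maxSifts", object@maxSifts,
      "| stopSD", object@stopSD, "| envTol", object@envTol,
      "| ensemble", object@ensembleSize, "| noiseRatio", object@noiseRatio,
      "| seed", object@seed, "\n")
})

setMethod("show", "IMFSet", function(object) {
  cat("IMFSet:", ncol(object@modes), "modes +residual,",
      length(object@residual), "samples @", object@rate, "Hz\n")
})

setMethod("show", "Montage", function(object) {
  cat("Montage:", length(object@channelNames), "electrodes (",
      paste(head(object@channelNames, 4), collapse = ", "), "...)\n")
})

setMethod("show", "SourceGrid", function(object) {
  cat("SourceGrid:", nrow(object@positions), "nodes, spacing",
      object@spacing, "m, radius", object@radius, "m\n")
})

setMethod("show", "LeadField", function(object) {
  cat("LeadField:", nrow(object@gain), "electrodes x", ncol(object@gain),
      "columns (", object@orientation, "orientation ),",
      nrow(object@grid@positions), "nodes\n")
})

setMethod("show", "SourceMap", function(object) {
  cat("SourceMap:", length(object@energy), "nodes",
      if (nzchar(object@label)) paste0("[", object@label, "]") else "",
      "| peak energy", format(max(object@energy), digits = 4), "\n")
})

setMethod("show", "StatResult", function(object) {
  cat("StatResult:", length(object@t), "nodes |", object@method,
      "randomization,", object@nPerm, "permutations | min corrected p",
      format(min(object@p), digits = 4), "\n")
})

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nrow(object@data), "channels x", ncol(object@data),
      "samples @", object@rate, "Hz,", nrow(object@markers), "markers\n")
})

setMethod("show", "EEGEpochs", function(object) {
  d <- dim(object@data)
  cat("EEGEpochs:", d[1], "channels x", d[2], "samples x", d[3],
      "trials @", object@rate, "Hz\n")
})
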