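#' @include AllClasses.R
NULL

#' Sampling rate accessor
#' @param object an EEGRecording, EpochSet or SourceEstimate.
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Channel names accessor
#'
#' Methods for the `Biobase::channelNames` generic (re-exported), so the
#' accessor keeps working whatever the package attach order.
#'
#' @param object an object carrying channel labels.
#' @return Character vector of channel names.
#' @importFrom Biobase channelNames
#' @export channelNames
#' @name channelNames
#' @aliases channelNames
NULL

#' Event table accessor
#' @param object an EEGRecording.
#' @return data.frame of segment-onset events.
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' Raw signal accessor
#' @param object an EEGRecording or EpochSet.
#' @return The numeric data (matrix or array).
#' @export
setGeneric("signalData", function(object) standardGeneric("signalData"))

#' Epoch condition labels
#' @param object an EpochSet.
#' @return Factor of condition labels.
#' @export
setGeneric("epochLabels", function(object) standardGeneric("epochLabels"))

#' Epoch grouping table
#' @param object an EpochSet.
#' @return data.frame with subject, lap, segment per epoch.
#' @export
setGeneric("groupTable", function(object) standardGeneric("groupTable"))

#' Source-estimate values
#' @param object a SourceEstimate.
#' @return sources x time matrix.
#' @export
setGeneric("stcValues", function(object) standardGeneric("stcValues"))

#' ROI masks of a toy leadfield
#' @param object a ToyLeadfield.
#' @return Named list of integer source-index vectors.
#' @export
setGeneric("roiMasks", function(object) standardGeneric("roiMasks"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGRecording", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SourceEstimate", function(object) object@fs)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGRecording", function(object) rownames(object@data))
#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(object) dimnames(object@data)[[2]])
#' @rdname channelNames
#' @export
setMethod("channelNames", "ToyLeadfield", function(object) object@channelNames)
#' @rdname channelNames
#' @export
setMethod("channelNames", "InverseOperator", function(object) object@channelNames)

#' @rdname eventTable
#' @export
setMethod("eventTable", "EEGRecording", function(object) object@events)

#' @rdname signalData
#' @export
setMethod("signalData", "EEGRecording", function(object) object@data)
#' @rdname signalData
#' @export
setMethod("signalData", "EpochSet", function(object) object@data)

#' @rdname epochLabels
#' @export
setMethod("epochLabels", "EpochSet", function(object) object@labels)

#' @rdname groupTable
#' @export
setMethod("groupTable", "EpochSet", function(object) object@groups)

#' @rdname stcValues
#' @export
setMethod("stcValues", "SourceEstimate", function(object) object@values)

#' @rdname roiMasks
#' @export
setMethod("roiMasks", "ToyLeadfield", function(object) object@roiMasks)

setMethod("show", "EEGRecording", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGRecording: %d channels x %d samples (%.1f s at %g Hz)\n",
              d[1], d[2], d[2] / object@fs, object@fs))
  cat(sprintf("  events: %d", nrow(object@events)))
  if (nrow(object@events) > 0)
    cat(sprintf(" (%s)", paste(names(table(object@events$condition)),
                               collapse = ", ")))
  cat("\n")
  if (nrow(object@artifacts) > 0)
    cat(sprintf("  artifacts: %d annotated\n", nrow(object@artifacts)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples [%g, %g] s at %g Hz\n",
              d[1], d[2], d[3], object@tmin, object@tmax, object@fs))
  tb <- table(droplevels(object@labels))
  if (length(tb)) cat("  labels:",
                      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
                      "\n")
  if (length(object@log)) cat("  log:", paste(object@log, collapse = "; "), "\n")
})

setMethod("show", "ToyLeadfield", function(object) {
  cat(sprintf("ToyLeadfield: %d channels, %d sources (%d ROIs: %s)\n",
              nrow(object@gain), nrow(object@positions),
              length(object@roiMasks),
              paste(names(object@roiMasks), collapse = ", ")))
})

setMethod("show", "InverseOperator", function(object) {
  cat(sprintf(
    "InverseOperator: %d sources x %d channels, lambda2=%.4g, loose=%g, depth=%g\n",
    nrow(object@kernel) / 3L, ncol(object@kernel), object@lambda2,
    object@loose, object@depth))
})

setMethod("show", "SourceEstimate", function(object) {
  d <- dim(object@values)
  cat(sprintf("SourceEstimate [%s]: %d sources x %d samples, tmin=%g s, fs=%g Hz\n",
              object@condition, d[1], d[2], object@tmin, object@fs))
})
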