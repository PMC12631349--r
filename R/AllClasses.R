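#' @include engageEEG-package.R
NULL

# ---- EEGRecording ----------------------------------------------------------

#' Continuous multichannel EEG recording
#'
#' Container for a continuous channels-by-samples recording in microvolts,
#' with sampling rate, an event table marking segment onsets, and optional
#' artifact annotations. Channel names are the row names of `data`.
#'
#' Events carry one row per road segment with columns `onset_sample`
#' (1-based sample index), `condition` (one of [conditionLevels()]),
#' `subject`, `lap` and `segment`.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot events data.frame of segment-onset events, sorted by onset.
#' @slot artifacts data.frame of injected artifact annotations (may be empty).
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric",
                 events = "data.frame", artifacts = "data.frame"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (is.null(rownames(object@data)))
    msg <- c(msg, "data must have channel names as row names")
  else if (anyDuplicated(rownames(object@data)))
    msg <- c(msg, "channel names must be unique")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite with no NaN")
  ev <- object@events
  if (nrow(ev) > 0) {
    need <- c("onset_sample", "condition", "subject", "lap", "segment")
    if (!all(need %in% names(ev)))
      msg <- c(msg, paste("events must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (is.unsorted(ev$onset_sample))
        msg <- c(msg, "events must be sorted by onset_sample")
      if (any(ev$onset_sample < 1 | ev$onset_sample > ncol(object@data)))
        msg <- c(msg, "event onsets must lie within the recording")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix with channel row names.
#' @param fs sampling rate (Hz).
#' @param events data.frame of events (see [EEGRecording-class]); may be empty.
#' @param artifacts data.frame of artifact annotations; may be empty.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, fs, events = emptyEvents(),
                         artifacts = emptyArtifacts()) {
  new("EEGRecording", data = data, fs = fs, events = events,
      artifacts = artifacts)
}

emptyEvents <- function() {
  data.frame(onset_sample = integer(), condition = character(),
             subject = integer(), lap = integer(), segment = integer())
}

emptyArtifacts <- function() {
  data.frame(onset_sample = integer(), type = character(),
             channel = character())
}

# ---- EpochSet --------------------------------------------------------------

#' Epoched EEG data
#'
#' Epochs x channels x time tensor cut around segment onsets, with the
#' condition label and the (subject, lap, segment) grouping tuple of each
#' epoch. The time axis runs from `tmin` to `tmax` seconds relative to the
#' event, with `round((tmax - tmin) * fs) + 1` samples.
#'
#' @slot data numeric array, epochs x channels x time (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot tmin,tmax epoch window in seconds relative to the event onset.
#' @slot labels factor of condition labels, one per epoch.
#' @slot groups data.frame with columns subject, lap, segment (one row per
#'   epoch).
#' @slot baselineWindow numeric length-2: window used (or to be used) for
#'   baseline correction, seconds.
#' @slot log character vector of processing notes (dropped epochs etc.).
#'
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", fs = "numeric", tmin = "numeric",
                 tmax = "numeric", labels = "factor", groups = "data.frame",
                 baselineWindow = "numeric", log = "character"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-d array (epochs x channels x time)")
  nt <- round((object@tmax - object@tmin) * object@fs) + 1
  if (d[3] != nt)
    msg <- c(msg, sprintf("time axis has %d samples, expected %d", d[3], nt))
  if (length(object@labels) != d[1])
    msg <- c(msg, "one label per epoch required")
  if (!all(levels(object@labels) %in% conditionLevels()))
    msg <- c(msg, "labels must be in conditionLevels()")
  if (nrow(object@groups) != d[1])
    msg <- c(msg, "one group row per epoch required")
  if (!all(c("subject", "lap", "segment") %in% names(object@groups)))
    msg <- c(msg, "groups must have subject, lap, segment columns")
  if (is.null(dimnames(object@data)[[2]]))
    msg <- c(msg, "channel names required on dim 2")
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param data epochs x channels x time array; dim 2 must carry channel names.
#' @param fs sampling rate (Hz).
#' @param tmin,tmax epoch window (s).
#' @param labels condition labels (character or factor).
#' @param groups data.frame with subject, lap, segment per epoch.
#' @param baselineWindow baseline window (s), default `c(-0.2, 0)`.
#' @param log processing notes.
#' @return An [EpochSet-class] object.
#' @export
EpochSet <- function(data, fs, tmin, tmax, labels, groups,
                     baselineWindow = c(-0.2, 0), log = character()) {
  labels <- factor(as.character(labels), levels = conditionLevels())
  new("EpochSet", data = data, fs = fs, tmin = tmin, tmax = tmax,
      labels = labels, groups = groups, baselineWindow = baselineWindow,
      log = log)
}

# ---- ToyLeadfield ----------------------------------------------------------

#' Toy-geometry forward model
#'
#' A quasi-dipolar leadfield on a spherical toy geometry: sources on an
#' inner spherical sheet, sensors on an outer shell. Gain columns come in
#' orientation triplets per source, ordered (tangent1, tangent2, normal) in
#' the source-local frame, so that the third column of each triplet is the
#' cortex-normal component. ROI masks partition the sources into six named
#' angular sectors labelled with the study's regions.
#'
#' @slot gain channels x (3 * sources) matrix.
#' @slot positions sources x 3 coordinates.
#' @slot normals sources x 3 unit outward normals.
#' @slot roiMasks named list of integer source-index vectors.
#' @slot channelNames character channel labels.
#'
#' @exportClass ToyLeadfield
setClass("ToyLeadfield",
  representation(gain = "matrix", positions = "matrix", normals = "matrix",
                 roiMasks = "list", channelNames = "character"))

setValidity("ToyLeadfield", function(object) {
  msg <- character()
  S <- nrow(object@positions)
  if (ncol(object@gain) != 3L * S)
    msg <- c(msg, "gain must have 3 columns per source")
  if (nrow(object@gain) != length(object@channelNames))
    msg <- c(msg, "gain rows must match channelNames")
  if (any(!is.finite(object@gain))) msg <- c(msg, "gain must be finite")
  nn <- sqrt(rowSums(object@normals^2))
  if (any(abs(nn - 1) > 1e-6)) msg <- c(msg, "normals must be unit length")
  if (length(msg)) msg else TRUE
})

# ---- InverseOperator -------------------------------------------------------

#' Regularized minimum-norm inverse operator with dSPM normalization
#'
#' @slot kernel (3 * sources) x channels matrix `K = R G' (G R G' + lambda2 C)^-1`.
#' @slot dspmScale per-source noise-normalization factors.
#' @slot lambda2 regularization `1 / SNR^2`.
#' @slot loose transverse-orientation scale in `[0, 1]`.
#' @slot depth depth-weighting exponent in `[0, 1]`.
#' @slot noiseCov channels x channels noise covariance used.
#' @slot channelNames channel labels the kernel expects.
#'
#' @exportClass InverseOperator
setClass("InverseOperator",
  representation(kernel = "matrix", dspmScale = "numeric",
                 lambda2 = "numeric", loose = "numeric", depth = "numeric",
                 noiseCov = "matrix", channelNames = "character"))

setValidity("InverseOperator", function(object) {
  msg <- character()
  if (object@lambda2 <= 0) msg <- c(msg, "lambda2 must be positive")
  if (any(object@dspmScale <= 0)) msg <- c(msg, "dspmScale must be positive")
  if (nrow(object@kernel) %% 3L != 0L)
    msg <- c(msg, "kernel rows must come in orientation triplets")
  if (length(msg)) msg else TRUE
})

# ---- SourceEstimate --------------------------------------------------------

#' Noise-normalized source estimate (dSPM)
#'
#' Source x time matrix of dimensionless dSPM values, with the time axis of
#' the generating epochs and a condition/contrast tag.
#'
#' @slot values sources x time matrix.
#' @slot fs sampling rate (Hz).
#' @slot tmin start of the time axis (s).
#' @slot condition condition or contrast tag.
#'
#' @exportClass SourceEstimate
setClass("SourceEstimate",
  representation(values = "matrix", fs = "numeric", tmin = "numeric",
                 condition = "character"))

setValidity("SourceEstimate", function(object) {
  if (any(!is.finite(object@values))) "values must be finite" else TRUE
})

# ---- ChannelNormalizer -----------------------------------------------------

#' Train-fold channel normalizer
#'
#' Stores per-channel means and standard deviations estimated on training
#' epochs only; applying it to held-out epochs uses the stored statistics,
#' never re-fits (the leakage contract of the validation schemes).
#'
#' @slot means,sds per-channel statistics.
#' @slot epsilon floor applied to near-zero standard deviations.
#' @slot channelNames channels the statistics refer to.
#'
#' @exportClass ChannelNormalizer
setClass("ChannelNormalizer",
  representation(means = "numeric", sds = "numeric", epsilon = "numeric",
                 channelNames = "character"))

# ---- FeatureTable ----------------------------------------------------------

#' Per-epoch feature table
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the assembled wavelet features: assay `"features"` is features x
#' epochs; `rowData` describes each feature (kind, channel or pair, sub-band,
#' statistic); `colData` carries the condition label and the (subject, lap,
#' segment) grouping of every epoch.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' required")
  else if (anyNA(SummarizedExperiment::assay(object, "features")))
    msg <- c(msg, "features must not contain NA")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be unique")
  cd <- names(SummarizedExperiment::colData(object))
  if (!all(c("label", "subject", "lap", "segment") %in% cd))
    msg <- c(msg, "colData must have label, subject, lap, segment")
  if (length(msg)) msg else TRUE
})
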