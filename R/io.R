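#' @include AllClasses.R
NULL

# Plain-text serialization. Recordings are written as a TSV signal matrix
# plus a JSON sidecar (sampling rate, channel order); events use the
# documented TSV layout; feature tables go to CSV with a JSON sidecar for
# labels and groups.

#' Write / read a segment-event table
#'
#' TSV with columns onset_sample, condition, subject, lap, segment.
#'
#' @param events data.frame of events (see [EEGRecording-class]).
#' @param path file path.
#' @return `readEventsTSV` returns the data.frame.
#' @export
writeEventsTSV <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEventsTSV
#' @export
readEventsTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a continuous recording as text
#'
#' `<path>.tsv` holds the channels x samples matrix (one channel per row,
#' first column the channel name); `<path>.json` the sampling rate;
#' `<path>.events.tsv` the event table.
#'
#' @param recording an [EEGRecording-class].
#' @param path base path (without extension).
#' @param digits signal rounding for the text representation.
#' @return `readRecordingText` returns the [EEGRecording-class].
#' @export
writeRecordingText <- function(recording, path, digits = 6) {
  stopifnot(is(recording, "EEGRecording"))
  df <- data.frame(channel = rownames(recording@data),
                   signif(recording@data, digits), check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = recording@fs,
                            n_samples = ncol(recording@data)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  writeEventsTSV(recording@events, paste0(path, ".events.tsv"))
  invisible(path)
}

#' @rdname writeRecordingText
#' @export
readRecordingText <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  raw <- utils::read.delim(paste0(path, ".tsv"), header = FALSE,
                           stringsAsFactors = FALSE)
  X <- as.matrix(raw[, -1, drop = FALSE])
  rownames(X) <- raw[[1]]
  colnames(X) <- NULL
  storage.mode(X) <- "double"
  ev <- readEventsTSV(paste0(path, ".events.tsv"))
  EEGRecording(X, fs = meta$fs, events = ev)
}

#' Write / read a feature table
#'
#' `<path>.csv` holds the epochs x features matrix with structured feature
#' names as header; `<path>.json` the labels and grouping columns.
#'
#' @param features a [FeatureTable-class].
#' @param path base path (without extension).
#' @return `readFeatureCSV` returns the [FeatureTable-class].
#' @export
writeFeatureCSV <- function(features, path) {
  stopifnot(is(features, "FeatureTable"))
  X <- t(SummarizedExperiment::assay(features, "features"))
  utils::write.table(data.frame(X, check.names = FALSE),
                     paste0(path, ".csv"), sep = ",", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(features))
  jsonlite::write_json(cd, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  X <- as.matrix(utils::read.delim(paste0(path, ".csv"), sep = ",",
                                   check.names = FALSE))
  cd <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ft <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = S4Vectors::DataFrame(cd))
  new("FeatureTable", ft)
}

#' Write a ground-truth record as JSON
#'
#' @param ground_truth the `ground_truth` element of [generateRecording()].
#' @param path file path.
#' @export
writeGroundTruthJSON <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
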