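#' @include AllClasses.R utils.R
NULL

#' Re-reference a recording
#'
#' Earlobe mode subtracts the mean of the A1/A2 (or other named) reference
#' channels from every channel and, by default, drops the reference channels
#' afterwards. Common-average mode subtracts the per-sample mean across all
#' channels and is idempotent.
#'
#' @param recording an [EEGRecording-class].
#' @param reference `"earlobe"` or `"common-average"`.
#' @param ref_channels reference channel names for earlobe mode.
#' @param drop_refs drop the reference channels after earlobe referencing.
#' @return The re-referenced [EEGRecording-class].
#' @export
rereference <- function(recording,
                        reference = c("earlobe", "common-average"),
                        ref_channels = c("A1", "A2"), drop_refs = TRUE) {
  stopifnot(is(recording, "EEGRecording"))
  reference <- match.arg(reference)
  X <- recording@data
  if (reference == "earlobe") {
    miss <- setdiff(ref_channels, rownames(X))
    if (length(miss))
      stop(sprintf("reference channel(s) missing: %s",
                   paste(miss, collapse = ", ")))
    ref <- colMeans(X[ref_channels, , drop = FALSE])
    X <- sweep(X, 2, ref, "-")
    if (drop_refs) X <- X[setdiff(rownames(X), ref_channels), , drop = FALSE]
  } else {
    if (nrow(X) < 2) stop("common-average reference needs >= 2 channels")
    X <- sweep(X, 2, colMeans(X), "-")
  }
  out <- recording
  out@data <- X
  validObject(out)
  out
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming windowed-sinc design with order set from the lower transition
#' width `min(lo, 0.25 * lo + 2)` Hz, applied with exact group-delay
#' compensation (linear phase, zero net shift). Default 2-36 Hz.
#'
#' @param recording an [EEGRecording-class].
#' @param lo,hi band edges in Hz, `0 < lo < hi < fs/2`.
#' @param transition optional transition-width override (Hz).
#' @return Filtered [EEGRecording-class].
#' @export
bandpassFIR <- function(recording, lo = 2, hi = 36, transition = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@fs
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    stop("need 0 < lo < hi < fs/2")
  taps <- designBandpass(fs, lo, hi, transition)
  n <- ncol(recording@data)
  if (n < 3 * length(taps))
    stop(sprintf("signal (%d samples) shorter than 3x filter length (%d taps)",
                 n, length(taps)))
  out <- recording
  out@data <- t(applyFIR(t(recording@data), taps))
  dimnames(out@data) <- dimnames(recording@data)
  out
}

#' Zero-phase FIR notch filter
#'
#' Band-stop Hamming windowed-sinc notches (default +/- 2.5 Hz stop edges,
#' 1.5 Hz transitions) at the mains frequency and its first harmonic,
#' applied with group-delay compensation. An empty frequency set is the
#' identity.
#'
#' @param recording an [EEGRecording-class].
#' @param freqs notch center frequencies (Hz), each below `fs/2`.
#' @param half_width stop-band half width (Hz).
#' @param transition transition width (Hz).
#' @return Filtered [EEGRecording-class].
#' @export
notchFilter <- function(recording, freqs = c(50, 100), half_width = 2.5,
                        transition = 1.5) {
  stopifnot(is(recording, "EEGRecording"))
  if (length(freqs) == 0) return(recording)
  fs <- recording@fs
  if (any(freqs >= fs / 2))
    stop("notch frequencies must be below fs/2")
  out <- recording
  X <- t(out@data)
  for (f in freqs) {
    taps <- designBandstop(fs, f - half_width, f + half_width, transition)
    if (nrow(X) < 3 * length(taps))
      stop(sprintf("signal (%d samples) shorter than 3x filter length (%d taps)",
                   nrow(X), length(taps)))
    X <- applyFIR(X, taps)
  }
  out@data <- t(X)
  dimnames(out@data) <- dimnames(recording@data)
  out
}

#' Cut epochs around segment-onset events
#'
#' One epoch per event spanning `tmin` to `tmax` seconds around the onset,
#' carrying the event's condition label and (subject, lap, segment) tuple.
#' Events whose window crosses a recording edge are dropped and counted in
#' the epoch log.
#'
#' @param recording an [EEGRecording-class] with events.
#' @param tmin,tmax epoch window (s), defaults -0.4 and 1.6.
#' @return An [EpochSet-class].
#' @export
epochRecording <- function(recording, tmin = -0.4, tmax = 1.6) {
  stopifnot(is(recording, "EEGRecording"))
  ev <- recording@events
  if (nrow(ev) == 0) stop("recording has no events")
  fs <- recording@fs
  nt <- as.integer(round((tmax - tmin) * fs)) + 1L
  off0 <- as.integer(round(tmin * fs))
  n <- ncol(recording@data)
  start <- ev$onset_sample + off0
  end <- start + nt - 1L
  ok <- start >= 1L & end <= n
  dropped <- sum(!ok)
  if (!any(ok)) stop("no usable events: all epoch windows cross the edges")
  evk <- ev[ok, , drop = FALSE]
  C <- nrow(recording@data)
  data <- array(0, dim = c(sum(ok), C, nt),
                dimnames = list(NULL, rownames(recording@data), NULL))
  st <- start[ok]
  for (i in seq_len(sum(ok)))
    data[i, , ] <- recording@data[, st[i]:(st[i] + nt - 1L)]
  log <- sprintf("epoched %d events; dropped %d at edges", sum(ok), dropped)
  EpochSet(data, fs, tmin, tmax, labels = evk$condition,
           groups = data.frame(subject = evk$subject, lap = evk$lap,
                               segment = evk$segment),
           log = log)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default -0.2 to 0 s); the window mean of the output is exactly zero.
#'
#' @param epochs an [EpochSet-class].
#' @param window numeric `c(t1, t2)` within `[tmin, 0]`.
#' @return Baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-0.2, 0)) {
  stopifnot(is(epochs, "EpochSet"))
  if (window[1] < epochs@tmin - 1e-9 || window[2] > 1e-9 ||
      window[1] >= window[2])
    stop("baseline window must be a nonempty interval within [tmin, 0]")
  idx <- windowIndices(window, epochs@tmin, epochs@fs, dim(epochs@data)[3])
  if (length(idx) == 0) stop("baseline window contains no samples")
  bl <- apply(epochs@data[, , idx, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out@data <- epochs@data - array(rep(bl, dim(epochs@data)[3]),
                                  dim = dim(epochs@data))
  out@baselineWindow <- window
  out@log <- c(epochs@log,
               sprintf("baseline-corrected over [%g, %g] s", window[1], window[2]))
  out
}

#' Fit a per-channel z-score normalizer on training epochs
#'
#' Means and standard deviations are computed per channel over all training
#' epochs and time points. Standard deviations below `epsilon` are floored
#' (with a message) so constant channels stay finite. The fitted object is
#' applied with [applyChannelNorm()]; it never re-fits, which is the
#' leakage contract enforced by the validation fold plans.
#'
#' @param epochs_train training [EpochSet-class].
#' @param epsilon variance floor.
#' @return A [ChannelNormalizer-class].
#' @export
fitChannelNorm <- function(epochs_train, epsilon = 1e-8) {
  stopifnot(is(epochs_train, "EpochSet"))
  X <- epochs_train@data
  C <- dim(X)[2]
  m <- numeric(C); s <- numeric(C)
  for (c in seq_len(C)) {
    v <- X[, c, ]
    m[c] <- mean(v)
    s[c] <- stats::sd(as.numeric(v))
  }
  floored <- s < epsilon
  if (any(floored)) {
    message(sprintf("%d zero-variance channel(s) floored at epsilon", sum(floored)))
    s[floored] <- epsilon
  }
  new("ChannelNormalizer", means = m, sds = s, epsilon = epsilon,
      channelNames = channelNames(epochs_train))
}

#' Apply a fitted channel normalizer
#'
#' @param normalizer a [ChannelNormalizer-class] from [fitChannelNorm()].
#' @param epochs an [EpochSet-class] with the same channels.
#' @return Normalized [EpochSet-class].
#' @export
applyChannelNorm <- function(normalizer, epochs) {
  stopifnot(is(normalizer, "ChannelNormalizer"), is(epochs, "EpochSet"))
  if (!identical(normalizer@channelNames, channelNames(epochs)))
    stop("channel sets of normalizer and epochs differ")
  out <- epochs
  X <- epochs@data
  for (c in seq_len(dim(X)[2]))
    X[, c, ] <- (X[, c, ] - normalizer@means[c]) / normalizer@sds[c]
  out@data <- X
  out
}
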