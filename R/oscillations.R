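#' @include utils.R
NULL

#' Frequency band definitions
#'
#' The canonical analysis set (theta 4-7, alpha 8-12, mu 8-13 specific to
#' motor sites, beta 13-30 Hz) and the coarser grouping used by the
#' classifier's sub-band interpretation (delta-theta 2-8, alpha 8-12,
#' beta-low 13-20, beta-high 20-36 Hz).
#'
#' @param set `"canonical"` or `"classifier"`.
#' @return data.frame with columns name, lo, hi.
#' @export
bandDefs <- function(set = c("canonical", "classifier")) {
  set <- match.arg(set)
  if (set == "canonical")
    data.frame(name = c("theta", "alpha", "mu", "beta"),
               lo = c(4, 8, 8, 13), hi = c(7, 12, 13, 30))
  else
    data.frame(name = c("delta-theta", "alpha", "beta-low", "beta-high"),
               lo = c(2, 8, 13, 20), hi = c(8, 12, 20, 36))
}

#' ROI-band analysis plan
#'
#' The hypothesis-driven (ROI, band) pairs evaluated for power and ERD/ERS:
#' motor beta and mu, visual alpha, frontal-midline theta, posterior
#' parietal alpha.
#'
#' @return data.frame with columns roi, band.
#' @export
roiBandPlan <- function() {
  data.frame(roi = c("Motor", "Motor", "Visual", "mPFC", "ACC", "PPC"),
             band = c("beta", "mu", "alpha", "theta", "theta", "alpha"))
}

# FIR band-pass a vector/matrix signal, capping the filter order so short
# epochs remain filterable (at most a third of the signal length).
bandFilter <- function(x, band, fs, transition = NULL) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  max_taps <- floor((n - 1) / 3)
  if (max_taps %% 2L == 0L) max_taps <- max_taps - 1L
  if (max_taps < 11L) stop("signal too short to band-pass filter")
  taps <- designBandpass(fs, band[1], band[2], transition, max_taps = max_taps)
  applyFIR(x, taps)
}

#' Band power of a time series
#'
#' Mean squared amplitude of the band-pass-filtered signal over the analysis
#' window (default 0.1-0.8 s after onset). The time axis is defined by
#' `tmin` and `fs`. A warning is issued when the window holds fewer than
#' three cycles of the band's lower edge.
#'
#' @param x numeric vector.
#' @param band `c(lo, hi)` in Hz, inside the Nyquist range.
#' @param fs sampling rate (Hz).
#' @param tmin time of the first sample (s), default 0.
#' @param window analysis window (s) or NULL for the full signal.
#' @param transition optional FIR transition-width override (Hz).
#' @return Non-negative scalar power in squared signal units.
#' @export
bandPower <- function(x, band, fs, tmin = 0, window = NULL,
                      transition = NULL) {
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < fs / 2)
  y <- bandFilter(x, band, fs, transition)
  if (!is.null(window)) {
    if (window[2] - window[1] < 3 / band[1])
      warning(sprintf("window shorter than 3 cycles of %g Hz", band[1]))
    idx <- windowIndices(window, tmin, fs, length(y))
    if (!length(idx)) stop("window outside signal support")
    y <- y[idx]
  }
  mean(y^2)
}

#' Event-related desynchronization / synchronization
#'
#' Percentage change of band power in the active window relative to the
#' pre-onset baseline: `(P_active - P_baseline) / P_baseline * 100`.
#' Negative values indicate desynchronization (power drop), positive values
#' synchronization. Zero baseline power is degenerate and yields `NA` with
#' a warning so the value can be excluded from aggregates. Scaling the whole
#' signal leaves the result unchanged.
#'
#' @param x numeric vector (one epoch of one channel or ROI time course).
#' @param band `c(lo, hi)` Hz.
#' @param fs sampling rate (Hz).
#' @param tmin time of the first sample (s).
#' @param active active window (s), default `c(0.1, 0.8)`.
#' @param baseline baseline window (s), default `c(-0.2, 0)`.
#' @return ERD/ERS in percent (scalar; `NA` if degenerate).
#' @export
erdErs <- function(x, band, fs, tmin, active = c(0.1, 0.8),
                   baseline = c(-0.2, 0)) {
  y <- bandFilter(x, band, fs)
  ia <- windowIndices(active, tmin, fs, length(y))
  ib <- windowIndices(baseline, tmin, fs, length(y))
  if (!length(ia) || !length(ib)) stop("window outside signal support")
  p_act <- mean(y[ia]^2)
  p_base <- mean(y[ib]^2)
  if (p_base <= 0) {
    warning("zero baseline power: ERD/ERS degenerate")
    return(NA_real_)
  }
  (p_act - p_base) / p_base * 100
}

#' Condition-average ERD/ERS over a set of epochs
#'
#' Band-pass filters every epoch, averages the active-window and
#' baseline-window powers across epochs, and forms the percent change from
#' the averaged powers (ratio of means). With short baselines the
#' per-epoch ratio is strongly upward-biased (the baseline power estimate
#' has very few degrees of freedom), so aggregates over epochs use this
#' estimator; [erdErs()] remains the single-series definition.
#'
#' @param epochs_matrix epochs x time numeric matrix (one channel or ROI).
#' @param band `c(lo, hi)` Hz.
#' @param fs sampling rate (Hz).
#' @param tmin time of the first sample (s).
#' @param active,baseline analysis windows (s).
#' @return ERD/ERS in percent.
#' @export
erdErsAveraged <- function(epochs_matrix, band, fs, tmin,
                           active = c(0.1, 0.8), baseline = c(-0.2, 0)) {
  if (is.null(dim(epochs_matrix)))
    epochs_matrix <- matrix(epochs_matrix, nrow = 1)
  Y <- bandFilter(t(epochs_matrix), band, fs) # time x epochs
  ia <- windowIndices(active, tmin, fs, nrow(Y))
  ib <- windowIndices(baseline, tmin, fs, nrow(Y))
  if (!length(ia) || !length(ib)) stop("window outside signal support")
  p_act <- mean(Y[ia, ]^2)
  p_base <- mean(Y[ib, ]^2)
  if (p_base <= 0) {
    warning("zero baseline power: ERD/ERS degenerate")
    return(NA_real_)
  }
  (p_act - p_base) / p_base * 100
}

#' Pearson correlation between two time courses
#'
#' Linear inter-regional coupling index `cov(x, y) / (sd(x) sd(y))`.
#' Zero-variance input is degenerate and returns `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]` (or `NA` if degenerate).
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length inputs with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: correlation degenerate")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Welch auto- and cross-spectra
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segment averages of the
#' periodogram and cross-periodogram. Spectra are scaled as densities
#' (`2 / (fs sum(w^2))`, one-sided); the scaling cancels in coherence.
#'
#' @param x,y numeric vectors of equal length (`y = NULL` for auto only).
#' @param fs sampling rate (Hz).
#' @param n_segments number of Welch segments (>= 2; coherence needs >= 8
#'   for acceptable estimator bias, which is about `1/n_segments`).
#' @param overlap fractional overlap in `[0, 1)`, default 0.5.
#' @return List with `freq`, `pxx` and (if `y` given) `pyy`, `pxy`
#'   (complex), `n_segments`, `seg_len`.
#' @export
welchSpectra <- function(x, y = NULL, fs, n_segments = 8, overlap = 0.5) {
  n <- length(x)
  if (!is.null(y) && length(y) != n) stop("x and y must have equal length")
  seg_len <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (seg_len < 8)
    stop(sprintf(
      "input too short: %d Welch segments of >= 8 samples need >= %d samples",
      n_segments, ceiling(8 * (1 + (n_segments - 1) * (1 - overlap)))))
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  starts <- starts[seq_len(min(length(starts), n_segments))]
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1))) # Hann
  U <- sum(w^2)
  nf <- seg_len %/% 2L + 1L
  pxx <- numeric(nf); pyy <- numeric(nf); pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1L)]
    X <- stats::fft((xs - mean(xs)) * w)[seq_len(nf)]
    pxx <- pxx + Mod(X)^2
    if (!is.null(y)) {
      ys <- y[s:(s + seg_len - 1L)]
      Y <- stats::fft((ys - mean(ys)) * w)[seq_len(nf)]
      pyy <- pyy + Mod(Y)^2
      pxy <- pxy + X * Conj(Y)
    }
  }
  K <- length(starts)
  scale <- 2 / (fs * U * K)
  out <- list(freq = (seq_len(nf) - 1) * fs / seg_len,
              pxx = pxx * scale, n_segments = K, seg_len = seg_len)
  if (!is.null(y)) {
    out$pyy <- pyy * scale
    out$pxy <- pxy * scale
  }
  out
}

#' Magnitude-squared coherence
#'
#' `C(f) = |Pxy|^2 / (Pxx Pyy)` from Welch spectra; values lie in `[0, 1]`.
#' With `K` segments the estimator is biased upward by roughly `1/K` under
#' independence, which is why a single segment (coherence identically 1) is
#' rejected.
#'
#' @inheritParams welchSpectra
#' @return List with `freq`, `coherence`, `n_segments`.
#' @export
msc <- function(x, y, fs, n_segments = 8, overlap = 0.5) {
  if (n_segments < 2) stop("coherence needs >= 2 Welch segments")
  sp <- welchSpectra(x, y, fs, n_segments, overlap)
  coh <- Mod(sp$pxy)^2 / (sp$pxx * sp$pyy)
  coh[!is.finite(coh)] <- 0
  list(freq = sp$freq, coherence = pmin(pmax(coh, 0), 1),
       n_segments = sp$n_segments)
}

#' Band-average coherence
#'
#' Mean coherence over the frequency bins inside a band.
#'
#' @param msc_result output of [msc()].
#' @param band `c(lo, hi)` Hz.
#' @return Scalar in `[0, 1]`.
#' @export
bandCoherence <- function(msc_result, band) {
  sel <- msc_result$freq >= band[1] & msc_result$freq <= band[2]
  if (!any(sel)) stop("no frequency bins inside the band")
  mean(msc_result$coherence[sel])
}

#' Pairwise ROI connectivity matrix
#'
#' Symmetric ROI x ROI matrix of either broadband Pearson correlations or
#' band-averaged magnitude-squared coherences between ROI time courses.
#'
#' @param timecourses ROI x time matrix (rows named).
#' @param metric `"correlation"` or `"coherence"`.
#' @param fs sampling rate (needed for coherence).
#' @param band `c(lo, hi)` Hz (coherence only).
#' @param n_segments Welch segments for coherence.
#' @param condition optional condition tag stored as an attribute.
#' @return ROI x ROI matrix with attributes `metric`, `band`, `condition`.
#' @export
connectivityMatrix <- function(timecourses,
                               metric = c("correlation", "coherence"),
                               fs = NULL, band = NULL, n_segments = 8,
                               condition = NA_character_) {
  metric <- match.arg(metric)
  R <- nrow(timecourses)
  M <- diag(1, R)
  dimnames(M) <- list(rownames(timecourses), rownames(timecourses))
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    v <- if (metric == "correlation") {
      stats::cor(timecourses[i, ], timecourses[j, ])
    } else {
      if (is.null(fs) || is.null(band))
        stop("coherence needs fs and band")
      bandCoherence(msc(timecourses[i, ], timecourses[j, ], fs,
                        n_segments), band)
    }
    M[i, j] <- M[j, i] <- v
  }
  attr(M, "metric") <- metric
  attr(M, "band") <- band
  attr(M, "condition") <- condition
  M
}

#' Contrast two connectivity matrices
#'
#' Elementwise difference of matrices sharing metric, band and shape;
#' antisymmetric under swapping the arguments.
#'
#' @param mat_a,mat_b matrices from [connectivityMatrix()].
#' @return Difference matrix with metadata attributes.
#' @export
connectivityContrast <- function(mat_a, mat_b) {
  if (!identical(attr(mat_a, "metric"), attr(mat_b, "metric")))
    stop("metric mismatch")
  if (!identical(attr(mat_a, "band"), attr(mat_b, "band")))
    stop("band mismatch")
  if (!identical(dim(mat_a), dim(mat_b))) stop("shape mismatch")
  D <- unclass(mat_a) - unclass(mat_b)
  attr(D, "metric") <- attr(mat_a, "metric")
  attr(D, "band") <- attr(mat_a, "band")
  attr(D, "condition") <- paste(attr(mat_a, "condition"), "-",
                                attr(mat_b, "condition"))
  D
}
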