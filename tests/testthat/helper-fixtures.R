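# In-code fixtures shared across test files. All synthetic, built at test
# time; sizes kept small so the suite stays fast.

# a sinusoid recording with named channels
sineRecording <- function(freqs, fs = 250, dur = 20, amp = 1,
                          channels = paste0("ch", seq_along(freqs))) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  X <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), numeric(length(t))))
  rownames(X) <- channels
  EEGRecording(X, fs)
}

# a tiny white-noise recording with evenly spaced events
noiseRecording <- function(n_ch = 4, fs = 100, dur = 30, n_events = 8,
                           seed = 42, channels = NULL) {
  set.seed(seed)
  n <- fs * dur
  X <- matrix(rnorm(n_ch * n), n_ch, n)
  rownames(X) <- if (is.null(channels)) paste0("ch", seq_len(n_ch)) else channels
  onsets <- as.integer(seq(fs, n - 2 * fs, length.out = n_events))
  ev <- data.frame(onset_sample = onsets,
                   condition = rep(conditionLevels(), length.out = n_events),
                   subject = 1L, lap = 1L, segment = seq_len(n_events))
  EEGRecording(X, fs, events = ev)
}

# micro simulation config: tiny but structurally complete
microConfig <- function(..., seed = 11) {
  simConfig(n_subjects = 2, fs = 250, laps_per_subject = 1,
            segments_per_lap = 6, segment_duration = 2, seed = seed, ...)
}

# small epoch set straight from the generator + preprocessing
microEpochs <- function(n_subjects = 2, seed = 11, ...) {
  cfg <- simConfig(n_subjects = n_subjects, fs = 250, laps_per_subject = 1,
                   segments_per_lap = 6, segment_duration = 2, seed = seed,
                   ...)
  concatEpochs(lapply(seq_len(n_subjects), function(s)
    preprocessRecording(generateRecording(cfg, s)$recording,
                        notch_freqs = c(50))))
}

# direct windowed-DFT spectra oracle (independent of the Welch code path:
# plain loops, explicit DFT matrix, same segmentation/window definition)
dftSpectraOracle <- function(x, y, fs, n_segments, overlap = 0.5) {
  n <- length(x)
  seg_len <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)[seq_len(n_segments)]
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  nf <- seg_len %/% 2 + 1
  k <- 0:(nf - 1)
  m <- 0:(seg_len - 1)
  W <- exp(-2i * pi * outer(k, m) / seg_len) # DFT matrix, explicit
  pxx <- numeric(nf); pyy <- numeric(nf); pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1)]; ys <- y[s:(s + seg_len - 1)]
    X <- as.vector(W %*% ((xs - mean(xs)) * w))
    Y <- as.vector(W %*% ((ys - mean(ys)) * w))
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  scale <- 2 / (fs * sum(w^2) * length(starts))
  list(freq = k * fs / seg_len, pxx = pxx * scale, pyy = pyy * scale,
       pxy = pxy * scale)
}

# brute-force BH step-up from the definition: adjusted p_(i) =
# min over j >= i of min(1, m * p_(j) / j)
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
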