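# Internal helpers: seeding, windows, zero-phase FIR application, noise
# generators shared by the simulator and the spectral metrics.

#' Derive a reproducible child seed from a master seed
#'
#' Hashes a master seed together with integer indices (subject, stage, fold,
#' ...) into a new seed below 2^31, so that every stochastic stage draws from
#' its own deterministic substream.
#'
#' @param master Integer master seed.
#' @param ... Integer indices identifying the substream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
childSeed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[k]) * 16807 + k) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate expr with a locally-set RNG state, restoring the caller's state.
localSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Indices of a time window [w1, w2] (seconds, inclusive) on an axis that
# starts at tmin with sampling rate fs and n samples.
windowIndices <- function(window, tmin, fs, n) {
  tt <- tmin + (seq_len(n) - 1) / fs
  which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
}

nextMultiple <- function(n, k) as.integer(ceiling(n / k) * k)

# ---- FIR design and zero-phase application ---------------------------------

# Hamming windowed-sinc band-pass taps. Order from the transition width
# (Hamming main-lobe rule n ~= 3.3 fs / transition), forced even so the
# linear-phase group delay is an integer number of samples.
designBandpass <- function(fs, lo, hi, transition = NULL, max_taps = NULL) {
  stopifnot(lo > 0, lo < hi, hi < fs / 2)
  if (is.null(transition)) transition <- min(lo, 0.25 * lo + 2)
  n <- ceiling(3.3 * fs / transition)
  if (!is.null(max_taps)) n <- min(n, max_taps - 1L)
  n <- max(10L, as.integer(n))
  if (n %% 2L == 1L) n <- n + 1L
  as.numeric(signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass"))
}

designBandstop <- function(fs, lo, hi, transition = 1.5) {
  stopifnot(lo > 0, lo < hi, hi < fs / 2)
  n <- as.integer(ceiling(3.3 * fs / transition))
  if (n %% 2L == 1L) n <- n + 1L
  as.numeric(signal::fir1(n, c(lo, hi) / (fs / 2), type = "stop"))
}

# Zero-phase application of a symmetric (linear-phase, odd-length) FIR:
# reflect-pad, FFT overlap-free convolution, compensate the group delay.
# x: numeric vector or samples x channels matrix. Returns same shape.
applyFIR <- function(x, taps) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  L <- length(taps)
  if (L %% 2L != 1L) stop("FIR tap count must be odd (even order)")
  n <- nrow(X)
  pad <- min(L, n - 1L)
  # reflect padding keeps window-mean statistics near the edges unbiased
  Xp <- rbind(X[rev(seq_len(pad) + 1L), , drop = FALSE],
              X,
              X[n - seq_len(pad), , drop = FALSE])
  np <- nrow(Xp)
  nfft <- stats::nextn(np + L - 1L, 2)
  H <- stats::fft(c(taps, numeric(nfft - L)))
  XF <- stats::mvfft(rbind(Xp, matrix(0, nfft - np, ncol(Xp))))
  Y <- Re(stats::mvfft(XF * H, inverse = TRUE)) / nfft
  delay <- (L - 1L) / 2L
  out <- Y[pad + delay + seq_len(n), , drop = FALSE]
  if (vec) drop(out) else out
}

# ---- noise generators ------------------------------------------------------

# Unit-variance 1/f^exponent noise via spectral shaping of white noise.
pinkNoise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f) # two-sided frequency index
  scale <- c(0, f[-1]^(-exponent / 2))
  y <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Unit-variance noise strictly band-limited to [lo, hi] Hz (brick-wall in
# the DFT domain). Used for planted oscillations so that coherence targets
# follow the analytic common-source model exactly in band.
bandNoise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  keep <- freq >= lo & freq <= hi
  if (sum(keep) < 2) stop("band too narrow for the requested length")
  W[!keep] <- 0
  y <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("degenerate band-limited noise")
  y / s
}

# Raised-cosine on/off ramps over `ramp` samples at both ends.
envelopeRamp <- function(n, ramp) {
  if (ramp <= 0 || 2 * ramp >= n) return(rep(1, n))
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  c(up, rep(1, n - 2 * ramp), rev(up))
}
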