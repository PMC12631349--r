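test_that("band power matches the analytic sinusoid value", {
  fs <- 250
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  p_alpha <- bandPower(x, c(8, 12), fs, tmin = 0, window = c(5, 15))
  expect_lt(abs(p_alpha - 0.5) / 0.5, 0.05)
  p_beta <- bandPower(x, c(13, 30), fs, tmin = 0, window = c(5, 15))
  expect_lt(p_beta, 0.025)
  expect_equal(bandPower(rep(0, 5000), c(8, 12), fs), 0)
  expect_warning(bandPower(x, c(4, 7), fs, tmin = 0, window = c(5, 5.2)),
                 "3 cycles")
})

test_that("ERD/ERS follows the percent-change formula and is scale invariant", {
  fs <- 250
  tmin <- -2
  t <- seq(tmin, 4, by = 1 / fs)
  # amplitude-modulated alpha: baseline amplitude 1, active amplitude a1
  make <- function(a1) {
    amp <- ifelse(t < 0, 1, a1)
    amp * sin(2 * pi * 10 * t)
  }
  # power ratio a1^2: constructed to reproduce the reported -50.11% / +97.9%
  erd <- erdErs(make(sqrt(0.4989)), c(8, 12), fs, tmin,
                active = c(0.5, 3.5), baseline = c(-1.8, -0.2))
  expect_lt(abs(erd - (-50.11)), 1.5)
  ers <- erdErs(make(sqrt(1.979)), c(8, 12), fs, tmin,
                active = c(0.5, 3.5), baseline = c(-1.8, -0.2))
  expect_lt(abs(ers - 97.9), 3)
  # equal power -> 0%
  expect_lt(abs(erdErs(make(1), c(8, 12), fs, tmin,
                       active = c(0.5, 3.5), baseline = c(-1.8, -0.2))), 1)
  # multiplying the signal by c leaves ERD/ERS unchanged
  x <- make(0.7)
  e1 <- erdErs(x, c(8, 12), fs, tmin)
  e2 <- erdErs(5.3 * x, c(8, 12), fs, tmin)
  expect_equal(e1, e2, tolerance = 1e-10)
  # zero baseline power flagged degenerate
  expect_warning(out <- erdErs(rep(0, 2000), c(8, 12), fs, tmin = -2),
                 "degenerate")
  expect_true(is.na(out))
})

test_that("pearsonCorr handles exact and degenerate cases", {
  x <- rnorm(50)
  expect_equal(pearsonCorr(x, x), 1)
  expect_equal(pearsonCorr(x, -x), -1)
  expect_equal(pearsonCorr(x, 2 * x + 3), 1)
  expect_warning(r <- pearsonCorr(x, rep(1, 50)), "degenerate")
  expect_true(is.na(r))
  expect_error(pearsonCorr(x, rnorm(10)), "equal-length")
})

test_that("Welch spectra match the direct windowed-DFT oracle to 1e-10", {
  set.seed(5)
  x <- rnorm(256); y <- rnorm(256)
  for (K in c(4, 8)) {
    got <- welchSpectra(x, y, fs = 128, n_segments = K)
    ref <- dftSpectraOracle(x, y, fs = 128, n_segments = K)
    expect_lt(max(abs(got$pxx - ref$pxx)) / max(ref$pxx), 1e-10)
    expect_lt(max(abs(got$pyy - ref$pyy)) / max(ref$pyy), 1e-10)
    expect_lt(max(Mod(got$pxy - ref$pxy)) / max(Mod(ref$pxy)), 1e-10)
    cg <- msc(x, y, 128, n_segments = K)
    cref <- Mod(ref$pxy)^2 / (ref$pxx * ref$pyy)
    expect_lt(max(abs(cg$coherence - pmin(cref, 1))), 1e-10)
  }
})

test_that("coherence: identical signals 1, independent noise near 1/K bias", {
  set.seed(6)
  fs <- 128
  x <- rnorm(napprox <- 130 * 64)
  expect_true(all(abs(msc(x, x, fs, 8)$coherence - 1) < 1e-9))
  y <- rnorm(napprox)
  m <- msc(x, y, fs, n_segments = 64)
  expect_lt(mean(m$coherence), 0.05)
  expect_error(msc(rnorm(20), rnorm(20), fs, 8), "too short")
})

test_that("common-source mixing recovers the analytic coherence 0.6", {
  set.seed(7)
  fs <- 200
  n <- 200 * 60
  # common-source model: with shared-power fraction a2 per channel the
  # analytic coherence is a2^2, so a2 = sqrt(0.6) targets coherence 0.6
  s <- rnorm(n); a2 <- sqrt(0.6)
  x <- sqrt(a2) * s + sqrt(1 - a2) * rnorm(n)
  y <- sqrt(a2) * s + sqrt(1 - a2) * rnorm(n)
  m <- msc(x, y, fs, n_segments = 32)
  got <- bandCoherence(m, c(8, 12))
  expect_lt(abs(got - 0.6), 0.1)
})

test_that("band powers over a partition of 2-36 Hz sum to broadband power", {
  set.seed(8)
  fs <- 250
  x <- rnorm(fs * 30)
  xb <- signalData(bandpassFIR(EEGRecording(
    matrix(x, 1, dimnames = list("a")), fs), 2, 36))[1, ]
  parts <- list(c(2, 8), c(8, 13), c(13, 22), c(22, 36))
  tot <- sum(vapply(parts, function(b)
    bandPower(xb, b, fs, tmin = 0, window = c(5, 25), transition = 1),
    numeric(1)))
  broad <- mean(xb[windowIndices(c(5, 25), 0, fs, length(xb))]^2)
  expect_lt(abs(tot - broad) / broad, 0.1)
})

test_that("coherence is invariant under channel-wise linear filtering in band", {
  set.seed(9)
  fs <- 200
  n <- 200 * 40
  s <- rnorm(n); a <- sqrt(0.5)
  x <- a * s + sqrt(1 - a^2) * rnorm(n)
  y <- a * s + sqrt(1 - a^2) * rnorm(n)
  c0 <- bandCoherence(msc(x, y, fs, 16), c(8, 12))
  yf <- signalData(bandpassFIR(EEGRecording(
    matrix(y, 1, dimnames = list("a")), fs), 3, 40))[1, ]
  c1 <- bandCoherence(msc(x, yf, fs, 16), c(8, 12))
  expect_lt(abs(c1 - c0), 0.05)
})

test_that("connectivity matrices are symmetric with valid ranges and contrasts", {
  set.seed(10)
  tc <- matrix(rnorm(4 * 2000), 4, 2000,
               dimnames = list(c("Motor", "mPFC", "Visual", "PPC"), NULL))
  Mc <- connectivityMatrix(tc, "correlation", condition = "MD-Easy")
  expect_equal(Mc, t(Mc))
  expect_true(all(diag(Mc) == 1))
  Mh <- connectivityMatrix(tc, "coherence", fs = 100, band = c(4, 7),
                           condition = "AD-Easy")
  expect_true(all(Mh >= 0 & Mh <= 1))
  D <- connectivityContrast(Mc, Mc)
  expect_true(all(D == 0))
  M2 <- connectivityMatrix(tc + rnorm(length(tc)), "correlation",
                           condition = "AD-Easy")
  expect_equal(as.numeric(connectivityContrast(Mc, M2)),
               as.numeric(-connectivityContrast(M2, Mc)), tolerance = 1e-12)
  expect_error(connectivityContrast(Mc, Mh), "metric")
})
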