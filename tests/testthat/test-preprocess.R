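test_that("earlobe re-referencing subtracts the A1/A2 mean elementwise", {
  set.seed(1)
  X <- matrix(rnorm(4 * 50), 4, 50)
  rownames(X) <- c("Fz", "Cz", "A1", "A2")
  rec <- EEGRecording(X, 100)
  out <- rereference(rec, "earlobe", drop_refs = FALSE)
  ref <- (X["A1", ] + X["A2", ]) / 2
  for (ch in rownames(X))
    expect_equal(signalData(out)[ch, ], X[ch, ] - ref)
  # zero reference leaves data unchanged
  X2 <- X; X2["A2", ] <- -X2["A1", ]
  rec2 <- EEGRecording(X2, 100)
  out2 <- rereference(rec2, "earlobe", drop_refs = FALSE)
  expect_equal(signalData(out2), X2)
  expect_error(rereference(rec, "earlobe", ref_channels = c("M1", "M2")),
               "missing")
})

test_that("common-average referencing is idempotent", {
  rec <- noiseRecording()
  once <- rereference(rec, "common-average")
  twice <- rereference(once, "common-average")
  expect_equal(signalData(once), signalData(twice))
  expect_lt(max(abs(colMeans(signalData(once)))), 1e-12)
})

test_that("band-pass FIR attenuates stop-band, preserves pass-band at zero lag", {
  fs <- 250
  rec <- sineRecording(c(50, 10, 0.00001), fs = fs, dur = 30)
  # a DC-offset channel
  X <- signalData(rec)
  X[3, ] <- 5
  rec <- EEGRecording(X, fs)
  out <- bandpassFIR(rec, 2, 36)
  mid <- 2000:5000 # avoid edges
  amp <- function(v) sqrt(2 * mean(v[mid]^2))
  expect_lt(amp(signalData(out)[1, ]), 0.05)       # 50 Hz removed
  expect_gt(amp(signalData(out)[2, ]), 0.95)       # 10 Hz preserved
  expect_lt(abs(amp(signalData(out)[2, ]) - 1), 0.05)
  # DC (5 uV offset) suppressed by the Hamming stop band (~53 dB)
  expect_lt(abs(mean(signalData(out)[3, ])), 0.02)
  # zero phase: cross-correlation peak of the 10 Hz channel at lag 0
  cc <- ccf(signalData(out)[2, mid], signalData(rec)[2, mid], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filtering is linear and rejects too-short input", {
  fs <- 250
  set.seed(2)
  a <- rnorm(8000); b <- rnorm(8000)
  recA <- EEGRecording(matrix(a, 1, dimnames = list("x")), fs)
  recB <- EEGRecording(matrix(b, 1, dimnames = list("x")), fs)
  recAB <- EEGRecording(matrix(2 * a - 3 * b, 1, dimnames = list("x")), fs)
  fA <- signalData(bandpassFIR(recA))[1, ]
  fB <- signalData(bandpassFIR(recB))[1, ]
  fAB <- signalData(bandpassFIR(recAB))[1, ]
  expect_lt(max(abs(fAB - (2 * fA - 3 * fB))) / max(abs(fAB)), 1e-8)
  short <- EEGRecording(matrix(rnorm(100), 1, dimnames = list("x")), fs)
  expect_error(bandpassFIR(short), "shorter than 3x")
})

test_that("notch removes mains, leaves the pass-band, empty set is identity", {
  fs <- 250
  rec <- sineRecording(c(50, 10), fs = fs, dur = 30)
  out <- notchFilter(rec, 50)
  mid <- 2000:5000
  amp <- function(v) sqrt(2 * mean(v[mid]^2))
  expect_lt(amp(signalData(out)[1, ]), 0.1)                # >= 10x down
  expect_lt(abs(amp(signalData(out)[2, ]) - 1), 0.02)      # within 2%
  expect_identical(notchFilter(rec, numeric(0)), rec)
  expect_error(notchFilter(rec, 130), "below fs/2")
})

test_that("epoching drops edge events, keeps labels in event order", {
  rec <- noiseRecording(n_ch = 3, fs = 100, dur = 30, n_events = 8)
  ev <- eventTable(rec)
  # add an event too close to the start
  ev2 <- rbind(data.frame(onset_sample = 5L, condition = "MD-Easy",
                          subject = 1L, lap = 1L, segment = 0L), ev)
  rec2 <- EEGRecording(signalData(rec), 100, events = ev2)
  ep <- epochRecording(rec2, -0.4, 1.6)
  expect_equal(dim(signalData(ep))[1], 8)
  expect_match(ep@log, "dropped 1")
  expect_equal(as.character(epochLabels(ep)), ev$condition)
  expect_equal(dim(signalData(ep))[3], round(2 * 100) + 1)
  # 1001 samples at 500 Hz
  ep500 <- epochRecording(noiseRecording(n_ch = 2, fs = 500, dur = 30,
                                         n_events = 10))
  expect_equal(dim(signalData(ep500))[3], 1001)
  onlybad <- EEGRecording(signalData(rec),
                          100, events = ev2[1, , drop = FALSE])
  expect_error(epochRecording(onlybad), "no usable events")
})

test_that("baseline correction zeroes the window mean exactly", {
  rec <- noiseRecording(n_ch = 2, fs = 100, dur = 30, n_events = 6)
  ep <- epochRecording(rec)
  # constant epochs -> all zeros
  cst <- ep
  cst@data[] <- 7
  out <- baselineCorrect(cst)
  expect_true(all(out@data == 0))
  # ramp epochs: ramp minus its baseline mean
  tt <- ep@tmin + (seq_len(dim(ep@data)[3]) - 1) / ep@fs
  rmp <- ep
  for (i in seq_len(dim(ep@data)[1]))
    for (c in seq_len(dim(ep@data)[2])) rmp@data[i, c, ] <- tt
  outr <- baselineCorrect(rmp)
  bidx <- which(tt >= -0.2 & tt <= 0)
  expect_equal(outr@data[1, 1, ], tt - mean(tt[bidx]))
  # random input: post-correction baseline mean below 1e-10
  outn <- baselineCorrect(ep)
  bl <- apply(outn@data[, , bidx, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  expect_error(baselineCorrect(ep, c(0.1, 0.5)), "within")
})

test_that("channel normalizer fits on train only and floors zero variance", {
  rec <- noiseRecording(n_ch = 3, fs = 100, dur = 30, n_events = 8)
  ep <- epochRecording(rec)
  nrm <- fitChannelNorm(ep)
  z <- applyChannelNorm(nrm, ep)
  for (c in 1:3) {
    expect_lt(abs(mean(z@data[, c, ])), 1e-10)
    expect_lt(abs(sd(as.numeric(z@data[, c, ])) - 1), 1e-2)
  }
  # shifted test data keeps a nonzero mean: no re-fitting
  shifted <- ep
  shifted@data <- shifted@data + 5
  zs <- applyChannelNorm(nrm, shifted)
  expect_gt(abs(mean(zs@data[, 1, ])), 1)
  # constant channel stays finite via the epsilon floor
  cst <- ep
  cst@data[, 2, ] <- 3
  expect_message(nc <- fitChannelNorm(cst), "floored")
  zc <- applyChannelNorm(nc, cst)
  expect_true(all(is.finite(zc@data)))
})
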