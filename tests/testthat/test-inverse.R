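test_that("toy leadfield is deterministic with sane geometry and ROIs", {
  lf1 <- suppressMessages(makeToyLeadfield(12, 24, geometry_seed = 4))
  lf2 <- suppressMessages(makeToyLeadfield(12, 24, geometry_seed = 4))
  expect_identical(lf1@gain, lf2@gain)
  expect_error(makeToyLeadfield(12, 6), ">= 2 per ROI")
  # well-separated sources have decorrelated gain columns (normal component)
  G <- lf1@gain[, seq(3, ncol(lf1@gain), by = 3)]
  pos <- lf1@positions
  d <- as.matrix(dist(pos))
  far <- which(d == max(d), arr.ind = TRUE)[1, ]
  expect_lt(abs(cor(G[, far[1]], G[, far[2]])), 0.9)
  # ROI masks partition all sources disjointly
  masks <- roiMasks(lf1)
  expect_equal(length(unique(unlist(masks))), 24)
  expect_gte(length(unlist(masks)) / nrow(pos), 0.8)
  expect_equal(sort(names(masks)),
               sort(c("Motor", "mPFC", "ACC", "Visual", "PPC", "DLPFC")))
})

test_that("baseline noise covariance matches white-noise analytic diagonal", {
  set.seed(9)
  fs <- 100
  n_ep <- 60; n_ch <- 4; nt <- 101
  sigma <- 2.5
  dat <- array(rnorm(n_ep * n_ch * nt, 0, sigma), c(n_ep, n_ch, nt),
               dimnames = list(NULL, paste0("ch", 1:n_ch), NULL))
  ep <- EpochSet(dat, fs, -0.5, 0.5,
                 labels = rep("MD-Easy", n_ep),
                 groups = data.frame(subject = 1, lap = 1,
                                     segment = seq_len(n_ep)))
  C <- noiseCovariance(ep, window = c(-0.5, 0), shrinkage = 0)
  expect_lt(max(abs(diag(C) - sigma^2)) / sigma^2, 0.1)
  expect_lt(max(abs(C[upper.tri(C)])) / sigma^2, 0.05)
  expect_lt(max(abs(C - t(C))), 1e-12)
  # identical channels: rank-1 before shrinkage (warned + enforced)
  dat2 <- dat
  for (c in 2:n_ch) dat2[, c, ] <- dat2[, 1, ]
  ep2 <- EpochSet(dat2, fs, -0.5, 0.5, labels = rep("MD-Easy", n_ep),
                  groups = data.frame(subject = 1, lap = 1,
                                      segment = seq_len(n_ep)))
  expect_warning(C2 <- noiseCovariance(ep2, c(-0.5, 0), shrinkage = 0),
                 "rank deficient")
  expect_equal(qr(C2)$rank, n_ch) # after enforced shrinkage
})

test_that("SNR 3 gives lambda2 = 0.111 and limit cases behave", {
  lf <- suppressMessages(makeToyLeadfield(12, 24, geometry_seed = 4))
  C <- diag(12); dimnames(C) <- list(channelNames(lf), channelNames(lf))
  inv <- makeInverse(lf, C, snr = 3)
  expect_equal(round(inv@lambda2, 3), 0.111)
  # loose = 0: transverse kernel rows vanish exactly
  inv0 <- makeInverse(lf, C, snr = 3, loose = 0)
  S <- nrow(inv0@kernel) / 3
  trans <- sort(c(seq(1, 3 * S, by = 3), seq(2, 3 * S, by = 3)))
  expect_true(all(inv0@kernel[trans, ] == 0))
  expect_error(makeInverse(lf, C, snr = -1), "positive")
  expect_error(makeInverse(lf, C, loose = 2), "loose")
})

test_that("loose = 1, depth = 0 kernel equals the ridge-regression solution", {
  set.seed(21)
  # 5-channel x 4-source instance, directly computed reference inverse
  G <- matrix(rnorm(5 * 12), 5, 12)
  rownames(G) <- paste0("s", 1:5)
  pos <- matrix(rnorm(12), 4, 3)
  nrm <- pos / sqrt(rowSums(pos^2))
  lf <- new("ToyLeadfield", gain = G, positions = pos, normals = nrm,
            roiMasks = list(A = 1:2, B = 3:4),
            channelNames = rownames(G))
  C <- crossprod(matrix(rnorm(25), 5, 5)) / 5 + diag(5) * 0.1
  dimnames(C) <- list(rownames(G), rownames(G))
  inv <- makeInverse(lf, C, snr = 2, loose = 1, depth = 0)
  lambda2 <- 1 / 4
  # with R = rho I the kernel is rho G' (rho G G' + lambda2 C)^-1
  rho <- sum(diag(C)) / sum(diag(G %*% t(G)))
  Kref <- rho * t(G) %*% solve(rho * G %*% t(G) + lambda2 * C)
  expect_lt(max(abs(inv@kernel - Kref)), 1e-10)
})

test_that("noise-only epochs give dSPM of order 1; zero input maps to zero", {
  set.seed(31)
  lf <- suppressMessages(makeToyLeadfield(16, 24, geometry_seed = 2))
  n_ch <- 16; n_ep <- 100; nt <- 51; fs <- 100
  Cn <- diag(n_ch)
  dimnames(Cn) <- list(channelNames(lf), channelNames(lf))
  dat <- array(rnorm(n_ep * n_ch * nt), c(n_ep, n_ch, nt),
               dimnames = list(NULL, channelNames(lf), NULL))
  dat[1, , ] <- 0
  ep <- EpochSet(dat, fs, 0, 0.5, labels = rep("MD-Easy", n_ep),
                 groups = data.frame(subject = 1, lap = 1,
                                     segment = seq_len(n_ep)))
  inv <- makeInverse(lf, Cn)
  stcs <- applyInverseDSPM(ep, inv)
  expect_true(all(stcValues(stcs[[1]]) == 0))
  m <- mean(vapply(stcs[-1], function(s) mean(abs(stcValues(s))), numeric(1)))
  expect_gt(m, 0.2); expect_lt(m, 2)
  # linearity up to the fixed dSPM scaling
  ep2 <- ep; ep2@data <- 3 * ep@data
  stcs2 <- applyInverseDSPM(ep2, inv)
  expect_equal(stcValues(stcs2[[2]]), 3 * stcValues(stcs[[2]]))
  # channel mismatch rejected with names
  epbad <- ep
  dimnames(epbad@data)[[2]][1] <- "XX"
  expect_error(applyInverseDSPM(epbad, inv), "mismatch")
})

test_that("contrast is antisymmetric and shape-checked", {
  v <- matrix(rnorm(20), 4, 5)
  a <- new("SourceEstimate", values = v, fs = 10, tmin = 0, condition = "A")
  b <- new("SourceEstimate", values = v + 1, fs = 10, tmin = 0, condition = "B")
  expect_true(all(stcValues(stcContrast(a, a)) == 0))
  expect_equal(stcValues(stcContrast(a, b)), -stcValues(stcContrast(b, a)))
  bb <- new("SourceEstimate", values = v[, 1:3], fs = 10, tmin = 0,
            condition = "B")
  expect_error(stcContrast(a, bb), "shapes")
})

test_that("ROI time courses are source means over masks and window-selectable", {
  v <- rbind(rep(1, 10), rep(3, 10), rep(5, 10))
  stc <- new("SourceEstimate", values = v, fs = 10, tmin = 0, condition = "A")
  tc <- roiTimecourse(stc, list(one = 2L, two = c(1L, 2L)))
  expect_equal(unname(tc["one", ]), rep(3, 10))
  expect_equal(unname(tc["two", ]), rep(2, 10))
  expect_error(roiTimecourse(stc, list(bad = integer(0))), "empty")
  tcw <- roiTimecourse(stc, list(a = 1L), window = c(0.2, 0.5))
  expect_equal(ncol(tcw), 4)
  # uniform value propagates to every ROI
  u <- new("SourceEstimate", values = matrix(2, 5, 8), fs = 10, tmin = 0,
           condition = "A")
  tcu <- roiTimecourse(u, list(a = 1:2, b = 3:5))
  expect_true(all(tcu == 2))
})

test_that("regularization is monotone: kernel norm shrinks as lambda2 grows", {
  lf <- suppressMessages(makeToyLeadfield(12, 24, geometry_seed = 4))
  C <- diag(12); dimnames(C) <- list(channelNames(lf), channelNames(lf))
  norms <- vapply(c(1, 3, 10, 100), function(snr)
    sqrt(sum(makeInverse(lf, C, snr = 1 / snr)@kernel^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})
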