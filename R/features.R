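#' @include AllClasses.R utils.R
NULL

# Daubechies-4 (8-tap, 4 vanishing moments) analysis filters in natural
# order; g is the quadrature mirror of h. The circular (periodized)
# convolution phase matches PyWavelets' mode = "periodization".
DB4_H <- c(0.230377813308855230, 0.714846570552541500,
           0.630880767929590400, -0.027983769416983850,
           -0.187034811718881140, 0.030841381835986965,
           0.032883011666982945, -0.010597401784997278)
DB4_G <- (-1)^(0:7) * rev(DB4_H)
DB4_SHIFT <- -3L

#' Wavelet decomposition plan
#'
#' Five-level db4 decomposition keeping five sub-bands: the approximation
#' A5 and details D5..D2 (D1 is discarded as it lies entirely above the
#' 2-36 Hz filtered content at 500 Hz). At `fs` Hz the nominal sub-band
#' ranges are A5 `0 - fs/64`, D5 `fs/64 - fs/32`, D4 `fs/32 - fs/16`,
#' D3 `fs/16 - fs/8`, D2 `fs/8 - fs/4` (at 500 Hz: 0-7.8, 7.8-15.6,
#' 15.6-31.25, 31.25-62.5, 62.5-125 Hz). Epochs are zero-padded to the next
#' multiple of `2^levels`; the transform is periodized and exactly
#' orthogonal, so sub-band energies satisfy Parseval.
#'
#' @param fs sampling rate the level map refers to (Hz).
#' @param levels decomposition depth (fixed at 5 for the five sub-bands).
#' @return A `WaveletPlan` list with the sub-band/frequency map.
#' @export
waveletPlan <- function(fs = 500, levels = 5L) {
  if (levels != 5L) stop("the feature set is defined on five sub-bands (levels = 5)")
  keep <- c("A5", "D5", "D4", "D3", "D2")
  level_map <- data.frame(
    subband = c("A5", paste0("D", levels:1)),
    lo = c(0, fs / 2^((levels:1) + 1)),
    hi = c(fs / 2^(levels + 1), fs / 2^(levels:1)))
  structure(list(wavelet = "db4", levels = levels, keep = keep,
                 boundary = "periodic", fs = fs, level_map = level_map),
            class = "WaveletPlan")
}

# One level of the periodized orthogonal DWT on the columns of X (even N).
dwtLevelMatrix <- function(X) {
  N <- nrow(X)
  if (N %% 2L != 0L) stop("even length required")
  half <- N %/% 2L
  A <- matrix(0, half, ncol(X))
  D <- matrix(0, half, ncol(X))
  base <- 2L * (seq_len(half) - 1L)
  for (m in 0:7) {
    idx <- (base + m + DB4_SHIFT) %% N + 1L
    A <- A + DB4_H[m + 1L] * X[idx, , drop = FALSE]
    D <- D + DB4_G[m + 1L] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

#' Discrete wavelet transform into sub-bands
#'
#' Periodized db4 decomposition of one signal (or the columns of a matrix)
#' to `plan$levels` levels after zero-padding to the next multiple of
#' `2^levels`. Returns all detail levels plus the final approximation so
#' that the decomposition is exactly energy-preserving (orthogonal
#' transform of the zero-padded signal).
#'
#' @param x numeric vector, or matrix with one signal per column.
#' @param plan a [waveletPlan()].
#' @return Named list `A5, D5, D4, D3, D2, D1` of coefficient vectors
#'   (or matrices when `x` is a matrix).
#' @export
dwtSubbands <- function(x, plan = waveletPlan()) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  if (nrow(X) < 64)
    stop("epoch too short: need >= 64 samples for a 5-level db4 decomposition")
  Np <- nextMultiple(nrow(X), 2L^plan$levels)
  if (Np > nrow(X)) X <- rbind(X, matrix(0, Np - nrow(X), ncol(X)))
  out <- list()
  A <- X
  for (lev in seq_len(plan$levels)) {
    r <- dwtLevelMatrix(A)
    out[[paste0("D", lev)]] <- if (vec) drop(r$D) else r$D
    A <- r$A
  }
  out[[paste0("A", plan$levels)]] <- if (vec) drop(A) else A
  out[c(paste0("A", plan$levels), paste0("D", plan$levels:1))]
}

#' Sub-band summary statistics
#'
#' Mean absolute amplitude, energy (sum of squares) and wavelet entropy
#' `-sum(p log p)` with `p = c^2 / sum(c^2)` (natural log; `0 log 0 = 0`).
#' All-zero coefficients are degenerate: entropy is defined as 0 and a
#' warning is raised.
#'
#' @param coeffs numeric coefficient vector (nonempty).
#' @return Named numeric: `mean_amplitude`, `energy`, `entropy`.
#' @export
subbandStats <- function(coeffs) {
  if (!length(coeffs)) stop("empty coefficient vector")
  energy <- sum(coeffs^2)
  if (energy == 0) {
    warning("all-zero coefficients: entropy degenerate (0)")
    return(c(mean_amplitude = 0, energy = 0, entropy = 0))
  }
  p <- coeffs^2 / energy
  p <- p[p > 0]
  c(mean_amplitude = mean(abs(coeffs)), energy = energy,
    entropy = -sum(p * log(p)))
}

#' Default 11-pair electrode list
#'
#' Anatomically informed fronto-parietal, fronto-central, centro-parietal
#' and interhemispheric pairs used for the wavelet-coefficient coherence
#' features. Any 11-pair list over the montage may be substituted.
#'
#' @return List of 11 character pairs.
#' @export
defaultPairList <- function() {
  list(c("Fz", "Pz"), c("F3", "P3"), c("F4", "P4"), c("F3", "C3"),
       c("F4", "C4"), c("C3", "P3"), c("C4", "P4"), c("F3", "F4"),
       c("C3", "C4"), c("P3", "P4"), c("O1", "O2"))
}

#' Wavelet-coefficient coherence features of one epoch
#'
#' Pearson correlation between the two channels' coefficient vectors,
#' per sub-band and electrode pair. Zero-variance coefficients yield 0
#' with a warning.
#'
#' @param epoch channels x time numeric matrix with channel row names.
#' @param plan a [waveletPlan()].
#' @param pairs list of channel-name pairs, default [defaultPairList()].
#' @return pairs x sub-bands numeric matrix.
#' @export
pairCoherenceFeatures <- function(epoch, plan = waveletPlan(),
                                  pairs = defaultPairList()) {
  chans <- rownames(epoch)
  bad <- setdiff(unique(unlist(pairs)), chans)
  if (length(bad))
    stop(sprintf("pair channels not in epoch: %s", paste(bad, collapse = ", ")))
  sb <- dwtSubbands(t(epoch), plan)[plan$keep]
  out <- matrix(NA_real_, length(pairs), length(plan$keep),
                dimnames = list(vapply(pairs, paste, character(1),
                                       collapse = "-"),
                                plan$keep))
  for (p in seq_along(pairs)) {
    ia <- match(pairs[[p]][1], chans)
    ib <- match(pairs[[p]][2], chans)
    for (s in seq_along(plan$keep)) {
      a <- sb[[s]][, ia]; b <- sb[[s]][, ib]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance coefficients: pair coherence set to 0")
        out[p, s] <- 0
      } else out[p, s] <- stats::cor(a, b)
    }
  }
  out
}

# column-wise centered correlation of paired columns
.pairCor <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  den <- sqrt(colSums(A^2) * colSums(B^2))
  r <- colSums(A * B) / den
  r[!is.finite(r)] <- 0
  r
}

#' Assemble the per-epoch feature table
#'
#' Per channel and sub-band: mean amplitude, energy and wavelet entropy
#' (channels x 5 sub-bands x 3 statistics); plus the Pearson correlation of
#' wavelet coefficients per electrode pair and sub-band (11 x 5). With the
#' 29-channel montage this yields the 490-dimensional feature vector
#' `29 * 5 * 3 + 11 * 5`. Feature extraction is strictly per-epoch, so the
#' table is fold-safe by construction; only normalization and selection
#' (fitted inside training folds) carry state.
#'
#' @param epochs an [EpochSet-class] (preprocessed).
#' @param plan a [waveletPlan()] (defaults to the epoch sampling rate).
#' @param pairs list of channel pairs, default [defaultPairList()].
#' @return A [FeatureTable-class] (features x epochs) whose `colData` holds
#'   label, subject, lap, segment, mode and difficulty.
#' @export
extractFeatures <- function(epochs, plan = NULL, pairs = defaultPairList()) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(plan)) plan <- waveletPlan(fs = epochs@fs)
  d <- dim(epochs@data)
  E <- d[1]; C <- d[2]; Tn <- d[3]
  chans <- channelNames(epochs)
  # columns ordered (epoch-major): column (e - 1) * C + c is epoch e, channel c
  M <- matrix(aperm(epochs@data, c(3, 2, 1)), nrow = Tn)
  sb <- dwtSubbands(M, plan)[plan$keep]
  stats_names <- c("mean_amplitude", "energy", "entropy")
  n_pow <- C * length(plan$keep) * 3L
  n_coh <- length(pairs) * length(plan$keep)
  feats <- matrix(NA_real_, n_pow + n_coh, E)
  fnames <- character(n_pow + n_coh)
  meta <- data.frame(kind = character(n_pow + n_coh),
                     channel = NA_character_, pair = NA_character_,
                     subband = NA_character_, statistic = NA_character_,
                     stringsAsFactors = FALSE)
  row <- 0L
  for (s in seq_along(plan$keep)) {
    Cf <- sb[[s]]
    en <- colSums(Cf^2)
    ma <- colMeans(abs(Cf))
    P <- sweep(Cf^2, 2, pmax(en, .Machine$double.xmin), "/")
    ent <- -colSums(ifelse(P > 0, P * log(P), 0))
    ent[en == 0] <- 0
    for (st in seq_along(stats_names)) {
      vals <- switch(st, ma, en, ent)
      V <- matrix(vals, nrow = C) # channels x epochs
      for (cc in seq_len(C)) {
        row <- row + 1L
        feats[row, ] <- V[cc, ]
        fnames[row] <- paste(chans[cc], plan$keep[s], stats_names[st],
                             sep = "_")
        meta[row, ] <- list("power", chans[cc], NA, plan$keep[s],
                            stats_names[st])
      }
    }
  }
  for (p in seq_along(pairs)) {
    ia <- match(pairs[[p]][1], chans)
    ib <- match(pairs[[p]][2], chans)
    if (is.na(ia) || is.na(ib))
      stop(sprintf("pair channels not in montage: %s",
                   paste(pairs[[p]], collapse = "-")))
    cols_a <- (seq_len(E) - 1L) * C + ia
    cols_b <- (seq_len(E) - 1L) * C + ib
    for (s in seq_along(plan$keep)) {
      row <- row + 1L
      feats[row, ] <- .pairCor(sb[[s]][, cols_a, drop = FALSE],
                               sb[[s]][, cols_b, drop = FALSE])
      pname <- paste(pairs[[p]], collapse = "-")
      fnames[row] <- paste("coh", pname, plan$keep[s], sep = "_")
      meta[row, ] <- list("coherence", NA, pname, plan$keep[s], "r")
    }
  }
  rownames(feats) <- fnames
  keep_ep <- !apply(feats, 2, anyNA)
  if (!all(keep_ep))
    message(sprintf("dropped %d epoch(s) with NaN features", sum(!keep_ep)))
  labs <- as.character(epochs@labels)
  gr <- epochs@groups
  cd <- S4Vectors::DataFrame(
    label = labs, subject = gr$subject, lap = gr$lap, segment = gr$segment,
    mode = sub("-.*", "", labs), difficulty = sub(".*-", "", labs))
  ft <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = feats[, keep_ep, drop = FALSE]),
    rowData = S4Vectors::DataFrame(meta), colData = cd[keep_ep, ])
  new("FeatureTable", ft)
}
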