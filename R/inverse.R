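#' @include AllClasses.R utils.R
NULL

# Fibonacci lattice on the upper hemisphere, radius r.
hemispherePoints <- function(n, r) {
  g <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  z <- i / n                      # (0, 1): upper hemisphere only
  phi <- 2 * pi * i / g
  rho <- sqrt(pmax(0, 1 - z^2))
  r * cbind(x = rho * cos(phi), y = rho * sin(phi), z = z)
}

#' Build a toy-geometry leadfield
#'
#' Sources sit on an inner spherical sheet (radius 0.75), sensors on an
#' outer shell (radius 1), both on Fibonacci lattices over the upper
#' hemisphere. The gain of a unit dipole with orientation `e` at source
#' position `p` seen by a sensor at `x` follows the quasi-dipolar decay
#' `e . (x - p) / |x - p|^3`. Per source, gain columns are ordered
#' (tangent1, tangent2, normal) in the source-local frame, the normal being
#' radial. Six contiguous azimuthal sectors provide ROI masks named after
#' the study's regions; no anatomical fidelity is claimed. The condition
#' number of the fixed-orientation (normal-component) gain is reported via
#' `message()`.
#'
#' @param n_channels number of sensors (default 29).
#' @param n_sources number of sources (>= 12 so each ROI has >= 2).
#' @param geometry_seed seed for the (tiny) jitter applied to positions.
#' @param channel_names optional channel labels (defaults to the montage for
#'   29 channels, `S1..Sn` otherwise).
#' @return A [ToyLeadfield-class].
#' @export
makeToyLeadfield <- function(n_channels = 29, n_sources = 60,
                             geometry_seed = 1L, channel_names = NULL) {
  rois <- c("Motor", "mPFC", "ACC", "Visual", "PPC", "DLPFC")
  if (n_sources < 2 * length(rois))
    stop("n_sources must be >= 2 per ROI (>= 12)")
  if (is.null(channel_names))
    channel_names <- if (n_channels == 29) cognionicsMontage()
                     else sprintf("S%02d", seq_len(n_channels))
  localSeed(geometry_seed, {
    for (attempt in 1:5) {
      sens <- hemispherePoints(n_channels, 1) +
        matrix(stats::rnorm(3 * n_channels, 0, 0.01), ncol = 3)
      src <- hemispherePoints(n_sources, 0.75) +
        matrix(stats::rnorm(3 * n_sources, 0, 0.01), ncol = 3)
      dmin <- min(dist(rbind(sens, src)))
      if (dmin > 1e-3) break
      message("degenerate geometry (coincident points); regenerating with perturbation")
    }
    normals <- src / sqrt(rowSums(src^2))
    # local frames: two tangents orthogonal to the radial normal
    G <- matrix(0, n_channels, 3 * n_sources)
    for (i in seq_len(n_sources)) {
      nrm <- normals[i, ]
      ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      t1 <- ref - sum(ref * nrm) * nrm
      t1 <- t1 / sqrt(sum(t1^2))
      t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
              nrm[3] * t1[1] - nrm[1] * t1[3],
              nrm[1] * t1[2] - nrm[2] * t1[1])
      basis <- cbind(t1, t2, nrm)
      d <- sweep(sens, 2, src[i, ], "-")
      r3 <- rowSums(d^2)^1.5
      for (o in 1:3) G[, 3 * (i - 1) + o] <- (d %*% basis[, o]) / r3
    }
    G <- G / stats::median(sqrt(colSums(G^2)))
    rownames(G) <- channel_names
    # ROI masks: contiguous azimuthal sectors over all sources
    az <- atan2(src[, 2], src[, 1])
    sector <- cut(rank(az, ties.method = "first"),
                  breaks = length(rois), labels = FALSE)
    masks <- lapply(seq_along(rois), function(k) which(sector == k))
    names(masks) <- rois
    Gn <- G[, seq(3, 3 * n_sources, by = 3)]
    message(sprintf("toy leadfield: fixed-orientation gain condition number %.3g",
                    kappa(Gn, exact = FALSE)))
    new("ToyLeadfield", gain = G, positions = src, normals = normals,
        roiMasks = masks, channelNames = channel_names)
  })
}

#' Baseline noise covariance
#'
#' Channel covariance of the baseline samples pooled across epochs, with
#' shrinkage toward the scaled identity: `(1 - s) C + s mean(diag(C)) I`.
#' If the raw covariance is rank deficient and shrinkage is zero, shrinkage
#' 0.1 is enforced with a warning.
#'
#' @param epochs an [EpochSet-class].
#' @param window baseline window (s), default `c(-0.2, 0)`.
#' @param shrinkage shrinkage weight in `[0, 1]`, default 0.1.
#' @return Symmetric positive semi-definite channels x channels matrix.
#' @export
noiseCovariance <- function(epochs, window = c(-0.2, 0), shrinkage = 0.1) {
  stopifnot(is(epochs, "EpochSet"))
  if (dim(epochs@data)[1] < 2) stop("need >= 2 epochs")
  idx <- windowIndices(window, epochs@tmin, epochs@fs, dim(epochs@data)[3])
  if (length(idx) < 2) stop("baseline window within the epoch support required")
  d <- dim(epochs@data)
  # samples x channels: stack baseline stretches of all epochs
  M <- matrix(aperm(epochs@data[, , idx, drop = FALSE], c(3, 1, 2)),
              ncol = d[2])
  C <- stats::cov(M)
  if (shrinkage == 0 && qr(C)$rank < ncol(C)) {
    warning("baseline covariance is rank deficient; enforcing shrinkage 0.1")
    shrinkage <- 0.1
  }
  C <- (1 - shrinkage) * C + shrinkage * mean(diag(C)) * diag(ncol(C))
  C <- (C + t(C)) / 2
  dimnames(C) <- list(channelNames(epochs), channelNames(epochs))
  C
}

#' Assemble the regularized minimum-norm inverse operator
#'
#' Builds the source covariance `R` with per-source depth weights
#' `w_i = |G_i|_F^(-2 depth)` on each orientation triplet and transverse
#' orientation variance `loose^2` relative to the normal component, scales
#' `R` so that `trace(G R G') = trace(C)` (implicit whitening), and forms
#' the kernel `K = R G' (G R G' + lambda2 C)^-1` with `lambda2 = 1/snr^2`.
#' The dSPM normalization factor of source `i` is
#' `1 / sqrt(sum_orientations diag(K C K')_i)`.
#'
#' @param leadfield a [ToyLeadfield-class].
#' @param noise_cov channels x channels covariance from [noiseCovariance()].
#' @param snr assumed amplitude SNR (default 3, so `lambda2 = 1/9`).
#' @param loose transverse orientation scale in `[0, 1]` (default 0.2).
#' @param depth depth-weighting exponent in `[0, 1]` (default 0.8).
#' @return An [InverseOperator-class].
#' @export
makeInverse <- function(leadfield, noise_cov, snr = 3.0, loose = 0.2,
                        depth = 0.8) {
  stopifnot(is(leadfield, "ToyLeadfield"))
  if (snr <= 0) stop("snr must be positive")
  if (loose < 0 || loose > 1) stop("loose must be in [0, 1]")
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]")
  G <- leadfield@gain
  S <- ncol(G) / 3L
  lambda2 <- 1 / snr^2
  w <- vapply(seq_len(S), function(i) {
    cols <- 3L * (i - 1L) + 1:3
    nf <- sqrt(sum(G[, cols]^2))
    nf^(-2 * depth)
  }, numeric(1))
  rdiag <- as.numeric(t(outer(w, c(loose^2, loose^2, 1))))
  # implicit whitening: put G R G' on the scale of the noise covariance
  GR <- sweep(G, 2, rdiag, "*")
  M0 <- GR %*% t(G)
  rho <- sum(diag(noise_cov)) / sum(diag(M0))
  rdiag <- rdiag * rho
  M <- M0 * rho + lambda2 * noise_cov
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) || !all(is.finite(ch)))
    stop(sprintf("singular system matrix (condition number %.3g); cannot invert",
                 kappa(M)))
  Minv <- chol2inv(ch)
  K <- sweep(t(G), 1, rdiag, "*") %*% Minv
  KCKt_diag <- rowSums((K %*% noise_cov) * K)
  dspm <- 1 / sqrt(vapply(seq_len(S), function(i)
    sum(KCKt_diag[3L * (i - 1L) + 1:3]), numeric(1)))
  new("InverseOperator", kernel = K, dspmScale = dspm, lambda2 = lambda2,
      loose = loose, depth = depth, noiseCov = noise_cov,
      channelNames = leadfield@channelNames)
}

#' Apply the inverse with dSPM normalization
#'
#' Projects each epoch through the kernel, keeps the component normal to
#' the source sheet (the third orientation of each triplet), and multiplies
#' by the per-source dSPM factor, yielding noise-normalized source time
#' courses. The dSPM scaling is epoch-independent, so projection is linear
#' up to that fixed factor.
#'
#' @param epochs an [EpochSet-class] whose channels match the operator.
#' @param inv an [InverseOperator-class].
#' @return List of [SourceEstimate-class], one per epoch, tagged with the
#'   epoch's condition label.
#' @export
applyInverseDSPM <- function(epochs, inv) {
  stopifnot(is(epochs, "EpochSet"), is(inv, "InverseOperator"))
  chans <- channelNames(epochs)
  if (!identical(chans, inv@channelNames)) {
    miss <- setdiff(inv@channelNames, chans)
    extra <- setdiff(chans, inv@channelNames)
    stop(sprintf("channel mismatch; missing: {%s}, unexpected: {%s}",
                 paste(miss, collapse = ","), paste(extra, collapse = ",")))
  }
  S <- nrow(inv@kernel) / 3L
  nidx <- seq(3L, 3L * S, by = 3L)
  Kn <- inv@kernel[nidx, , drop = FALSE] * inv@dspmScale
  labs <- as.character(epochs@labels)
  lapply(seq_len(dim(epochs@data)[1]), function(i) {
    vals <- Kn %*% epochs@data[i, , ]
    new("SourceEstimate", values = vals, fs = epochs@fs, tmin = epochs@tmin,
        condition = labs[i])
  })
}

#' Average source estimates within conditions
#'
#' @param stcs list of [SourceEstimate-class] (per epoch).
#' @return Named list of condition-average [SourceEstimate-class].
#' @export
conditionAverageSTC <- function(stcs) {
  labs <- vapply(stcs, function(s) s@condition, character(1))
  out <- lapply(unique(labs), function(lb) {
    sel <- stcs[labs == lb]
    vals <- Reduce(`+`, lapply(sel, stcValues)) / length(sel)
    new("SourceEstimate", values = vals, fs = sel[[1]]@fs,
        tmin = sel[[1]]@tmin, condition = lb)
  })
  names(out) <- unique(labs)
  out
}

#' Contrast two source estimates
#'
#' Elementwise `a - b` on aligned time axes, tagged
#' `"<condition a> - <condition b>"`; antisymmetric under argument swap.
#'
#' @param stc_a,stc_b [SourceEstimate-class] objects with identical shape,
#'   sampling rate and time origin.
#' @return A [SourceEstimate-class].
#' @export
stcContrast <- function(stc_a, stc_b) {
  stopifnot(is(stc_a, "SourceEstimate"), is(stc_b, "SourceEstimate"))
  if (!identical(dim(stc_a@values), dim(stc_b@values)))
    stop("mismatched shapes")
  if (stc_a@fs != stc_b@fs || abs(stc_a@tmin - stc_b@tmin) > 1e-9)
    stop("time axes are not aligned")
  new("SourceEstimate", values = stc_a@values - stc_b@values,
      fs = stc_a@fs, tmin = stc_a@tmin,
      condition = paste(stc_a@condition, "-", stc_b@condition))
}

#' Extract ROI-mean time courses
#'
#' Arithmetic mean of the dSPM values across the sources of each mask, per
#' time point, optionally restricted to an analysis window (the study used
#' 0.1-0.8 s after segment onset).
#'
#' @param stc a [SourceEstimate-class].
#' @param roi_masks named list of source-index vectors (see [roiMasks()]).
#' @param window optional `c(t1, t2)` window (s) to restrict the time axis.
#' @return ROI x time numeric matrix.
#' @export
roiTimecourse <- function(stc, roi_masks, window = NULL) {
  stopifnot(is(stc, "SourceEstimate"))
  if (any(vapply(roi_masks, length, integer(1)) == 0))
    stop("empty ROI mask")
  V <- stc@values
  if (!is.null(window)) {
    idx <- windowIndices(window, stc@tmin, stc@fs, ncol(V))
    V <- V[, idx, drop = FALSE]
  }
  out <- t(vapply(roi_masks, function(m)
    colMeans(V[m, , drop = FALSE]), numeric(ncol(V))))
  rownames(out) <- names(roi_masks)
  out
}
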