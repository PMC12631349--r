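#' @include simulate.R preprocess.R inverse.R oscillations.R features.R classify.R stats.R
NULL

# common-average re-reference applied directly to epoched data (the inverse
# stage always receives average-referenced input)
commonAverageEpochs <- function(epochs) {
  X <- epochs@data
  m <- apply(X, c(1, 3), mean)
  out <- epochs
  out@data <- X - aperm(array(m, dim = dim(X)[c(1, 3, 2)]), c(1, 3, 2))
  out
}

#' Concatenate epoch sets
#'
#' Binds epochs from several subjects (identical channels, sampling rate
#' and time axis) into one [EpochSet-class].
#'
#' @param epoch_list list of [EpochSet-class] objects.
#' @return Combined [EpochSet-class].
#' @export
concatEpochs <- function(epoch_list) {
  stopifnot(length(epoch_list) >= 1)
  e1 <- epoch_list[[1]]
  for (e in epoch_list[-1]) {
    if (!identical(channelNames(e), channelNames(e1)) ||
        e@fs != e1@fs || abs(e@tmin - e1@tmin) > 1e-9)
      stop("epoch sets are not compatible")
  }
  datas <- lapply(epoch_list, function(e) e@data)
  E <- sum(vapply(datas, function(d) dim(d)[1], integer(1)))
  d1 <- dim(datas[[1]])
  out <- array(0, dim = c(E, d1[2], d1[3]),
               dimnames = list(NULL, channelNames(e1), NULL))
  at <- 0L
  for (d in datas) {
    out[at + seq_len(dim(d)[1]), , ] <- d
    at <- at + dim(d)[1]
  }
  EpochSet(out, e1@fs, e1@tmin, e1@tmax,
           labels = unlist(lapply(epoch_list,
                                  function(e) as.character(e@labels))),
           groups = do.call(rbind, lapply(epoch_list, function(e) e@groups)),
           baselineWindow = e1@baselineWindow,
           log = unlist(lapply(epoch_list, function(e) e@log)))
}

#' Preprocess one recording with the documented default chain
#'
#' Earlobe re-referencing (references dropped), 2-36 Hz zero-phase FIR
#' band-pass, mains notch (frequencies above Nyquist are skipped), epoching
#' around segment onsets and baseline correction.
#'
#' @param recording an [EEGRecording-class].
#' @param lo,hi band-pass edges (Hz).
#' @param notch_freqs notch frequencies (Hz); those at or above `fs/2` are
#'   dropped.
#' @param tmin,tmax epoch window (s).
#' @param baseline baseline window (s).
#' @param reference `"earlobe"` or `"common-average"` first-stage reference.
#' @return An [EpochSet-class].
#' @export
preprocessRecording <- function(recording, lo = 2, hi = 36,
                                notch_freqs = c(50, 100), tmin = -0.4,
                                tmax = 1.6, baseline = c(-0.2, 0),
                                reference = "earlobe") {
  rec <- if (reference == "earlobe" &&
             all(c("A1", "A2") %in% channelNames(recording)))
    rereference(recording, "earlobe")
  else rereference(recording, "common-average")
  rec <- bandpassFIR(rec, lo, hi)
  nf <- notch_freqs[notch_freqs < samplingRate(recording) / 2]
  if (length(nf)) rec <- notchFilter(rec, nf)
  baselineCorrect(epochRecording(rec, tmin, tmax), baseline)
}

roiContrastPairs <- function() {
  list(c("MD-Easy", "AD-Easy"), c("MD-Hard", "AD-Hard"),
       c("MD-Hard", "MD-Easy"), c("AD-Hard", "AD-Easy"))
}

chk <- function(x) sprintf("%.10e/%d", sum(as.numeric(x)), length(x))

# collect repeated per-epoch warnings (short-window, degenerate baselines)
# into a single log message instead of one warning per epoch
collectWarnings <- function(expr) {
  msgs <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  if (length(msgs)) {
    tb <- table(msgs)
    message(paste(sprintf("%s (x%d)", names(tb), tb), collapse = "; "))
  }
  val
}

#' Run the full synthetic study
#'
#' Orchestrates simulate, preprocess, inverse, oscillations, features,
#' classify and stats into one reproducible report: per-subject ROI
#' activation contrasts with one-sample t-tests, the hypothesis-driven
#' ROI-band power and ERD/ERS tables, correlation/coherence connectivity
#' matrices and their contrasts, the four-class grouped-CV evaluation, the
#' four LOSO binary tasks, the cross-mode transfer test, and FDR-annotated
#' statistics grouped into test families. Identical `(config, seed)` yields
#' an identical report.
#'
#' @param config a [simConfig()]; use [quickConfig()] for fast runs.
#' @param seed master seed (defaults to `config$seed`).
#' @param n_sources toy-leadfield sources.
#' @param snr,loose,depth inverse-operator parameters.
#' @param spec a [classifierSpec()].
#' @param k1,k2 feature-selection sizes.
#' @param run_loso,run_transfer toggle the expensive evaluation blocks.
#' @param coherence_band band for coherence connectivity (Hz).
#' @return A `StudyReport` list; see Details.
#' @export
runStudy <- function(config = quickConfig(), seed = config$seed,
                     n_sources = 60, snr = 3, loose = 0.2, depth = 0.8,
                     spec = classifierSpec(n_trees = 300),
                     k1 = 200L, k2 = 100L, run_loso = TRUE,
                     run_transfer = TRUE, coherence_band = c(4, 7)) {
  stopifnot(inherits(config, "SimConfig"))
  config$seed <- as.integer(seed)

  # simulate + preprocess
  epo_list <- list(); gt <- list()
  for (s in seq_len(config$n_subjects)) {
    g <- generateRecording(config, s)
    gt[[s]] <- g$ground_truth
    epo_list[[s]] <- preprocessRecording(g$recording)
  }
  epochs <- concatEpochs(epo_list)
  labs <- as.character(epochLabels(epochs))
  info <- groupTable(epochs)

  # inverse on common-average data
  epochs_avg <- commonAverageEpochs(epochs)
  lf <- makeToyLeadfield(n_channels = length(channelNames(epochs)),
                         n_sources = n_sources,
                         geometry_seed = childSeed(seed, 31L),
                         channel_names = channelNames(epochs))
  ncov <- noiseCovariance(epochs_avg)
  inv <- makeInverse(lf, ncov, snr = snr, loose = loose, depth = depth)
  stcs <- applyInverseDSPM(epochs_avg, inv)
  rois <- names(roiMasks(lf))
  tc <- lapply(stcs, roiTimecourse, roi_masks = roiMasks(lf))

  # per-subject, per-condition ROI window means (0.1-0.8 s)
  fs <- samplingRate(epochs)
  widx <- windowIndices(c(0.1, 0.8), epochs@tmin, fs, dim(epochs@data)[3])
  wmean <- t(vapply(tc, function(m) rowMeans(m[, widx, drop = FALSE]),
                    numeric(length(rois))))
  subjects <- sort(unique(info$subject))
  condMeans <- function(vals) {
    out <- array(NA_real_, c(length(subjects), 4),
                 dimnames = list(subjects, conditionLevels()))
    for (i in seq_along(subjects)) for (cd in conditionLevels()) {
      sel <- info$subject == subjects[i] & labs == cd
      if (any(sel)) out[i, cd] <- mean(vals[sel])
    }
    out
  }
  roi_rows <- list()
  for (r in seq_along(rois)) {
    cm <- condMeans(wmean[, r])
    for (cp in roiContrastPairs()) {
      dvals <- cm[, cp[1]] - cm[, cp[2]]
      if (length(subjects) >= 2 && stats::sd(dvals) > 0) {
        tt <- oneSampleT(dvals, family = "roi-activation")
      } else {
        tt <- data.frame(estimate = mean(dvals), t = NA, df = NA,
                         p_raw = NA, p_fdr = NA, cohen_d = NA,
                         ci_low = NA, ci_high = NA, tails = "two",
                         family = "roi-activation", degenerate = TRUE)
      }
      tt$roi <- rois[r]
      tt$contrast <- paste(cp[1], "-", cp[2])
      roi_rows[[length(roi_rows) + 1L]] <- tt
    }
  }
  roi_table <- do.call(rbind, roi_rows)

  # hypothesis-driven ROI-band power and ERD/ERS
  plan <- roiBandPlan()
  bands <- bandDefs("canonical")
  pow_rows <- list(); erd_rows <- list()
  for (k in seq_len(nrow(plan))) {
    r <- match(plan$roi[k], rois)
    b <- bands[bands$name == plan$band[k], ]
    band <- c(b$lo, b$hi)
    pw <- collectWarnings(vapply(tc, function(m)
      bandPower(m[r, ], band, fs, tmin = epochs@tmin,
                window = c(0.1, 0.8)), numeric(1)))
    cm <- condMeans(log(pmax(pw, .Machine$double.xmin)))
    # ERD/ERS from condition-average powers (ratio of means)
    roi_tc <- t(vapply(tc, function(m) m[r, ], numeric(dim(epochs@data)[3])))
    cme <- array(NA_real_, c(length(subjects), 4),
                 dimnames = list(subjects, conditionLevels()))
    for (i in seq_along(subjects)) for (cdn in conditionLevels()) {
      sel <- info$subject == subjects[i] & labs == cdn
      if (any(sel))
        cme[i, cdn] <- collectWarnings(
          erdErsAveraged(roi_tc[sel, , drop = FALSE], band, fs,
                         tmin = epochs@tmin))
    }
    for (cp in roiContrastPairs()[1:2]) { # mode contrasts per difficulty
      dv <- cm[, cp[1]] - cm[, cp[2]]
      tt <- if (length(subjects) >= 2 && stats::sd(dv) > 0)
        oneSampleT(dv, family = "frequency-modulation")
      else data.frame(estimate = mean(dv), t = NA, df = NA, p_raw = NA,
                      p_fdr = NA, cohen_d = NA, ci_low = NA, ci_high = NA,
                      tails = "two", family = "frequency-modulation",
                      degenerate = TRUE)
      tt$roi <- plan$roi[k]; tt$band <- plan$band[k]
      tt$metric <- "log-band-power"
      tt$contrast <- paste(cp[1], "-", cp[2])
      pow_rows[[length(pow_rows) + 1L]] <- tt
    }
    erd_rows[[length(erd_rows) + 1L]] <- data.frame(
      roi = plan$roi[k], band = plan$band[k],
      condition = conditionLevels(),
      erd_ers = colMeans(cme, na.rm = TRUE))
  }
  pow_table <- do.call(rbind, pow_rows)
  erd_table <- do.call(rbind, erd_rows)

  # connectivity on concatenated active-window ROI time courses
  conn <- list()
  for (cd in conditionLevels()) {
    sel <- which(labs == cd)
    cat_tc <- do.call(cbind, lapply(sel, function(i)
      tc[[i]][, widx, drop = FALSE]))
    conn[[cd]] <- list(
      correlation = connectivityMatrix(cat_tc, "correlation",
                                       condition = cd),
      coherence = connectivityMatrix(cat_tc, "coherence", fs = fs,
                                     band = coherence_band,
                                     n_segments = 8, condition = cd))
  }
  conn_contrasts <- list(
    "MD-Easy - AD-Easy" = connectivityContrast(
      conn[["MD-Easy"]]$coherence, conn[["AD-Easy"]]$coherence),
    "MD-Hard - AD-Hard" = connectivityContrast(
      conn[["MD-Hard"]]$coherence, conn[["AD-Hard"]]$coherence),
    "MD: Hard - Easy (corr)" = connectivityContrast(
      conn[["MD-Hard"]]$correlation, conn[["MD-Easy"]]$correlation),
    "AD: Hard - Easy (corr)" = connectivityContrast(
      conn[["AD-Hard"]]$correlation, conn[["AD-Easy"]]$correlation))

  # sensor-level features and classification
  features <- extractFeatures(epochs)
  cv <- runCV(features, foldPlan(seed = childSeed(seed, 41L)), spec,
              k1 = k1, k2 = k2)
  loso <- NULL
  if (run_loso && length(subjects) >= 3) {
    loso <- lapply(c("mode", "difficulty", "difficulty-MD",
                     "difficulty-AD"),
                   function(tk) runLOSO(features, tk, spec, k1, k2,
                                        seed = childSeed(seed, 42L)))
    names(loso) <- c("mode", "difficulty", "difficulty-MD", "difficulty-AD")
  }
  transfer <- if (run_transfer)
    crossModeTransfer(features, spec, k1, k2,
                      seed = childSeed(seed, 43L)) else NULL

  stats_table <- adjustFamilies(rbind(
    roi_table[, c("estimate", "t", "df", "p_raw", "p_fdr", "cohen_d",
                  "ci_low", "ci_high", "tails", "family", "degenerate")],
    pow_table[, c("estimate", "t", "df", "p_raw", "p_fdr", "cohen_d",
                  "ci_low", "ci_high", "tails", "family", "degenerate")]))
  stats_table$label <- c(
    paste(roi_table$roi, roi_table$contrast),
    paste(pow_table$roi, pow_table$band, pow_table$contrast))

  manifest <- list(
    config = config[setdiff(names(config),
                            c("effect_table", "coupling_table"))],
    n_effects = length(config$effect_table),
    n_couplings = length(config$coupling_table),
    seed = seed,
    version = as.character(utils::packageVersion("engageEEG")),
    checksums = list(epochs = chk(epochs@data),
                     features = chk(SummarizedExperiment::assay(features)),
                     kernel = chk(inv@kernel)))

  structure(list(roi_contrasts = roi_table, power = pow_table,
                 erd_ers = erd_table, connectivity = conn,
                 connectivity_contrasts = conn_contrasts, cv = cv,
                 loso = loso, transfer = transfer,
                 stats = stats_table, ground_truth = gt,
                 manifest = manifest),
            class = "StudyReport")
}

#' @export
print.StudyReport <- function(x, ...) {
  cat("StudyReport\n")
  cat(sprintf("  4-class CV accuracy: %.3f +/- %.3f (macro-F1 %.3f)\n",
              x$cv$accuracy, x$cv$accuracy_sd, x$cv$macro_f1))
  if (!is.null(x$loso))
    for (tk in names(x$loso))
      cat(sprintf("  LOSO %-13s accuracy %.3f (p = %.3g)\n", tk,
                  x$loso[[tk]]$mean_accuracy, x$loso[[tk]]$p))
  if (!is.null(x$transfer))
    cat(sprintf("  cross-mode transfer accuracy %.3f (p = %.3g)\n",
                x$transfer$accuracy, x$transfer$p))
  cat(sprintf("  %d statistics rows, %d FDR survivors at q = 0.05\n",
              nrow(x$stats), sum(x$stats$survives_fdr, na.rm = TRUE)))
  invisible(x)
}
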