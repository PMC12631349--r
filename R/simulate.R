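#' @include AllClasses.R utils.R
NULL

# The generator plants condition effects as band-limited oscillations on top
# of a spatially-correlated 1/f background. Condition multipliers are defined
# on the band-POWER scale (amplitudes are scaled by sqrt(multiplier)), so a
# planted theta multiplier ratio of 2 between MD and AD shows up as a factor
# ~2 in Welch band power on the target channels.

#' Describe a planted condition effect
#'
#' A band-limited oscillation added to a group of channels whose power is
#' scaled per condition. Event-locked effects (`tonic = FALSE`) are present
#' only during the segment, producing condition-dependent band power and
#' synchronization relative to the pre-onset baseline. Tonic effects run
#' through the whole recording at base power and are rescaled during each
#' segment's active period, which is how a planted mu-rhythm
#' desynchronization (power drop, negative ERD) is emulated.
#'
#' @param name identifier used in ground-truth records and error messages.
#' @param channels channel subset carrying the effect.
#' @param band numeric `c(lo, hi)` in Hz.
#' @param base_amplitude oscillation standard deviation in microvolts at
#'   multiplier 1.
#' @param multipliers named numeric, band-power ratio per condition; names
#'   must be [conditionLevels()]. All must be positive.
#' @param tonic logical; see Details.
#' @return A `PlantedEffect` list.
#' @export
plantedEffect <- function(name, channels, band, base_amplitude,
                          multipliers, tonic = FALSE) {
  stopifnot(length(channels) >= 1, length(band) == 2)
  if (band[1] >= band[2])
    stop(sprintf("effect '%s': band lo must be < hi", name))
  if (!all(conditionLevels() %in% names(multipliers)))
    stop(sprintf("effect '%s': multipliers must name all four conditions", name))
  if (any(multipliers <= 0))
    stop(sprintf("effect '%s': multipliers must be positive", name))
  structure(list(name = name, channels = channels, band = band,
                 base_amplitude = base_amplitude,
                 multipliers = multipliers[conditionLevels()],
                 tonic = isTRUE(tonic)),
            class = "PlantedEffect")
}

#' Describe a planted inter-regional coupling
#'
#' Two channel groups share a common band-limited source mixed with
#' independent band-limited noise. With mixing weight `a` on the shared
#' source and `sqrt(1 - a^2)` on the private noise (all unit variance), the
#' magnitude-squared coherence between a channel of group A and one of group
#' B is `a^4` in band; the generator therefore uses `a^2 = sqrt(strength)`
#' to hit a target coherence `strength`.
#'
#' @param name identifier.
#' @param group_a,group_b channel subsets.
#' @param band numeric `c(lo, hi)` Hz.
#' @param strength named numeric in `[0, 1]`, target coherence per condition.
#' @param amplitude oscillation standard deviation in microvolts.
#' @return A `PlantedCoupling` list.
#' @export
plantedCoupling <- function(name, group_a, group_b, band, strength,
                            amplitude = 3) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (!all(conditionLevels() %in% names(strength)))
    stop(sprintf("coupling '%s': strength must name all four conditions", name))
  if (any(strength < 0 | strength > 1))
    stop(sprintf("coupling '%s': strength must lie in [0, 1]", name))
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 band = band, strength = strength[conditionLevels()],
                 amplitude = amplitude),
            class = "PlantedCoupling")
}

#' Default planted effects of the study conditions
#'
#' Mirrors the directions reported for the engagement-mode and complexity
#' contrasts: frontal-midline theta raised under manual driving (more so
#' when hard), occipito-parietal alpha raised under manual driving, motor
#' beta raised under manual-hard, and a tonic motor mu rhythm suppressed
#' under manual-easy (planting an ERD of roughly -50%).
#'
#' @return List of [plantedEffect()] objects.
#' @export
defaultEffectTable <- function() {
  list(
    plantedEffect("frontal_theta", c("AF3", "Fz", "AF4"), c(4, 7), 4,
      c("MD-Easy" = 2.0, "MD-Hard" = 2.6, "AD-Easy" = 1.0, "AD-Hard" = 1.1)),
    plantedEffect("occipital_alpha", c("O1", "O2", "PO3", "PO4", "PO7", "PO8"),
      c(8, 12), 4,
      c("MD-Easy" = 2.0, "MD-Hard" = 1.6, "AD-Easy" = 1.0, "AD-Hard" = 1.2)),
    plantedEffect("parietal_alpha", c("P3", "Pz", "P4"), c(8, 12), 3,
      c("MD-Easy" = 1.8, "MD-Hard" = 1.5, "AD-Easy" = 1.0, "AD-Hard" = 1.1)),
    plantedEffect("motor_beta", c("C3", "Cz", "C4"), c(13, 30), 3,
      c("MD-Easy" = 1.2, "MD-Hard" = 1.8, "AD-Easy" = 1.0, "AD-Hard" = 1.0)),
    plantedEffect("motor_mu_tonic", c("C3", "C4"), c(8, 13), 4,
      c("MD-Easy" = 0.4, "MD-Hard" = 0.8, "AD-Easy" = 1.0, "AD-Hard" = 1.0),
      tonic = TRUE))
}

#' Default planted couplings
#'
#' Fronto-parietal theta- and beta-band coherent coupling, stronger under
#' manual driving than under passive replay.
#'
#' @return List of [plantedCoupling()] objects.
#' @export
defaultCouplingTable <- function() {
  list(
    plantedCoupling("frontoparietal_theta", c("F3", "Fz", "F4"),
      c("P3", "Pz", "P4"), c(4, 7),
      c("MD-Easy" = 0.55, "MD-Hard" = 0.6, "AD-Easy" = 0.2, "AD-Hard" = 0.2),
      amplitude = 3),
    plantedCoupling("frontoparietal_beta", c("F3", "Fz", "F4"),
      c("P3", "Pz", "P4"), c(13, 20),
      c("MD-Easy" = 0.45, "MD-Hard" = 0.55, "AD-Easy" = 0.15, "AD-Hard" = 0.2),
      amplitude = 2.5))
}

#' Simulation configuration
#'
#' Defines the synthetic study: montage, session structure (manual-driving
#' laps followed by replay laps, segments alternating Easy/Hard within each
#' lap), background-noise model, planted effects and couplings, and the
#' master seed. Defaults reproduce the study conditions: 11 subjects, 500 Hz,
#' 29-channel montage plus earlobe references, 5 laps per mode with 20
#' alternating segments per lap.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param fs sampling rate, Hz.
#' @param channel_names scalp montage (default [cognionicsMontage()]).
#' @param include_reference append A1/A2 earlobe reference channels.
#' @param laps_per_subject laps per engagement mode.
#' @param segments_per_lap segments per lap, alternating Easy/Hard.
#' @param segment_duration segment length in seconds (the source study does
#'   not state one; 6 s is this package's documented choice).
#' @param noise_exponent 1/f slope of the background.
#' @param background_sd background standard deviation, microvolts.
#' @param sensor_noise_sd white sensor noise, microvolts.
#' @param effect_table list of [plantedEffect()].
#' @param coupling_table list of [plantedCoupling()].
#' @param subject_sd_mode log-scale between-subject jitter of the
#'   engagement-mode component of every planted effect. The mode contrast
#'   (MD vs AD) of each effect's log-multipliers is scaled per subject by
#'   `exp(rnorm(1, 0, subject_sd_mode))`; the default 0.6 makes mode
#'   signatures strongly subject-specific, emulating the reported
#'   inter-individual variability of engagement signatures.
#' @param subject_sd_diff as `subject_sd_mode` but for the task-complexity
#'   (Easy vs Hard) component; the default 0.2 keeps complexity signatures
#'   comparatively consistent across subjects.
#' @param subject_sd_amp log-scale jitter of each subject's overall
#'   amplitude (default 0.2, i.e. a between-subject coefficient of
#'   variation around 20%).
#' @param randomize_order randomize Easy/Hard order within laps instead of
#'   strict alternation (for order-confound experiments).
#' @param seed master seed; all subject/segment substreams derive from it.
#' @return A `SimConfig` list.
#' @export
simConfig <- function(n_subjects = 11, fs = 500,
                      channel_names = cognionicsMontage(),
                      include_reference = TRUE,
                      laps_per_subject = 5, segments_per_lap = 20,
                      segment_duration = 6, noise_exponent = 1,
                      background_sd = 10, sensor_noise_sd = 2,
                      effect_table = defaultEffectTable(),
                      coupling_table = defaultCouplingTable(),
                      subject_sd_mode = 0.6, subject_sd_diff = 0.2,
                      subject_sd_amp = 0.2, randomize_order = FALSE,
                      seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (anyDuplicated(channel_names)) stop("channel_names must be unique")
  if (abs(segment_duration * fs - round(segment_duration * fs)) > 1e-9)
    stop("segment_duration * fs must be an integer sample count")
  for (e in effect_table) {
    if (e$band[2] >= fs / 2)
      stop(sprintf("effect '%s': band upper edge %g Hz is not below fs/2 = %g Hz",
                   e$name, e$band[2], fs / 2))
    bad <- setdiff(e$channels, channel_names)
    if (length(bad))
      stop(sprintf("effect '%s': unknown channels %s", e$name,
                   paste(bad, collapse = ", ")))
  }
  for (cp in coupling_table) {
    if (cp$band[2] >= fs / 2)
      stop(sprintf("coupling '%s': band upper edge %g Hz is not below fs/2 = %g Hz",
                   cp$name, cp$band[2], fs / 2))
    bad <- setdiff(c(cp$group_a, cp$group_b), channel_names)
    if (length(bad))
      stop(sprintf("coupling '%s': unknown channels %s", cp$name,
                   paste(bad, collapse = ", ")))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), fs = fs,
    channel_names = channel_names, include_reference = include_reference,
    laps_per_subject = as.integer(laps_per_subject),
    segments_per_lap = as.integer(segments_per_lap),
    segment_duration = segment_duration, noise_exponent = noise_exponent,
    background_sd = background_sd, sensor_noise_sd = sensor_noise_sd,
    effect_table = effect_table, coupling_table = coupling_table,
    subject_sd_mode = subject_sd_mode, subject_sd_diff = subject_sd_diff,
    subject_sd_amp = subject_sd_amp,
    randomize_order = isTRUE(randomize_order),
    seed = as.integer(seed)), class = "SimConfig")
}

#' Reduced-scale configuration profile
#'
#' Three subjects and two laps per mode, the profile used for fast
#' continuous-integration runs of the full study.
#'
#' @param ... overrides passed to [simConfig()].
#' @return A `SimConfig`.
#' @export
quickConfig <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 3, laps_per_subject = 2)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# Segment schedule of one subject: lap-level mode blocks (all MD laps first,
# mirroring the fixed session order), Easy/Hard alternation within lap.
segmentSchedule <- function(config, subject_id) {
  L <- config$laps_per_subject
  spl <- config$segments_per_lap
  laps <- rep(seq_len(2L * L), each = spl)
  mode <- ifelse(laps <= L, "MD", "AD")
  seg_in_lap <- rep(seq_len(spl), times = 2L * L)
  difficulty <- rep(c("Easy", "Hard"), length.out = spl)
  diff_all <- unlist(lapply(seq_len(2L * L), function(l) {
    if (config$randomize_order) sample(rep(c("Easy", "Hard"),
                                           length.out = spl))
    else difficulty
  }))
  data.frame(subject = subject_id, lap = laps, segment = seg_in_lap,
             mode = mode, difficulty = diff_all,
             condition = paste(mode, diff_all, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic recording for one subject
#'
#' Builds the continuous signal as 1/f background with shared low-rank
#' spatial structure, plus per-segment band-limited oscillations scaled by
#' the condition multipliers, plus coupled common-source oscillations, plus
#' white sensor noise. Events mark every segment onset. Bit-identical output
#' for identical `(config, subject_id)`.
#'
#' @param config a [simConfig()].
#' @param subject_id subject index in `1:n_subjects`.
#' @return List with elements `recording` ([EEGRecording-class]), `events`
#'   (data.frame) and `ground_truth` (list: segment table, per-subject
#'   realized effect multipliers and coupling targets, seed).
#' @export
generateRecording <- function(config, subject_id) {
  stopifnot(inherits(config, "SimConfig"))
  if (subject_id < 1 || subject_id > config$n_subjects)
    stop("subject_id must be in 1:n_subjects")
  seed <- childSeed(config$seed, subject_id)
  localSeed(seed, {
    fs <- config$fs
    chans <- config$channel_names
    if (config$include_reference) chans <- c(chans, "A1", "A2")
    C <- length(chans)
    sched <- segmentSchedule(config, subject_id)
    nseg <- nrow(sched)
    seg_len <- as.integer(round(config$segment_duration * fs))
    pad <- as.integer(fs) # 1 s lead-in/out so -0.4 s epochs fit
    n <- 2L * pad + nseg * seg_len
    sched$onset_sample <- pad + (seq_len(nseg) - 1L) * seg_len + 1L

    # spatially-correlated 1/f background + independent channel background
    K <- min(6L, C)
    lat <- vapply(seq_len(K), function(k) pinkNoise(n, config$noise_exponent),
                  numeric(n))
    B <- matrix(stats::rnorm(K * C), K, C)
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    shared <- lat %*% B
    own <- vapply(seq_len(C), function(k) pinkNoise(n, config$noise_exponent),
                  numeric(n))
    X <- (sqrt(0.5) * shared + sqrt(0.5) * own) * config$background_sd

    # per-subject effect-size jitter: the mode and difficulty components of
    # each effect's log-multipliers are scaled by independent log-normal
    # factors, preserving direction while varying magnitude; the mode
    # component varies more across subjects than the complexity component
    gamma_m <- exp(stats::rnorm(length(config$effect_table), 0,
                                config$subject_sd_mode))
    gamma_d <- exp(stats::rnorm(length(config$effect_table), 0,
                                config$subject_sd_diff))
    amp_scale <- exp(stats::rnorm(1, 0, config$subject_sd_amp))
    ramp <- max(1L, as.integer(round(0.05 * fs)))

    jitterMultipliers <- function(m, gm, gd) {
      lm <- log(m)
      g <- mean(lm)
      dm <- mean(lm[c("MD-Easy", "MD-Hard")]) -
        mean(lm[c("AD-Easy", "AD-Hard")])
      d_md <- lm[["MD-Hard"]] - lm[["MD-Easy"]]
      d_ad <- lm[["AD-Hard"]] - lm[["AD-Easy"]]
      out <- c(
        "MD-Easy" = g + gm * dm / 2 - gd * d_md / 2,
        "MD-Hard" = g + gm * dm / 2 + gd * d_md / 2,
        "AD-Easy" = g - gm * dm / 2 - gd * d_ad / 2,
        "AD-Hard" = g - gm * dm / 2 + gd * d_ad / 2)
      exp(out)
    }

    eff_real <- list()
    for (j in seq_along(config$effect_table)) {
      e <- config$effect_table[[j]]
      mult <- jitterMultipliers(e$multipliers, gamma_m[j], gamma_d[j])
      eff_real[[e$name]] <- mult
      rows <- match(e$channels, chans)
      if (e$tonic) {
        osc <- bandNoise(n, fs, e$band[1], e$band[2])
        gain <- rep(1, n)
        for (s in seq_len(nseg)) {
          i0 <- sched$onset_sample[s]
          idx <- i0:(i0 + seg_len - 1L)
          g <- sqrt(mult[[sched$condition[s]]])
          gain[idx] <- 1 + (g - 1) * envelopeRamp(seg_len, ramp)
        }
        wave <- e$base_amplitude * amp_scale * osc * gain
        X[, rows] <- X[, rows] + wave
      } else {
        for (s in seq_len(nseg)) {
          i0 <- sched$onset_sample[s]
          idx <- i0:(i0 + seg_len - 1L)
          a <- e$base_amplitude * amp_scale *
            sqrt(mult[[sched$condition[s]]])
          wave <- a * bandNoise(seg_len, fs, e$band[1], e$band[2]) *
            envelopeRamp(seg_len, ramp)
          X[idx, rows] <- X[idx, rows] + wave
        }
      }
    }

    coup_real <- list()
    for (cp in config$coupling_table) {
      coup_real[[cp$name]] <- cp$strength
      rows_a <- match(cp$group_a, chans)
      rows_b <- match(cp$group_b, chans)
      for (s in seq_len(nseg)) {
        i0 <- sched$onset_sample[s]
        idx <- i0:(i0 + seg_len - 1L)
        cstr <- cp$strength[[sched$condition[s]]]
        a2 <- sqrt(cstr)            # per-channel shared-power fraction
        env <- envelopeRamp(seg_len, ramp)
        sh <- bandNoise(seg_len, fs, cp$band[1], cp$band[2])
        for (r in c(rows_a, rows_b)) {
          priv <- bandNoise(seg_len, fs, cp$band[1], cp$band[2])
          X[idx, r] <- X[idx, r] + cp$amplitude * env *
            (sqrt(a2) * sh + sqrt(1 - a2) * priv)
        }
      }
    }

    X <- X + matrix(stats::rnorm(n * C, 0, config$sensor_noise_sd), n, C)

    events <- data.frame(onset_sample = sched$onset_sample,
                         condition = sched$condition,
                         subject = sched$subject, lap = sched$lap,
                         segment = sched$segment,
                         stringsAsFactors = FALSE)
    dat <- t(X)
    rownames(dat) <- chans
    rec <- EEGRecording(dat, fs, events = events)
    gt <- list(segments = sched, effects = eff_real,
               couplings = coup_real, effect_gamma_mode = gamma_m,
               effect_gamma_diff = gamma_d,
               amplitude_scale = amp_scale, seed = seed)
    list(recording = rec, events = events, ground_truth = gt)
  })
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds blink-like low-frequency transients on frontal channels (raised
#' cosine pulses, ~300 ms) at Poisson times, and broadband high-frequency
#' EMG bursts on named channels. With `blink_rate = 0` and `emg_sd = 0` the
#' recording is returned unchanged. Artifact onsets are annotated in the
#' returned recording's `artifacts` slot.
#'
#' @param recording an [EEGRecording-class].
#' @param blink_rate blink rate in Hz (events per second), >= 0.
#' @param blink_channels channels receiving blinks.
#' @param blink_amplitude peak blink amplitude, microvolts.
#' @param emg_channels channels receiving EMG bursts.
#' @param emg_sd EMG burst standard deviation, microvolts (0 disables).
#' @param emg_rate burst rate in Hz.
#' @param seed RNG seed.
#' @return The recording with artifacts added and annotated.
#' @export
injectArtifacts <- function(recording, blink_rate = 0,
                            blink_channels = c("Fp1", "Fp2", "AF3", "AF4"),
                            blink_amplitude = 80,
                            emg_channels = character(), emg_sd = 0,
                            emg_rate = 0.1, seed = 1L) {
  stopifnot(is(recording, "EEGRecording"))
  if (blink_rate < 0 || emg_sd < 0 || emg_rate < 0)
    stop("rates and amplitudes must be >= 0")
  chans <- channelNames(recording)
  bad <- setdiff(c(if (blink_rate > 0) blink_channels,
                   if (emg_sd > 0) emg_channels), chans)
  if (length(bad))
    stop(sprintf("unknown channel name(s): %s", paste(bad, collapse = ", ")))
  if (blink_rate == 0 && emg_sd == 0) return(recording)
  localSeed(seed, {
    X <- recording@data
    fs <- recording@fs
    n <- ncol(X)
    ann <- recording@artifacts
    if (blink_rate > 0) {
      nb <- stats::rpois(1, blink_rate * n / fs)
      if (nb > 0) {
        onsets <- sort(sample.int(n - as.integer(0.4 * fs), nb))
        pl <- as.integer(round(0.3 * fs))
        pulse <- blink_amplitude * (0.5 * (1 - cos(2 * pi * seq_len(pl) / pl)))^2
        rows <- match(blink_channels, chans)
        for (o in onsets) {
          idx <- o:(o + pl - 1L)
          X[rows, idx] <- X[rows, idx] +
            matrix(pulse, length(rows), pl, byrow = TRUE)
        }
        ann <- rbind(ann, data.frame(onset_sample = onsets, type = "blink",
                                     channel = paste(blink_channels,
                                                     collapse = "|")))
      }
    }
    if (emg_sd > 0 && length(emg_channels)) {
      nb <- stats::rpois(1, emg_rate * n / fs)
      if (nb > 0) {
        bl <- as.integer(round(0.5 * fs))
        onsets <- sort(sample.int(n - bl, nb))
        rows <- match(emg_channels, chans)
        hi <- min(0.45 * fs, 120)
        for (o in onsets) {
          idx <- o:(o + bl - 1L)
          for (r in rows) {
            burst <- emg_sd * bandNoise(bl, fs, 20, hi) *
              envelopeRamp(bl, as.integer(0.05 * fs))
            X[r, idx] <- X[r, idx] + burst
          }
        }
        ann <- rbind(ann, data.frame(onset_sample = onsets, type = "emg",
                                     channel = paste(emg_channels,
                                                     collapse = "|")))
      }
    }
    out <- recording
    out@data <- X
    out@artifacts <- ann[order(ann$onset_sample), , drop = FALSE]
    validObject(out)
    out
  })
}
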