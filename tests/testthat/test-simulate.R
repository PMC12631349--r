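test_that("identical (config, seed) gives bit-identical recordings", {
  cfg <- microConfig()
  a <- generateRecording(cfg, 1)
  b <- generateRecording(cfg, 1)
  expect_identical(signalData(a$recording), signalData(b$recording))
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generateRecording(cfg, 2)
  expect_false(identical(signalData(a$recording), signalData(c2$recording)))
})

test_that("session structure follows the lap/segment schedule", {
  cfg <- microConfig()
  g <- generateRecording(cfg, 1)
  ev <- eventTable(g$recording)
  expect_equal(nrow(ev), 2 * 6) # 2 laps x 6 segments
  # MD laps precede AD laps; Easy/Hard alternate within lap
  expect_equal(unique(sub("-.*", "", ev$condition[ev$lap == 1])), "MD")
  expect_equal(unique(sub("-.*", "", ev$condition[ev$lap == 2])), "AD")
  expect_equal(sub(".*-", "", ev$condition[1:4]),
               c("Easy", "Hard", "Easy", "Hard"))
  expect_false(is.unsorted(ev$onset_sample))
  # onsets spaced by exactly one segment
  expect_true(all(diff(ev$onset_sample[1:6]) == 2 * 250))
})

test_that("with no planted effects band power is equal across conditions", {
  cfg <- simConfig(n_subjects = 1, fs = 200, laps_per_subject = 3,
                   segments_per_lap = 20, segment_duration = 1,
                   effect_table = list(), coupling_table = list(),
                   subject_sd_amp = 0, seed = 5)
  g <- generateRecording(cfg, 1)
  rec <- bandpassFIR(rereference(g$recording, "earlobe"), 2, 36)
  ev <- eventTable(g$recording)
  seg_len <- 200
  pw <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$onset_sample[i]:(ev$onset_sample[i] + seg_len - 1)
    bandPower(signalData(rec)["Fz", idx], c(4, 7), 200)
  }, numeric(1))
  md <- pw[grepl("^MD", ev$condition)]
  ad <- pw[grepl("^AD", ev$condition)]
  ratio <- mean(md) / mean(ad)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("default config plants MD > AD frontal theta (direction)", {
  cfg <- simConfig(n_subjects = 1, fs = 250, laps_per_subject = 2,
                   segments_per_lap = 10, segment_duration = 2, seed = 3)
  g <- generateRecording(cfg, 1)
  rec <- rereference(g$recording, "earlobe")
  ev <- eventTable(g$recording)
  seg_len <- 2 * 250
  theta <- vapply(seq_len(nrow(ev)), function(i) {
    idx <- ev$onset_sample[i]:(ev$onset_sample[i] + seg_len - 1)
    mean(vapply(c("AF3", "Fz", "AF4"), function(ch)
      bandPower(signalData(rec)[ch, idx], c(4, 7), 250), numeric(1)))
  }, numeric(1))
  expect_gt(mean(theta[grepl("^MD", ev$condition)]),
            mean(theta[grepl("^AD", ev$condition)]))
})

test_that("invalid bands and channels are rejected with the effect named", {
  expect_error(
    simConfig(fs = 100, effect_table = list(plantedEffect(
      "bad_beta", "Cz", c(13, 60), 1,
      c("MD-Easy" = 1, "MD-Hard" = 1, "AD-Easy" = 1, "AD-Hard" = 1)))),
    "bad_beta")
  expect_error(plantedEffect("neg", "Cz", c(4, 7), 1,
    c("MD-Easy" = -1, "MD-Hard" = 1, "AD-Easy" = 1, "AD-Hard" = 1)),
    "positive")
  expect_error(plantedCoupling("c", "F3", "P3", c(4, 7),
    c("MD-Easy" = 1.2, "MD-Hard" = 1, "AD-Easy" = 1, "AD-Hard" = 1)),
    "\\[0, 1\\]")
  expect_error(simConfig(segment_duration = 1 / 3), "integer sample count")
})

test_that("artifact injector: identity at zero rates, counts and topography", {
  cfg <- microConfig()
  rec <- generateRecording(cfg, 1)$recording
  expect_identical(injectArtifacts(rec, blink_rate = 0, emg_sd = 0), rec)
  expect_error(injectArtifacts(rec, blink_rate = 1,
                               blink_channels = "NoSuch"), "NoSuch")

  # ~15 blinks expected at 0.25 Hz on a 60 s recording
  long <- noiseRecording(n_ch = 6, fs = 100, dur = 60, n_events = 4,
                         channels = c("Fp1", "Fp2", "AF3", "AF4", "Cz", "Pz"))
  counts <- vapply(1:20, function(s) {
    out <- injectArtifacts(long, blink_rate = 0.25, seed = s)
    sum(out@artifacts$type == "blink")
  }, numeric(1))
  expect_gt(mean(counts), 10)
  expect_lt(mean(counts), 20)

  # blink power concentrates at low frequencies on frontal channels
  out <- injectArtifacts(long, blink_rate = 0.5, seed = 2)
  lofreq_var <- function(rec) {
    f <- bandpassFIR(rec, 0.5, 4)
    apply(signalData(f), 1, var)
  }
  dv <- lofreq_var(out) - lofreq_var(long)
  frontal <- c("Fp1", "Fp2", "AF3", "AF4")
  expect_gt(min(dv[frontal]), max(dv[c("Cz", "Pz")]))
})

test_that("null generator is centrally calibrated (type-I error near 5%)", {
  # 500 micro replicates: paired per-segment MD-AD log band-power t-test
  # on effect-free recordings must reject at close to the nominal rate
  rej <- vapply(1:500, function(r) {
    cfg <- simConfig(n_subjects = 1, fs = 128, laps_per_subject = 1,
                     segments_per_lap = 10, segment_duration = 1,
                     channel_names = c("Fz", "Cz", "Pz"),
                     include_reference = FALSE, effect_table = list(),
                     coupling_table = list(), subject_sd_mode = 0,
                     subject_sd_diff = 0, subject_sd_amp = 0,
                     seed = 1000 + r)
    g <- generateRecording(cfg, 1)
    x <- signalData(bandpassFIR(g$recording, 4, 7, transition = 2))["Fz", ]
    ev <- eventTable(g$recording)
    pw <- vapply(ev$onset_sample, function(o) mean(x[o:(o + 127)]^2),
                 numeric(1))
    d <- log(pw[1:10]) - log(pw[11:20])
    t.test(d)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
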