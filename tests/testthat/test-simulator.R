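test_that("profile validation enforces the physiological invariants", {
  expect_error(subject_profile(heart_rate = 30), "heart_rate")
  expect_error(subject_profile(spo2 = c(finger_L = 0, finger_R = 98,
                                        toe_L = 97, toe_R = 97)), "spo2")
  expect_error(subject_profile(transit = c(earlobe = 0.3, arm = 0.16, wrist = 0.2,
                                           finger = 0.26, ankle = 0.3, toe = 0.36)),
               "transit")
})

test_that("the default channel table has 27 channels at their nominal rates", {
  ct <- channel_table()
  expect_equal(nrow(ct), 27)
  counts <- table(ct$kind)
  expect_equal(as.integer(counts[c("PPG", "ECG", "HS", "LS", "PPS",
                                   "CUFF_PRESSURE", "BODWS")]),
               c(4L, 1L, 1L, 1L, 6L, 6L, 8L))
  expect_true(all(ct$fs[ct$kind == "PPG"] == 400))
  expect_true(all(ct$fs[ct$kind == "ECG"] == 1600))
  expect_true(all(ct$fs[ct$kind %in% c("HS", "LS")] == 3200))
  expect_true(all(ct$fs[ct$kind %in% c("PPS", "CUFF_PRESSURE", "BODWS")] == 400))
  expect_equal(anyDuplicated(ct$channel_id), 0L)
})

test_that("simulation is deterministic given the profile seed", {
  sched <- tiny_schedule()
  ct <- channel_table()[c(1, 5, 7, 11, 17, 20), ]
  r1 <- simulate_recording(subject_profile(seed = 33), sched, ct)
  r2 <- simulate_recording(subject_profile(seed = 33), sched, ct)
  expect_identical(r1$channels$samples, r2$channels$samples)
  r3 <- simulate_recording(subject_profile(seed = 34), sched, ct)
  expect_false(identical(r1$channels$samples, r3$channels$samples))
})

test_that("noise-free jitter-free ECG has exactly periodic R peaks", {
  prof <- subject_profile(heart_rate = 60, rr_jitter_sd = 0,
                          noise_sd = c(ECG = 0), seed = 9)
  set.seed(9)
  ecg <- simulate_ecg(prof, 10, 1600)
  truth <- attr(ecg, "r_times")
  expect_true(length(truth) %in% c(10, 11))
  expect_equal(diff(truth), rep(1, length(truth) - 1), tolerance = 1e-12)
})

test_that("configured RR jitter is realized in the generated beat sequence", {
  prof <- subject_profile(heart_rate = 60, rr_jitter_sd = 0.05, seed = 4)
  set.seed(4)
  ecg <- simulate_ecg(prof, 310, 1600)
  rr <- diff(attr(ecg, "r_times"))
  expect_gt(length(rr), 250)
  expect_gt(sd(rr), 0.04)
  expect_lt(sd(rr), 0.06)
})

test_that("heart sounds carry the configured S2/S1 ratio and burst count", {
  prof <- subject_profile(heart_rate = 60, rr_jitter_sd = 0,
                          noise_sd = c(HS = 0, LS = 0), seed = 6)
  set.seed(6)
  r_times <- seq(0.5, 29.5, by = 1)
  snd <- simulate_sounds(prof, r_times, 30, 3200)
  fs <- 3200
  env <- abs(snd$hs)
  ratios <- vapply(r_times[1:29], function(r) {
    i0 <- round(r * fs); third <- round(fs / 3)
    s1 <- max(env[i0:(i0 + third)])
    s2 <- max(env[(i0 + third):(i0 + 2 * third)])
    s2 / s1
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.6), 0.1)
  # zero noise: exactly two bursts per cycle, seen on the smoothed envelope
  i0 <- round(r_times[3] * fs); i1 <- round(r_times[4] * fs)
  sm <- stats::filter(env, rep(1 / 64, 64), sides = 2)
  seg <- sm[i0:i1] > 0.05
  runs <- rle(as.vector(seg[!is.na(seg)]))
  expect_equal(sum(runs$values), 2)
})

test_that("the lung-sound envelope peaks at the respiration rate", {
  prof <- subject_profile(noise_sd = c(LS = 0), seed = 8)
  set.seed(8)
  snd <- simulate_sounds(prof, seq(0.5, 59.5, by = 1), 60, 3200)
  env <- moving_avg <- stats::filter(abs(snd$ls), rep(1 / 3200, 3200), sides = 2)
  env <- env[!is.na(env)]
  sp <- Mod(fft(env - mean(env)))
  fn <- 3200 / length(env)
  peak_hz <- (which.max(sp[2:round(1 / fn)]) ) * fn
  expect_equal(peak_hz, 0.25, tolerance = 0.2)
})

test_that("pulse amplitude under the cuff peaks at MAP and is occluded distally", {
  sched <- reduced_schedule()
  prof <- subject_profile(seed = 12)
  ct <- channel_table()
  keep <- c("ecg", "pps_wrist_L", "cuff_wrist_L", "ppg_finger_L", "ppg_earlobe_L")
  rec <- simulate_recording(prof, sched, ct[ct$channel_id %in% keep, ])
  w <- rec$segments
  fs <- 400
  # PPS envelope argmax over the deflation recovers the wrist MAP
  win <- w[w$rmps == "RMPS2", ]
  i1 <- floor(win$t_start * fs) + 1; i2 <- ceiling(win$t_end * fs)
  p <- recording_channel(rec, "cuff_wrist_L")[i1:i2]
  x <- recording_channel(rec, "pps_wrist_L")[i1:i2]
  s <- which.max(p)
  res <- suppressWarnings(compute_mpap(p[s:length(p)], x[s:length(x)], fs))
  # the raw (unsmoothed) envelope argmax is a cycle-quantized estimate of MAP
  expect_lt(abs(res$mpap - (80 + 40 / 3)), 5)
  # distal pulse flat-lines during the occlusive hold
  win4 <- w[w$rmps == "RMPS4", ]
  hold <- function(ch) {
    v <- recording_channel(rec, ch)
    v[(floor((win4$t_start + 10) * fs) + 1):ceiling((win4$t_end - 1) * fs)]
  }
  expect_lt(max(hold("ppg_finger_L")) - min(hold("ppg_finger_L")), 0.08)
  # while the earlobe keeps pulsing
  expect_gt(max(hold("ppg_earlobe_L")) - min(hold("ppg_earlobe_L")), 0.5)
})

test_that("earlobe channels are unaffected by the pressure phases", {
  fx <- cached_default_analysis()
  agg <- fx$ana$aggregates
  el <- agg[agg$channel_id == "ppg_earlobe_L" &
              agg$parameter %in% c("A_d", "K", "t_RWMACR") &
              agg$rmps %in% c("RMPS1", "RMPS4"), ]
  wide <- tidyr::pivot_wider(el[, c("parameter", "rmps", "mean")],
                             names_from = "rmps", values_from = "mean")
  expect_true(all(abs(wide$RMPS4 / wide$RMPS1 - 1) < 0.02))
})

test_that("dual-wavelength occlusion drift follows the configured signs", {
  sched <- reduced_schedule()
  prof <- subject_profile(occlusion_drift = c("660" = -6, "940" = 6), seed = 13)
  ct <- channel_table()
  ct <- ct[ct$channel_id %in% c("ecg", "bodws_finger_L_660", "bodws_finger_L_940"), ]
  rec <- simulate_recording(prof, sched, ct)
  w <- rec$segments
  fs <- 400
  win <- w[w$rmps == "RMPS4", ]
  # measure inside the fully occluded part of the hold (after the ramp)
  i1 <- floor((win$t_start + 10) * fs) + 1; i2 <- ceiling((win$t_end - 0.5) * fs)
  di660 <- diff(recording_channel(rec, "bodws_finger_L_660")[c(i1, i2)])
  di940 <- diff(recording_channel(rec, "bodws_finger_L_940")[c(i1, i2)])
  expect_lt(di660, 0)
  expect_gt(di940, 0)
  # opposite configured drifts give opposite last-minus-first differences
  expect_lt(abs(di660 + di940), abs(di660) * 0.2)
  # zero drift: DC constant through the occlusive hold
  prof0 <- subject_profile(occlusion_drift = c("660" = 0, "940" = 0),
                           noise_sd = c(BODWS = 0), seed = 13)
  rec0 <- simulate_recording(prof0, sched, ct)
  seg <- recording_channel(rec0, "bodws_finger_L_940")[i1:i2]
  expect_lt(max(seg) - min(seg), 1e-6)
})

test_that("quantization rounds half away from zero and clips to 14 bits", {
  expect_equal(quantize_adcv(100.4), 100L)
  expect_equal(quantize_adcv(100.5), 101L)
  expect_equal(quantize_adcv(16384), 16383L)
  expect_equal(quantize_adcv(-3), 0L)
  # round-trip error bounded by half a quantization step on a dense grid
  gain <- 37.5; offset <- 1000
  x <- seq(-20, 400, by = 0.01)
  x <- x[offset + gain * x >= 0 & offset + gain * x <= 16383]
  q <- quantize_adcv(x, gain, offset)
  back <- dequantize_adcv(q, gain, offset)
  expect_lte(max(abs(back - x)), 0.5 / gain + 1e-12)
})
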