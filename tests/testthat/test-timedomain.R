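test_that("K of an offset sinusoid equals mean over peak-to-peak analytically", {
  fs <- 400
  f0 <- 1.25
  t <- seq(0, 1 / f0, by = 1 / fs)
  x <- 2 + 0.5 * sin(2 * pi * f0 * t)
  p <- pulse_cycle_params(x, fs)
  k <- p$value[p$parameter == "K"]
  expect_equal(k, 2 / (2 * 0.5), tolerance = 0.01)
  # A_d is the full swing
  expect_equal(p$value[p$parameter == "A_d"], 1, tolerance = 0.01)
})

test_that("flat cycles are flagged rather than producing divisions by zero", {
  p <- pulse_cycle_params(rep(3, 100), 400)
  expect_equal(p$value[p$parameter == "A_d"], 0)
  expect_true(is.na(p$value[p$parameter == "K"]))
  expect_equal(p$flag[p$parameter == "K"], "flat_cycle")
  expect_true(is.na(p$value[p$parameter == "NMARR"]))
})

test_that("scaling behaviour: amplitudes scale linearly, shape indices are invariant", {
  set.seed(14)
  fs <- 400
  t <- seq(0, 0.9, by = 1 / fs)
  x <- 1 + exp(-((t - 0.2)^2) / 0.01) + 0.2 * sin(9 * t)
  p1 <- pulse_cycle_params(x, fs)
  p3 <- pulse_cycle_params(3 * x, fs)
  val <- function(p, nm) p$value[p$parameter == nm]
  expect_equal(val(p3, "A_d"), 3 * val(p1, "A_d"))
  for (nm in c("K", "NMACR", "NMARR", "t_R_to_max", "t_R_to_min", "t_RWMACR")) {
    expect_equal(val(p3, nm), val(p1, nm), tolerance = 1e-12)
  }
})

test_that("ECG fiducials recover the template timing", {
  prof <- subject_profile(heart_rate = 60, rr_jitter_sd = 0,
                          noise_sd = c(ECG = 0), seed = 15)
  set.seed(15)
  fs <- 1600
  ecg <- smooth5(simulate_ecg(prof, 30, fs))
  truth <- attr(simulate_ecg(prof, 30, fs), "r_times")
  peaks <- detect_r_peaks(ecg, fs)
  part <- select_calculated_cycles(peaks, fs)
  acc <- part$cycles[part$cycles$accepted, ]
  p <- ecg_cycle_params(ecg, fs, acc$r_start[3], acc$r_end[3])
  val <- function(nm) p$value[p$parameter == nm]
  # template Q at -30 ms and S at +30 ms from R: t_QS = 60 ms give or take
  # the width of the Gaussian bumps
  expect_equal(val("t_QS"), 0.060, tolerance = 0.35)
  expect_equal(val("t_RR"), 1, tolerance = 0.01)
  # template symmetric Q/S depths scale A_RQ/A_SR towards their amp ratio
  expect_equal(val("A_RQ") / val("A_SR"), (1 + 0.08) / (1 + 0.20),
               tolerance = 0.15)
  expect_gt(val("t_RP"), 0.08)
  expect_gt(val("t_RT"), 0.1)
  expect_gt(val("NMACR_QR"), 0)
})

test_that("sound thirds ratios behave on constructed envelopes", {
  fs <- 3200
  # constant envelope: every per-third mean/max ratio is 1
  x <- rep(c(0.5, -0.5), fs / 2)
  p <- sound_cycle_params(x, fs, "LS")
  for (k in 1:3) {
    expect_equal(p$value[p$parameter == sprintf("mean_over_max_seg%d", k)], 1,
                 tolerance = 1e-6)
  }
  expect_equal(p$value[p$parameter == "amp_mean_seg23_over_seg1"], 1,
               tolerance = 1e-6)
  # silence flags
  ps <- sound_cycle_params(rep(0, 1000), fs, "HS")
  expect_equal(ps$flag[1], "silent")
})

test_that("simulated S2/S1 ratio is recovered per cycle from the heart sound", {
  fx <- cached_default_analysis()
  agg <- fx$ana$aggregates
  s21 <- agg[agg$channel_id == "hs" & agg$parameter == "s2_over_s1", ]
  expect_gt(nrow(s21), 0)
  expect_equal(mean(s21$mean), 0.6, tolerance = 0.1 / 0.6)
})

test_that("aggregates compute mean, SD and NSD with flagged zero means", {
  df <- tibble::tibble(
    channel_id = "x", rmps = "RMPS1",
    parameter = rep(c("a", "b"), each = 3),
    value = c(1, 2, 3, 5, 5, 5)
  )
  agg <- aggregate_rmps(df)
  a <- agg[agg$parameter == "a", ]
  expect_equal(a$mean, 2)
  expect_equal(a$sd, 1)
  expect_equal(a$nsd, 0.5)
  b <- agg[agg$parameter == "b", ]
  expect_equal(b$nsd, 0)
  zero <- aggregate_rmps(tibble::tibble(channel_id = "x", rmps = "RMPS1",
                                        parameter = "c", value = c(-1, 1)))
  expect_true(is.na(zero$nsd))
})

test_that("NSD is invariant under positive scaling of the parameter", {
  set.seed(16)
  v <- rlnorm(50)
  df <- function(x) tibble::tibble(channel_id = "x", rmps = "RMPS1",
                                   parameter = "p", value = x)
  n1 <- aggregate_rmps(df(v))$nsd
  n2 <- aggregate_rmps(df(17.3 * v))$nsd
  expect_equal(n1, n2, tolerance = 1e-12)
})

test_that("left/right ratios reflect construction and symmetry", {
  agg <- tibble::tibble(
    kind = "PPS", site = "wrist", rmps = "RMPS1",
    parameter = rep(c("A_d", "K"), each = 2),
    side = rep(c("L", "R"), 2),
    mean = c(2, 1, 0.8, 0.8)
  )
  lr <- left_right_ratios(agg)
  expect_equal(lr$ratio[lr$parameter == "A_d"], 2)
  expect_equal(lr$ratio[lr$parameter == "K"], 1)
  # symmetric simulation: downstream ratios near 1
  fx <- cached_default_analysis()
  lr2 <- fx$ana$lr_ratios
  ad <- lr2[lr2$parameter == "A_d" & lr2$site == "wrist" & lr2$rmps == "RMPS1", ]
  expect_equal(ad$ratio, 1, tolerance = 0.05)
})

test_that("asymmetric transit times surface in the RWMACR-time ratio", {
  sched <- tiny_schedule()
  prof <- subject_profile(
    transit = c(earlobe = 0.12, arm = 0.16, wrist = 0.20, finger = 0.26,
                ankle = 0.30, toe = 0.36, wrist_L = 0.24, wrist_R = 0.18),
    seed = 17
  )
  ct <- channel_table()
  ct <- ct[ct$channel_id %in% c("ecg", "pps_wrist_L", "pps_wrist_R",
                                "cuff_wrist_L", "cuff_wrist_R"), ]
  rec <- simulate_recording(prof, sched, ct)
  ana <- analyze_recording(rec, compute_bands = FALSE)
  agg <- ana$aggregates
  tw <- agg[agg$parameter == "t_RWMACR" & agg$rmps == "RMPS1" &
              agg$site == "wrist", ]
  ratio <- tw$mean[tw$side == "L"] / tw$mean[tw$side == "R"]
  expect_equal(ratio, 0.24 / 0.18, tolerance = 0.1)
})

test_that("occlusion trend statistics match hand computation on a drift toy", {
  # linear drifts with identical cycle structure; drift660 = 2 x drift940.
  # Per-cycle last-minus-first and window last-minus-first are both
  # proportional to the drift, so under ACR = A/(DI*T) the drift cancels and
  # ROS = 1; under the simpler ACR = DI/T convention ROS = 2.
  fs <- 100
  dur <- 40
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  d940 <- 1.5
  x940 <- 100 + d940 * t
  x660 <- 100 + 2 * d940 * t
  r_peaks <- round(seq(0, dur - 1, by = 1) * fs) + 1L
  windows <- tibble::tibble(rmps = c("RMPS1", "RMPS4"),
                            t_start = c(0, 20), t_end = c(15, 38))
  part <- select_calculated_cycles(r_peaks, fs, windows)
  tr <- bodws_trend(x660, x940, fs, part, c(20, 38))
  # hand values: T = 18; per-cycle change = drift x 1 s; DI = drift x 18
  expect_equal(tr$t_rmps, 18)
  expect_equal(tr$a_660 / tr$a_940, 2, tolerance = 1e-6)
  expect_equal(tr$di_660 / tr$di_940, 2, tolerance = 1e-6)
  # per-cycle change spans rr - 1/fs and DI spans T - 1/fs, hence the 2 %
  expect_equal(tr$acr_660, (2 * d940 * 1) / (2 * d940 * 18 * 18), tolerance = 0.02)
  expect_equal(tr$ros, 1, tolerance = 1e-6)
  tr2 <- bodws_trend(x660, x940, fs, part, c(20, 38), convention = "simple")
  expect_equal(tr2$ros, 2, tolerance = 1e-6)
  # identical series: ROS = NROS = 1
  tr3 <- bodws_trend(x940, x940, fs, part, c(20, 38))
  expect_equal(tr3$ros, 1)
  expect_equal(tr3$nros, 1)
  # zero drift flags DI
  flatl <- rep(100, length(t)) + 0.001 * sin(2 * pi * t)
  tr4 <- bodws_trend(rep(100, length(t)), flatl, fs, part, c(20, 38))
  expect_equal(tr4$flag, "zero_di")
})

test_that("path-length regressions and PWV arithmetic are stated", {
  expect_equal(path_length_heart_ankle(171), 0.8129 * 171 + 12.328)
  expect_equal(path_length_heart_ankle(171), 151.3339, tolerance = 1e-6)
  expect_equal(path_length_heart_arm(171), 0.2195 * 171 - 2.0734, tolerance = 1e-9)
  res <- pwv(0, c(`1` = 0.15, `2` = 0.15), path_length_heart_ankle(171),
             "heart", "ankle_L")
  expect_equal(res$pwv_m_s, (151.3339 / 100) / 0.15, tolerance = 1e-6)
  # equal proximal and distal timings are invalid
  bad <- pwv(c(`1` = 0.2), c(`1` = 0.2), 100)
  expect_equal(bad$flag, "nonpositive_t")
  expect_true(is.na(bad$pwv_m_s))
})

test_that("simulated ankle transit yields PWV within 5 percent of length over delay", {
  fx <- cached_default_analysis()
  pw <- fx$ana$pwv
  row <- pw[pw$site_b == "ankle_L", ]
  # RWMACR sits just after the pulse onset; allow the upstroke offset
  delay_true <- 0.30 + 0.015
  expected <- (path_length_heart_ankle(170) / 100) / delay_true
  expect_equal(row$pwv_m_s, expected, tolerance = 0.05)
})

test_that("oscillometric BP recovers the configured pressures and orders dia < MPAP < sys", {
  fx <- cached_default_analysis()
  bp <- fx$ana$bp
  expect_true(all(is.na(bp$flag)))
  expect_true(all(bp$dbp < bp$mpap & bp$mpap < bp$sbp))
  wr <- bp[bp$site == "wrist", ]
  expect_lt(max(abs(wr$sbp - 120)), 5)
  expect_lt(max(abs(wr$dbp - 80)), 5)
  an <- bp[bp$site == "ankle", ]
  expect_lt(max(abs(an$sbp - 130)), 5)
})

test_that("a monotone envelope with no down-slope flags the systolic reading", {
  fs <- 50
  dur <- 30
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  pressure <- 90 - 2 * t  # deflation entirely below the envelope centre
  env <- exp(-((pressure - 95)^2) / (2 * 18^2))
  pulse <- 1 + env * (0.5 - 0.5 * cos(2 * pi * 1.2 * t))
  res <- suppressWarnings(
    oscillometric_bp(pressure, pulse, fs, c(0, dur), site = "wrist", side = "L")
  )
  expect_true(is.na(res$sbp))
  expect_match(res$flag, "systolic")
})
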