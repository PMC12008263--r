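test_that("default schedule reproduces the protocol table field by field", {
  sched <- build_protocol(protocol_config())
  seg <- sched[sched$is_rmps, ]
  expect_equal(seg$segment, paste0("RMPS", 1:7))
  expect_equal(seg$t_end - seg$t_start, c(40, 120, 30, 40, 120, 30, 40))
  expect_equal(seg$pressure_mode,
               c("none", "gradual_decrease", "constant", "constant",
                 "gradual_decrease", "constant", "constant"))
  expect_equal(seg$pressure_target,
               c("zero", "MP_to_floor", "MPAP", "MP", "MP_to_floor", "MPAP", "MP"))
  wa <- sort(c("wrist_L", "wrist_R", "ankle_L", "ankle_R"))
  aa <- sort(c("arm_L", "arm_R", "ankle_L", "ankle_R"))
  expect_identical(seg$cuffs[[1]], character(0))
  for (i in 2:4) expect_equal(sort(seg$cuffs[[i]]), wa)
  for (i in 5:7) expect_equal(sort(seg$cuffs[[i]]), aa)
  # 15-s rest gaps between consecutive phases
  rests <- sched[!sched$is_rmps, ]
  expect_equal(nrow(rests), 6)
  expect_true(all(rests$t_end - rests$t_start == 15))
  expect_equal(protocol_duration(sched), sum(c(40, 120, 30, 40, 120, 30, 40)) + 6 * 15)
})

test_that("config validation names the offending field", {
  expect_error(protocol_config(max_pressure = -1), "max_pressure")
  expect_error(protocol_config(deflation_floor = 200), "deflation_floor")
  expect_error(protocol_config(durations = c(1, 2, 3)), "durations")
  expect_error(protocol_config(rest_interval = -5), "rest_interval")
})

test_that("unit durations give 7 s of pressure phases plus 6 rest gaps", {
  sched <- build_protocol(protocol_config(durations = rep(1, 7)))
  expect_equal(protocol_duration(sched), 7 + 6 * 15)
})

test_that("cuff pressure trace holds MP through the occlusive phase and is zero elsewhere", {
  sched <- build_protocol(protocol_config())
  fs <- 20
  tr <- cuff_pressure_trace(sched, "wrist_L", mpap = 93, fs = fs)
  expect_length(tr, ceiling(protocol_duration(sched) * fs))
  expect_true(all(tr >= 0))
  t <- (seq_along(tr) - 1) / fs
  w <- rmps_windows(sched)
  # MP = 180 through the RMPS4 hold (after the inflation ramp)
  i4 <- w$rmps == "RMPS4"
  hold <- tr[t >= w$t_start[i4] + 180 / 20 + 0.5 & t < w$t_end[i4]]
  expect_true(all(hold == 180))
  # zero during the no-pressure segment and all rest gaps
  expect_true(all(tr[t < w$t_end[w$rmps == "RMPS1"]] == 0))
  rests <- sched[!sched$is_rmps, ]
  for (i in seq_len(nrow(rests))) {
    expect_true(all(tr[t >= rests$t_start[i] & t < rests$t_end[i]] == 0))
  }
  # a site never cuffed yields an all-zero trace
  expect_true(all(cuff_pressure_trace(sched, "earlobe_L", fs = fs) == 0))
})

test_that("deflation decreases linearly from MP to the floor at the vent rate", {
  cfg <- protocol_config()
  sched <- build_protocol(cfg)
  fs <- 10
  tr <- cuff_pressure_trace(sched, "ankle_L", mpap = 95, fs = fs)
  t <- (seq_along(tr) - 1) / fs
  w <- rmps_windows(sched)
  i2 <- w$rmps == "RMPS2"
  t_inflate <- cfg$max_pressure / cfg$inflation_rate
  rate <- (cfg$max_pressure - cfg$deflation_floor) / (120 - t_inflate)
  # independent closed-form evaluation of the deflation line
  sel <- which(t >= w$t_start[i2] + t_inflate & t < w$t_end[i2])
  expected <- pmax(cfg$max_pressure - (t[sel] - w$t_start[i2] - t_inflate) * rate,
                   cfg$deflation_floor)
  expect_equal(tr[sel], expected, tolerance = 1e-12)
  expect_true(all(diff(tr[sel]) <= 0))
  expect_equal(tr[sel][1], cfg$max_pressure, tolerance = rate / fs * 1.01)
  expect_equal(tr[sel][length(sel)], cfg$deflation_floor, tolerance = rate / fs * 1.01)
})

test_that("an explicit vent rate overrides the derived one", {
  cfg <- protocol_config(vent_rate = 5)
  sched <- build_protocol(cfg)
  fs <- 10
  tr <- cuff_pressure_trace(sched, "wrist_L", mpap = 93, fs = fs)
  w <- rmps_windows(sched)
  t <- (seq_along(tr) - 1) / fs
  i2 <- w$rmps == "RMPS2"
  sel <- t >= w$t_start[i2] + 9 + 1 & t < w$t_start[i2] + 9 + 10
  expect_equal(diff(tr[sel]), rep(-5 / fs, sum(sel) - 1), tolerance = 1e-9)
})

test_that("constant-MPAP segments require an mpap value", {
  sched <- build_protocol(protocol_config())
  expect_error(cuff_pressure_trace(sched, "wrist_L", mpap = NULL, fs = 10), "mpap")
})

test_that("mpap computation matches the brute-force envelope scan", {
  set.seed(5)
  fs <- 50
  dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  pressure <- 150 - 2 * t
  center <- 93
  amp_env <- exp(-((pressure - center)^2) / (2 * 20^2))
  pulse <- amp_env * (0.5 - 0.5 * cos(2 * pi * 1.2 * t))
  res <- compute_mpap(pressure, pulse, fs, band = NULL)
  orc <- oracle_envelope(pressure, pulse, fs)
  expect_equal(res$mpap, orc$mpap)
  expect_equal(res$envelope$amplitude, orc$amp)
  expect_equal(res$envelope$pressure, orc$pres)
})

test_that("mpap ties break towards the higher pressure", {
  fs <- 40
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  pressure <- 120 - 3 * t
  pulse <- 0.5 - 0.5 * cos(2 * pi * 1 * t)  # identical cycles
  res <- compute_mpap(pressure, pulse, fs, band = NULL)
  # constant amplitudes: the argmax must sit at the highest cycle pressure
  expect_equal(res$mpap, max(res$envelope$pressure))
})

test_that("mpap errors on too few cycles and warns on non-monotone pressure", {
  fs <- 40
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  pulse <- sin(2 * pi * 1 * t)
  expect_error(compute_mpap(rep(100, length(t)), pulse, fs, band = NULL),
               class = "cardiocuff_insufficient_data")
  t2 <- seq(0, 20 - 1 / fs, by = 1 / fs)
  pulse2 <- 0.5 - 0.5 * cos(2 * pi * 1 * t2)
  expect_warning(compute_mpap(100 + 2 * sin(0.3 * t2), pulse2, fs, band = NULL),
                 "monoton")
})

test_that("mpap recovery: envelope centers drawn in 70-110 mmHg are located within 3 mmHg", {
  errs <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    fs <- 50
    t <- seq(0, 55 - 1 / fs, by = 1 / fs)
    pressure <- 150 - 2 * t
    center <- runif(1, 70, 110)
    hr_hz <- runif(1, 0.9, 1.5)
    env <- exp(-((pressure - center)^2) / (2 * 22^2))
    pulse <- env * (0.5 - 0.5 * cos(2 * pi * hr_hz * t)) + rnorm(length(t), 0, 0.01)
    res <- compute_mpap(pressure, pulse, fs)
    abs(res$mpap - center)
  }, numeric(1))
  expect_lt(median(errs), 3)
})

test_that("schedule JSON export round-trips segment timing", {
  sched <- build_protocol(protocol_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_protocol_json(sched, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$segments), 13)
  expect_equal(back$segments[[2]]$segment, "REST1")
  expect_equal(back$segments[[3]]$t_end - back$segments[[3]]$t_start, 120)
})
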