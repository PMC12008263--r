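# Shared fixtures. Problem sizes are reduced relative to the clinical
# protocol (shorter phases, faster deflation over the same pressure span)
# so the suite stays quick; the pressure range swept and the signal
# structure are unchanged.

reduced_config <- function() {
  protocol_config(durations = c(20, 60, 12, 20, 60, 12, 20), rest_interval = 8)
}

reduced_schedule <- function() build_protocol(reduced_config())

tiny_schedule <- function() {
  build_protocol(protocol_config(durations = c(8, 12, 6, 8, 12, 6, 8),
                                 rest_interval = 4))
}

# channel subset for parameter-recovery runs: ECG plus the pulse/cuff
# channels the checks need
recovery_channels <- function() {
  ct <- channel_table()
  keep <- c("ecg", "pps_wrist_L", "pps_wrist_R", "cuff_wrist_L", "cuff_wrist_R",
            "pps_arm_L", "cuff_arm_L", "pps_ankle_L", "cuff_ankle_L")
  ct[ct$channel_id %in% keep, ]
}

# one default reduced recording + analysis, cached across tests in a run
.fixture_cache <- new.env(parent = emptyenv())

cached_default_analysis <- function() {
  if (is.null(.fixture_cache$ana)) {
    rec <- simulate_recording(subject_profile(seed = 11), reduced_schedule())
    .fixture_cache$rec <- rec
    .fixture_cache$ana <- analyze_recording(rec, compute_bands = FALSE)
  }
  list(rec = .fixture_cache$rec, ana = .fixture_cache$ana)
}

# random recovery subject drawn from a seeded RNG
random_profile <- function(seed) {
  set.seed(seed)
  sbp <- runif(1, 105, 140)
  dbp <- runif(1, 62, sbp - 35)
  bp <- default_bp_table()
  bp$sbp <- sbp
  bp$dbp <- dbp
  subject_profile(
    heart_rate = runif(1, 55, 95),
    rr_jitter_sd = 0.015,
    bp = bp,
    spo2 = c(finger_L = runif(1, 94, 99), finger_R = 98, toe_L = 97, toe_R = 97),
    seed = seed
  )
}
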