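#' Simulated-subject ground truth
#'
#' Bundles the physiological quantities the simulator encodes and the
#' analysis is expected to recover: heart rate and its beat-to-beat jitter,
#' per-site systolic/diastolic pressures, per-extremity SpO2, height,
#' R-peak-to-pulse transit times, occlusion drift of the dual-wavelength
#' channels, per-kind noise levels, and the seed.
#'
#' Mean arterial pressure is taken as `DBP + (SBP - DBP)/3`. The
#' oscillometric envelope a cuffed pressure-pulse channel follows is an
#' asymmetric Gaussian in cuff pressure, centred at the site MAP, whose
#' widths are set so the pulse amplitude equals `osc_c_sys` of the peak at
#' the site SBP (above MAP) and `osc_c_dia` of the peak at the site DBP
#' (below MAP) - the fixed-ratio definition by which the generator encodes
#' blood pressure.
#'
#' @param heart_rate Heart rate in bpm (40-150, the calibrated range).
#' @param rr_jitter_sd SD of beat-to-beat R-R jitter (s).
#' @param premature_rate Probability that a beat is premature (shortened R-R
#'   followed by a compensatory pause and a reduced S1).
#' @param bp Tibble with columns `site` (wrist/arm/ankle), `side` (L/R),
#'   `sbp`, `dbp` in mmHg.
#' @param spo2 Named vector of per-extremity saturations (percent), names
#'   `finger_L`, `finger_R`, `toe_L`, `toe_R`.
#' @param height Subject height in cm.
#' @param transit Named vector of R-peak-to-pulse-onset transit times (s) by
#'   site (`earlobe`, `arm`, `wrist`, `finger`, `ankle`, `toe`); a
#'   `site_side` name (e.g. `wrist_L`) overrides its site default.
#' @param occlusion_drift Named vector of DC drift (a.u./s) of the
#'   dual-wavelength channels while flow is blocked; names `"660"`/`"940"`,
#'   or `extremity_side_wavelength` (e.g. `finger_L_660`) for overrides.
#' @param noise_sd Named vector of additive white-noise SDs by channel kind.
#' @param s2_s1_ratio Amplitude ratio of the second to the first heart sound.
#' @param s1_delay Time from the R peak to S1 onset (s).
#' @param s2_frac Position of S2 onset as a fraction of the R-R interval.
#' @param respiration_hz Respiration rate modulating the lung sound (Hz).
#' @param osc_floor Pressure-independent floor of the oscillometric
#'   amplitude envelope (fraction of the peak).
#' @param osc_c_sys,osc_c_dia Normalized envelope amplitudes at which the
#'   generator places SBP and DBP.
#' @param bodws_dc DC level of the dual-wavelength channels (a.u.).
#' @param bodws_ac Baseline per-cycle AC/DC ratio of the 940 nm channel.
#' @param seed Integer seed; the recording is deterministic given the
#'   profile.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(heart_rate = 70,
                            rr_jitter_sd = 0.02,
                            premature_rate = 0,
                            bp = default_bp_table(),
                            spo2 = c(finger_L = 98, finger_R = 98, toe_L = 97, toe_R = 97),
                            height = 170,
                            transit = c(earlobe = 0.12, arm = 0.16, wrist = 0.20,
                                        finger = 0.26, ankle = 0.30, toe = 0.36),
                            occlusion_drift = c("660" = -8, "940" = 4),
                            noise_sd = c(ECG = 0.01, HS = 0.01, LS = 0.005, PPG = 0.005,
                                         PPS = 0.005, CUFF_PRESSURE = 0.2, BODWS = 0.02),
                            s2_s1_ratio = 0.6,
                            s1_delay = 0.04,
                            s2_frac = 0.36,
                            respiration_hz = 0.25,
                            osc_floor = 0.10,
                            osc_c_sys = 0.55,
                            osc_c_dia = 0.75,
                            bodws_dc = 8000,
                            bodws_ac = 0.04,
                            seed = 1L) {
  check_number(heart_rate, "heart_rate", min = 40, max = 150)
  check_number(rr_jitter_sd, "rr_jitter_sd", min = 0)
  check_number(premature_rate, "premature_rate", min = 0, max = 0.5)
  check_number(height, "height", min = 0, strict_min = TRUE)
  if (!all(c("site", "side", "sbp", "dbp") %in% names(bp))) {
    stop_field("bp", "must have columns site, side, sbp, dbp")
  }
  if (any(bp$dbp >= bp$sbp)) stop_field("bp", "dbp must be below sbp")
  if (any(spo2 <= 0 | spo2 > 100)) stop_field("spo2", "must lie in (0, 100]")
  site_t <- function(s) transit[[s]]
  for (pair in list(c("earlobe", "arm"), c("arm", "wrist"),
                    c("wrist", "finger"), c("ankle", "toe"))) {
    if (site_t(pair[1]) >= site_t(pair[2])) {
      stop_field("transit", sprintf("must be ordered %s < %s", pair[1], pair[2]))
    }
  }
  if (any(transit <= 0)) stop_field("transit", "must be positive")
  structure(
    list(
      heart_rate = heart_rate, rr_jitter_sd = rr_jitter_sd,
      premature_rate = premature_rate, bp = bp, spo2 = spo2, height = height,
      transit = transit, occlusion_drift = occlusion_drift, noise_sd = noise_sd,
      s2_s1_ratio = s2_s1_ratio, s1_delay = s1_delay, s2_frac = s2_frac,
      respiration_hz = respiration_hz, osc_floor = osc_floor,
      osc_c_sys = osc_c_sys, osc_c_dia = osc_c_dia,
      bodws_dc = bodws_dc, bodws_ac = bodws_ac,
      seed = as.integer(seed)
    ),
    class = "subject_profile"
  )
}

#' Default per-site blood pressures
#' @return Tibble of site/side systolic and diastolic pressures (mmHg).
#' @export
default_bp_table <- function() {
  tibble(
    site = rep(c("wrist", "arm", "ankle"), each = 2L),
    side = rep(c("L", "R"), 3L),
    sbp = c(120, 120, 120, 120, 130, 130),
    dbp = c(80, 80, 80, 80, 80, 80)
  )
}

profile_bp <- function(profile, site, side) {
  row <- profile$bp[profile$bp$site == site & profile$bp$side == side, ]
  if (nrow(row) == 0L) abort(sprintf("no blood pressure for %s_%s", site, side))
  sbp <- row$sbp[1L]; dbp <- row$dbp[1L]
  list(sbp = sbp, dbp = dbp, map = dbp + (sbp - dbp) / 3)
}

profile_transit <- function(profile, site, side) {
  key <- paste(site, side, sep = "_")
  if (key %in% names(profile$transit)) return(profile$transit[[key]])
  profile$transit[[site]]
}

profile_drift <- function(profile, extremity, side, wavelength) {
  key <- paste(extremity, side, wavelength, sep = "_")
  if (key %in% names(profile$occlusion_drift)) return(profile$occlusion_drift[[key]])
  profile$occlusion_drift[[as.character(wavelength)]]
}

profile_noise <- function(profile, kind) {
  if (kind %in% names(profile$noise_sd)) profile$noise_sd[[kind]] else 0
}

#' Default 27-channel table
#'
#' The acquisition channel set: four photoplethysmographic channels (both
#' earlobes and fingers) at 400 Hz, one ECG at 1600 Hz, heart and lung sound
#' at 3200 Hz, six pressure-pulse and six cuff-pressure channels (both
#' wrists, arms, ankles) at 400 Hz, and eight dual-wavelength blood-oxygen
#' channels (660/940 nm at both fingers and toes) at 400 Hz.
#'
#' @return Tibble with columns `channel_id`, `kind`, `site`, `side`,
#'   `wavelength` (nm or `NA`), `fs` (Hz).
#' @export
channel_table <- function() {
  dplyr::bind_rows(
    tibble(kind = "PPG", site = rep(c("earlobe", "finger"), each = 2L),
           side = rep(c("L", "R"), 2L), wavelength = NA_real_, fs = 400),
    tibble(kind = "ECG", site = "chest", side = "none", wavelength = NA_real_, fs = 1600),
    tibble(kind = c("HS", "LS"), site = "chest", side = "none",
           wavelength = NA_real_, fs = 3200),
    tibble(kind = "PPS", site = rep(c("wrist", "arm", "ankle"), each = 2L),
           side = rep(c("L", "R"), 3L), wavelength = NA_real_, fs = 400),
    tibble(kind = "CUFF_PRESSURE", site = rep(c("wrist", "arm", "ankle"), each = 2L),
           side = rep(c("L", "R"), 3L), wavelength = NA_real_, fs = 400),
    tibble(kind = "BODWS", site = rep(c("finger", "toe"), each = 4L),
           side = rep(c("L", "L", "R", "R"), 2L),
           wavelength = rep(c(660, 940), 4L), fs = 400)
  ) |>
    dplyr::mutate(channel_id = dplyr::case_when(
      .data$kind %in% c("ECG", "HS", "LS") ~ tolower(.data$kind),
      .data$kind == "BODWS" ~ sprintf("bodws_%s_%s_%d", .data$site, .data$side, .data$wavelength),
      .data$kind == "CUFF_PRESSURE" ~ sprintf("cuff_%s_%s", .data$site, .data$side),
      TRUE ~ sprintf("%s_%s_%s", tolower(.data$kind), .data$site, .data$side)
    )) |>
    dplyr::relocate("channel_id")
}

# ---- beat sequence -------------------------------------------------------

# Draw the beat (R-peak) time sequence for the whole recording. Premature
# beats shorten one R-R interval and lengthen the next (compensatory pause).
draw_beats <- function(profile, duration) {
  rr0 <- 60 / profile$heart_rate
  n <- ceiling(duration / rr0 * 1.5) + 10L
  rr <- rr0 + rnorm(n, 0, profile$rr_jitter_sd)
  rr <- pmax(rr, 0.25)
  premature <- rep(FALSE, n)
  if (profile$premature_rate > 0) {
    u <- runif(n)
    i <- 1L
    while (i <= n - 1L) {
      if (u[i] < profile$premature_rate) {
        premature[i] <- TRUE
        rr[i] <- rr[i] * 0.75
        rr[i + 1L] <- rr[i + 1L] * 1.25
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
  }
  r_times <- 0.5 + cumsum(c(0, rr))
  keep <- r_times < duration
  list(r_times = r_times[keep], premature = c(FALSE, premature)[keep],
       rr = c(rr0, rr)[keep])
}

# ---- ECG -----------------------------------------------------------------

# Gaussian-bump P-QRS-T morphology; offsets (s) and amplitudes relative to R
ecg_morphology <- function() {
  tibble(
    wave = c("P", "Q", "R", "S", "T"),
    offset = c(-0.18, -0.030, 0, 0.030, 0.28),
    sd = c(0.022, 0.009, 0.010, 0.009, 0.050),
    amp = c(0.12, -0.08, 1.00, -0.20, 0.25)
  )
}

#' Simulate an ECG series
#'
#' Sum of Gaussian bumps (P, Q, R, S, T) per beat. R-R intervals are
#' `60/heart_rate` plus Gaussian jitter, with optional premature beats.
#'
#' @param profile A [subject_profile()].
#' @param duration Length in seconds.
#' @param fs Sampling rate (Hz). Default 1600.
#' @param r_times Optional beat times (s); when `NULL` they are drawn from
#'   the profile (seeded by the caller's RNG state).
#' @return Numeric series with attributes `r_times` (s) and `premature`.
#' @export
simulate_ecg <- function(profile, duration, fs = 1600, r_times = NULL) {
  if (is.null(r_times)) {
    beats <- draw_beats(profile, duration)
    r_times <- beats$r_times
    premature <- beats$premature
  } else {
    premature <- rep(FALSE, length(r_times))
  }
  n <- ceiling(duration * fs)
  x <- numeric(n)
  morph <- ecg_morphology()
  for (r in r_times) {
    i1 <- max(1L, floor((r - 0.35) * fs) + 1L)
    i2 <- min(n, ceiling((r + 0.55) * fs))
    if (i2 < i1) next
    tau <- ((i1:i2) - 1) / fs - r
    seg <- numeric(i2 - i1 + 1L)
    for (w in seq_len(nrow(morph))) {
      seg <- seg + morph$amp[w] * exp(-((tau - morph$offset[w])^2) / (2 * morph$sd[w]^2))
    }
    x[i1:i2] <- x[i1:i2] + seg
  }
  nsd <- profile_noise(profile, "ECG")
  if (nsd > 0) x <- x + rnorm(n, 0, nsd)
  attr(x, "r_times") <- r_times
  attr(x, "premature") <- premature
  x
}

# ---- heart and lung sounds ----------------------------------------------

burst <- function(tau, freq, decay = 0.02, dur = 0.12) {
  ifelse(tau >= 0 & tau < dur, sin(2 * pi * freq * tau) * exp(-tau / decay), 0)
}

#' Simulate heart-sound and lung-sound series
#'
#' Heart sound: damped-oscillation bursts, S1 at `s1_delay` after each R peak
#' and S2 at `s2_frac` of the R-R interval, with S2 amplitude `s2_s1_ratio`
#' of S1 (premature beats get a halved S1). Lung sound: band-limited noise
#' modulated by a respiration envelope.
#'
#' @param profile A [subject_profile()].
#' @param ecg_r_times Beat times (s).
#' @param duration Length in seconds.
#' @param fs Sampling rate (Hz). Default 3200.
#' @param premature Logical vector marking premature beats.
#' @return List with elements `hs` and `ls`.
#' @export
simulate_sounds <- function(profile, ecg_r_times, duration, fs = 3200,
                            premature = NULL) {
  n <- ceiling(duration * fs)
  t <- (seq_len(n) - 1) / fs
  hs <- numeric(n)
  if (is.null(premature)) premature <- rep(FALSE, length(ecg_r_times))
  rr <- diff(c(ecg_r_times, duration))
  for (b in seq_along(ecg_r_times)) {
    r <- ecg_r_times[b]
    s1_amp <- if (premature[b]) 0.5 else 1
    for (ev in list(c(r + profile$s1_delay, s1_amp, 45),
                    c(r + profile$s2_frac * rr[b], profile$s2_s1_ratio, 60))) {
      i1 <- max(1L, floor(ev[1L] * fs) + 1L)
      i2 <- min(n, ceiling((ev[1L] + 0.12) * fs))
      if (i2 < i1) next
      hs[i1:i2] <- hs[i1:i2] + ev[2L] * burst(t[i1:i2] - ev[1L], ev[3L])
    }
  }
  nhs <- profile_noise(profile, "HS")
  if (nhs > 0) hs <- hs + rnorm(n, 0, nhs)
  # lung sound: 100-500 Hz noise under a respiration envelope
  raw <- rnorm(n)
  bf <- signal::butter(2, c(100, 500) / (fs / 2), type = "pass")
  ls_noise <- signal::filtfilt(bf, raw)
  env <- 0.55 + 0.45 * sin(2 * pi * profile$respiration_hz * t - pi / 2)
  ls <- 0.3 * env * ls_noise
  nls <- profile_noise(profile, "LS")
  if (nls > 0) ls <- ls + rnorm(n, 0, nls)
  list(hs = hs, ls = ls)
}

# ---- pulse channels ------------------------------------------------------

# sharp half-cosine upstroke then exponential decay; unit peak
pulse_shape <- function(tau, rise = 0.03, tau_decay = 0.25) {
  out <- numeric(length(tau))
  up <- tau >= 0 & tau < rise
  down <- tau >= rise
  out[up] <- 0.5 * (1 - cos(pi * tau[up] / rise))
  out[down] <- exp(-(tau[down] - rise) / tau_decay)
  out
}

# unit pulse train evaluated at times t: each beat contributes
# amp[b] * pulse_shape(t - onset[b]). With `center = TRUE` each beat's
# analytic mean is subtracted, making the train zero-mean per beat (used by
# the optical channels so the per-cycle AC/DC ratio equals the configured
# one exactly).
pulse_train <- function(t, onsets, amps, center = FALSE) {
  idx <- findInterval(t, onsets)
  out <- numeric(length(t))
  pos <- idx >= 1L
  out[pos] <- amps[idx[pos]] * pulse_shape(t[pos] - onsets[idx[pos]])
  if (center && length(onsets) > 0L) {
    durs <- diff(c(onsets, max(t) + 1 / 400))
    means <- amps * pulse_shape_mean(durs) / pmax(durs, 1e-6)
    out[pos] <- out[pos] - means[idx[pos]]
  }
  out
}

# integral of pulse_shape over [0, d] divided into the half-cosine rise and
# the exponential decay
pulse_shape_mean <- function(d, rise = 0.03, tau_decay = 0.25) {
  up <- pmin(d, rise)
  int_up <- 0.5 * (up - (rise / pi) * sin(pi * up / rise))
  down <- pmax(d - rise, 0)
  int_down <- tau_decay * (1 - exp(-down / tau_decay))
  int_up + int_down
}

# normalized oscillometric amplitude envelope in cuff pressure: asymmetric
# Gaussian centred at MAP with widths tied to SBP/DBP via the fixed ratios
osc_envelope <- function(p_cuff, bp, profile) {
  f <- profile$osc_floor
  g_sys <- (profile$osc_c_sys - f) / (1 - f)
  g_dia <- (profile$osc_c_dia - f) / (1 - f)
  sd_hi <- (bp$sbp - bp$map) / sqrt(-2 * log(g_sys))
  sd_lo <- (bp$map - bp$dbp) / sqrt(-2 * log(g_dia))
  sdv <- ifelse(p_cuff >= bp$map, sd_hi, sd_lo)
  f + (1 - f) * exp(-((p_cuff - bp$map)^2) / (2 * sdv^2))
}

# occlusion factor of a distal site given the maximum upstream ratio
# pressure/SBP; 1 when unpressurized, 0 at or above systolic
occlusion_factor <- function(p_over_sbp) {
  clamp(1 - p_over_sbp, 0, 1)
}

upstream_sites <- function(site) {
  switch(site,
    finger = c("wrist", "arm"),
    toe = "ankle",
    earlobe = character(0),
    wrist = "wrist", arm = "arm", ankle = "ankle",
    character(0)
  )
}

# max over upstream cuffs of pressure/SBP at each sample (vectorized)
upstream_ratio <- function(profile, site, side, cuff_traces) {
  ups <- upstream_sites(site)
  ups <- setdiff(ups, site)  # only cuffs above the measurement point
  if (site %in% c("wrist", "arm", "ankle")) ups <- character(0)
  if (length(ups) == 0L) return(NULL)
  ratios <- lapply(ups, function(s) {
    tr <- cuff_traces[[paste(s, side, sep = "_")]]
    if (is.null(tr)) return(NULL)
    tr / profile_bp(profile, s, side)$sbp
  })
  ratios <- ratios[!vapply(ratios, is.null, logical(1))]
  if (length(ratios) == 0L) return(NULL)
  Reduce(pmax, ratios)
}

#' Simulate a photoplethysmographic or pressure-pulse channel
#'
#' Emits an asymmetric per-beat pulse waveform delayed from each R peak by
#' the site transit time. For a pressure-pulse channel under its own cuff the
#' beat amplitude follows the oscillometric envelope in cuff pressure
#' (peaked at the site MAP); for distal optical channels the amplitude is
#' scaled by an occlusion factor that reaches zero when any upstream cuff
#' is at or above the upstream site's systolic pressure. Earlobe channels
#' ignore all cuffs.
#'
#' @param profile A [subject_profile()].
#' @param spec One row of [channel_table()] (kind `PPG` or `PPS`).
#' @param cuff_pressure Cuff-pressure series at `spec$fs` for the site's own
#'   cuff (PPS) — required for cuffed sites.
#' @param ecg_r_times Beat times (s).
#' @param duration Length in seconds.
#' @param upstream Optional series of max upstream `pressure/SBP` at
#'   `spec$fs` for distal channels (finger/toe/earlobe PPG).
#' @return Numeric series (a.u., DC offset 1).
#' @export
simulate_pulse_channel <- function(profile, spec, cuff_pressure = NULL,
                                   ecg_r_times, duration, upstream = NULL) {
  stopifnot(spec$kind %in% c("PPG", "PPS"))
  fs <- spec$fs
  n <- ceiling(duration * fs)
  t <- (seq_len(n) - 1) / fs
  delay <- profile_transit(profile, spec$site, spec$side)
  onsets <- ecg_r_times + delay
  if (spec$kind == "PPS") {
    if (is.null(cuff_pressure)) {
      abort(sprintf("cuff pressure required for pressure-pulse channel at %s_%s",
                    spec$site, spec$side))
    }
    bp <- profile_bp(profile, spec$site, spec$side)
    p_at <- cuff_pressure[clamp(floor(onsets * fs) + 1L, 1L, n)]
    amps <- osc_envelope(p_at, bp, profile)
  } else if (spec$site == "earlobe") {
    amps <- rep(1, length(onsets))
  } else {
    if (is.null(upstream)) {
      amps <- rep(1, length(onsets))
    } else {
      amps <- occlusion_factor(upstream[clamp(floor(onsets * fs) + 1L, 1L, n)])
    }
  }
  x <- 1 + pulse_train(t, onsets, amps)
  nsd <- profile_noise(profile, spec$kind)
  if (nsd > 0) x <- x + rnorm(n, 0, nsd)
  x
}

#' Simulate a dual-wavelength blood-oxygen channel
#'
#' DC level plus a pulsatile AC dip whose per-cycle AC/DC ratio is the
#' profile's baseline ratio for 940 nm and that ratio times
#' `r_from_spo2(spo2)` for 660 nm, so the analysis-side ratio-of-ratios
#' recovers the configured saturation. While flow is blocked (upstream cuff
#' at or above systolic) pulsation is suppressed and the DC level drifts
#' linearly at the configured occlusion drift.
#'
#' @param profile A [subject_profile()].
#' @param spec One row of [channel_table()] (kind `BODWS`, wavelength 660
#'   or 940).
#' @param upstream Series of max upstream `pressure/SBP` at `spec$fs`
#'   (`NULL` for never-occluded channels).
#' @param ecg_r_times Beat times (s).
#' @param duration Length in seconds.
#' @return Numeric series (a.u.).
#' @export
simulate_bodws_channel <- function(profile, spec, upstream = NULL,
                                   ecg_r_times, duration) {
  stopifnot(spec$kind == "BODWS")
  if (!spec$wavelength %in% c(660, 940)) abort("wavelength must be 660 or 940")
  fs <- spec$fs
  n <- ceiling(duration * fs)
  t <- (seq_len(n) - 1) / fs
  delay <- profile_transit(profile, spec$site, spec$side)
  onsets <- ecg_r_times + delay
  occ <- if (is.null(upstream)) rep(1, n) else occlusion_factor(upstream)
  spo2 <- profile$spo2[[paste(spec$site, spec$side, sep = "_")]]
  ratio <- if (spec$wavelength == 660) {
    profile$bodws_ac * r_from_spo2(spo2)
  } else {
    profile$bodws_ac
  }
  drift <- profile_drift(profile, spec$site, spec$side, spec$wavelength)
  blocked <- occ <= 0
  dc <- profile$bodws_dc + drift * cumsum(blocked) / fs
  amps <- occ[clamp(floor(onsets * fs) + 1L, 1L, n)]
  x <- dc * (1 - ratio * pulse_train(t, onsets, amps, center = TRUE))
  nsd <- profile_noise(profile, "BODWS")
  if (nsd > 0) x <- x + rnorm(n, 0, nsd)
  x
}

# ---- quantization --------------------------------------------------------

#' Quantize a series to 14-bit acquisition units
#'
#' Affine map `offset + gain * x`, rounded half away from zero and clipped
#' to the 14-bit range 0..16383 (each acquisition value is the sum of four
#' adjacent 12-bit conversions).
#'
#' @param x Numeric series (calibrated units).
#' @param gain Gain (ADCV units per calibrated unit). Default 1.
#' @param offset Offset in ADCV units. Default 0.
#' @return Integer series in 0..16383.
#' @export
quantize_adcv <- function(x, gain = 1, offset = 0) {
  as.integer(clamp(round_half_away(offset + gain * x), 0, 16383))
}

#' Inverse of [quantize_adcv()]
#' @param q Quantized series.
#' @param gain,offset The map used to quantize.
#' @return Calibrated values.
#' @export
dequantize_adcv <- function(q, gain = 1, offset = 0) {
  (as.numeric(q) - offset) / gain
}

# per-kind gain/offset used when a recording is emitted in ADC units
adc_gains <- function() {
  tibble(
    kind = c("ECG", "HS", "LS", "PPG", "PPS", "CUFF_PRESSURE", "BODWS"),
    gain = c(1 / 4.30532e-4, 2000, 2000, 2000, 2000, 70, 1),
    offset = c(0.01042 / 4.30532e-4, 8192, 8192, 4096, 4096, 100, 0)
  )
}

# ---- full recording ------------------------------------------------------

#' Simulate a full multi-channel recording
#'
#' Generates every channel of `channels` over the whole schedule from one
#' continuous beat-time sequence, so all channels share the protocol clock.
#' The six cuff-pressure channels equal [cuff_pressure_trace()] (with the
#' site MAP as the MPAP hold target) plus noise. Deterministic given the
#' profile seed.
#'
#' @param profile A [subject_profile()].
#' @param schedule A `cuff_protocol`; default the standard seven-phase
#'   schedule.
#' @param channels Channel table; default [channel_table()] (27 channels).
#' @param units `"calibrated"` (default) or `"adc"` (14-bit quantized, with
#'   the per-kind gain/offset stored for inverse mapping).
#' @return An object of class `cuff_recording`: list with `channels` (the
#'   channel table plus a `samples` list column), `segments`
#'   ([rmps_windows()]), `schedule`, `profile`, `units`, `seed`.
#' @export
simulate_recording <- function(profile,
                               schedule = build_protocol(protocol_config()),
                               channels = channel_table(),
                               units = c("calibrated", "adc")) {
  units <- match.arg(units)
  if (nrow(channels) == 0L) abort("`channels` must be non-empty")
  duration <- protocol_duration(schedule)
  set.seed(profile$seed)
  beats <- draw_beats(profile, duration)
  cseeds <- sample.int(.Machine$integer.max - 1L, nrow(channels))

  # ideal cuff traces at 400 Hz for every cuffed site (MPAP target = site MAP)
  cuff_traces <- list()
  for (cs in cuff_sites()) {
    parts <- strsplit(cs, "_")[[1L]]
    bp <- profile_bp(profile, parts[1L], parts[2L])
    cuff_traces[[cs]] <- cuff_pressure_trace(schedule, cs, mpap = bp$map, fs = 400)
  }

  samples <- vector("list", nrow(channels))
  for (i in seq_len(nrow(channels))) {
    spec <- channels[i, ]
    set.seed(cseeds[i])
    samples[[i]] <- switch(spec$kind,
      ECG = as.numeric(simulate_ecg(profile, duration, spec$fs, r_times = beats$r_times)),
      HS = simulate_sounds(profile, beats$r_times, duration, spec$fs,
                           premature = beats$premature)$hs,
      LS = simulate_sounds(profile, beats$r_times, duration, spec$fs,
                           premature = beats$premature)$ls,
      CUFF_PRESSURE = {
        tr <- cuff_traces[[paste(spec$site, spec$side, sep = "_")]]
        nsd <- profile_noise(profile, "CUFF_PRESSURE")
        if (nsd > 0) tr + rnorm(length(tr), 0, nsd) else tr
      },
      PPS = simulate_pulse_channel(
        profile, spec,
        cuff_pressure = cuff_traces[[paste(spec$site, spec$side, sep = "_")]],
        ecg_r_times = beats$r_times, duration = duration
      ),
      PPG = simulate_pulse_channel(
        profile, spec, cuff_pressure = NULL, ecg_r_times = beats$r_times,
        duration = duration,
        upstream = upstream_ratio(profile, spec$site, spec$side, cuff_traces)
      ),
      BODWS = simulate_bodws_channel(
        profile, spec,
        upstream = upstream_ratio(profile, spec$site, spec$side, cuff_traces),
        ecg_r_times = beats$r_times, duration = duration
      ),
      abort(sprintf("unknown channel kind `%s`", spec$kind))
    )
  }
  gains <- NULL
  if (units == "adc") {
    gains <- adc_gains()
    for (i in seq_len(nrow(channels))) {
      g <- gains[gains$kind == channels$kind[i], ]
      samples[[i]] <- quantize_adcv(samples[[i]], g$gain, g$offset)
    }
  }
  channels$samples <- samples
  structure(
    list(
      channels = channels,
      segments = rmps_windows(schedule),
      schedule = schedule,
      profile = profile,
      units = units,
      adc_gains = gains,
      seed = profile$seed,
      r_times = beats$r_times
    ),
    class = "cuff_recording"
  )
}

#' @export
print.cuff_recording <- function(x, ...) {
  cat(sprintf("<cuff_recording> %d channels, %.0f s, units = %s, seed = %d\n",
              nrow(x$channels), max(x$segments$t_end), x$units, x$seed))
  invisible(x)
}

#' Extract one channel's samples from a recording
#' @param rec A `cuff_recording`.
#' @param channel_id Channel identifier (see [channel_table()]).
#' @return Numeric series.
#' @export
recording_channel <- function(rec, channel_id) {
  i <- match(channel_id, rec$channels$channel_id)
  if (is.na(i)) abort(sprintf("no channel `%s` in recording", channel_id))
  rec$channels$samples[[i]]
}
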