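#' Configuration of the seven-phase cuff-pressure protocol
#'
#' Holds the tunable parameters of the pressure-stimulation schedule: the
#' maximum cuff pressure used for the occlusive holds and the start of the
#' gradual deflations, the deflation floor, the inflation and vent rates, the
#' rest interval separating consecutive phases, and the seven per-phase
#' durations.
#'
#' @param max_pressure Maximum cuff pressure (MP) in mmHg. Default 180.
#' @param deflation_floor Pressure (mmHg) at which a gradual deflation stops.
#'   Default 30.
#' @param vent_rate Deflation rate in mmHg/s, or `NULL` (default) to derive
#'   the rate per segment so the deflation spans `max_pressure` down to
#'   `deflation_floor` within the segment after the inflation ramp.
#' @param inflation_rate Inflation rate in mmHg/s. Default 20. Inflation ramps
#'   live inside the nominal segment duration.
#' @param rest_interval Non-pressure interval (s) between consecutive phases.
#'   Default 15.
#' @param durations Numeric vector of the seven phase durations in seconds.
#'   Default `c(40, 120, 30, 40, 120, 30, 40)`.
#'
#' @return An object of class `protocol_config`.
#' @export
#' @examples
#' cfg <- protocol_config()
#' cfg$max_pressure
protocol_config <- function(max_pressure = 180,
                            deflation_floor = 30,
                            vent_rate = NULL,
                            inflation_rate = 20,
                            rest_interval = 15,
                            durations = c(40, 120, 30, 40, 120, 30, 40)) {
  check_number(max_pressure, "max_pressure", min = 0, strict_min = TRUE)
  check_number(deflation_floor, "deflation_floor", min = 0)
  if (deflation_floor >= max_pressure) {
    stop_field("deflation_floor", "must be below `max_pressure`")
  }
  if (!is.null(vent_rate)) check_number(vent_rate, "vent_rate", min = 0, strict_min = TRUE)
  check_number(inflation_rate, "inflation_rate", min = 0, strict_min = TRUE)
  check_number(rest_interval, "rest_interval", min = 0)
  if (!is.numeric(durations) || length(durations) != 7L ||
      any(!is.finite(durations)) || any(durations <= 0)) {
    stop_field("durations", "must be 7 positive durations in seconds")
  }
  structure(
    list(
      max_pressure = max_pressure,
      deflation_floor = deflation_floor,
      vent_rate = vent_rate,
      inflation_rate = inflation_rate,
      rest_interval = rest_interval,
      durations = unname(durations)
    ),
    class = "protocol_config"
  )
}

cuff_sites <- function() {
  c("wrist_L", "wrist_R", "arm_L", "arm_R", "ankle_L", "ankle_R")
}

# Table of the seven analyzed segments: pressure mode, target, and cuff group
rmps_table <- function() {
  wa <- c("wrist_L", "wrist_R", "ankle_L", "ankle_R")
  aa <- c("arm_L", "arm_R", "ankle_L", "ankle_R")
  tibble(
    rmps = paste0("RMPS", 1:7),
    pressure_mode = c("none", "gradual_decrease", "constant", "constant",
                      "gradual_decrease", "constant", "constant"),
    pressure_target = c("zero", "MP_to_floor", "MPAP", "MP",
                        "MP_to_floor", "MPAP", "MP"),
    cuffs = list(character(0), wa, wa, wa, aa, aa, aa)
  )
}

#' Build the seven-phase pressure-stimulation schedule
#'
#' Lays out the seven analyzed segments (no-pressure baseline, two gradual
#' wrist/ankle and arm/ankle deflations from MP to the floor, two
#' constant-MPAP holds, and two occlusive constant-MP holds) with a
#' non-pressure rest interval between consecutive phases.
#'
#' @param config A [protocol_config()].
#'
#' @return A tibble of class `cuff_protocol` with one row per segment
#'   (seven analyzed segments and six rest gaps) and columns `segment`,
#'   `is_rmps`, `pressure_mode`, `pressure_target`, `cuffs` (list column of
#'   cuff sites), `t_start`, `t_end` (seconds, 0-based half-open intervals).
#'   The configuration is attached as attribute `config`.
#' @export
#' @examples
#' sched <- build_protocol(protocol_config())
#' protocol_duration(sched)
build_protocol <- function(config = protocol_config()) {
  if (!inherits(config, "protocol_config")) {
    stop_field("config", "must be a `protocol_config`")
  }
  tab <- rmps_table()
  rows <- vector("list", 13L)
  t <- 0
  for (i in 1:7) {
    rows[[2L * i - 1L]] <- tibble(
      segment = tab$rmps[i],
      is_rmps = TRUE,
      pressure_mode = tab$pressure_mode[i],
      pressure_target = tab$pressure_target[i],
      cuffs = tab$cuffs[i],
      t_start = t,
      t_end = t + config$durations[i]
    )
    t <- t + config$durations[i]
    if (i < 7L) {
      rows[[2L * i]] <- tibble(
        segment = paste0("REST", i),
        is_rmps = FALSE,
        pressure_mode = "none",
        pressure_target = "zero",
        cuffs = list(character(0)),
        t_start = t,
        t_end = t + config$rest_interval
      )
      t <- t + config$rest_interval
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  class(out) <- c("cuff_protocol", class(out))
  out
}

#' Total duration of a schedule in seconds
#' @param schedule A `cuff_protocol`.
#' @return Length of the full schedule (s).
#' @export
protocol_duration <- function(schedule) {
  max(schedule$t_end)
}

#' Analyzed-segment windows of a schedule
#' @param schedule A `cuff_protocol`.
#' @return Tibble with columns `rmps`, `t_start`, `t_end` for the seven
#'   analyzed segments (half-open windows in seconds).
#' @export
rmps_windows <- function(schedule) {
  seg <- schedule[schedule$is_rmps, ]
  tibble(rmps = seg$segment, t_start = seg$t_start, t_end = seg$t_end)
}

#' Ideal cuff-pressure trace for one cuff site
#'
#' Evaluates the piecewise pressure waveform a cuff follows over the whole
#' schedule: zero outside its phases, a linear inflation ramp at
#' `inflation_rate` to the segment target at the start of each of its phases,
#' a constant hold (MP or MPAP) or a linear deflation from MP towards the
#' deflation floor, and an instantaneous release at the end of the phase.
#'
#' @param schedule A `cuff_protocol` from [build_protocol()].
#' @param cuff Cuff site, one of `cuff_sites()`. A site absent from every
#'   segment yields an all-zero trace.
#' @param mpap Maximum-pulse-amplitude pressure (mmHg) used as the target of
#'   constant-MPAP holds. Required if any such hold includes `cuff`.
#' @param fs Sampling rate (Hz).
#'
#' @return Numeric pressure series (mmHg) of length
#'   `ceiling(total_duration * fs)`; sample k has time `(k - 1)/fs`.
#' @export
cuff_pressure_trace <- function(schedule, cuff, mpap = NULL, fs = 400) {
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  config <- attr(schedule, "config")
  total <- protocol_duration(schedule)
  n <- ceiling(total * fs)
  t <- (seq_len(n) - 1) / fs
  p <- numeric(n)
  segs <- schedule[schedule$is_rmps & vapply(schedule$cuffs, function(cc) cuff %in% cc, logical(1)), ]
  if (nrow(segs) == 0L) return(p)
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    target <- switch(seg$pressure_target,
      MP = config$max_pressure,
      MP_to_floor = config$max_pressure,
      MPAP = {
        if (is.null(mpap)) {
          abort(sprintf("`mpap` is required for constant-MPAP segment %s on cuff %s",
                        seg$segment, cuff))
        }
        mpap
      },
      zero = 0
    )
    idx <- which(t >= seg$t_start & t < seg$t_end)
    if (length(idx) == 0L) next
    tau <- t[idx] - seg$t_start
    t_inflate <- target / config$inflation_rate
    ramp <- pmin(tau * config$inflation_rate, target)
    if (seg$pressure_mode == "constant") {
      p[idx] <- ramp
    } else {
      dur_deflate <- (seg$t_end - seg$t_start) - t_inflate
      rate <- config$vent_rate %||%
        ((config$max_pressure - config$deflation_floor) / dur_deflate)
      defl <- pmax(target - (tau - t_inflate) * rate, config$deflation_floor)
      p[idx] <- ifelse(tau < t_inflate, ramp, defl)
    }
  }
  p
}

#' Locate the maximum-pulse-amplitude pressure from a deflation
#'
#' Builds the oscillometric envelope (per-cycle pulse amplitude versus mean
#' cuff pressure of the cycle) from co-registered cuff-pressure and pulse
#' series over a gradual deflation, and returns the cuff pressure at the
#' envelope maximum (MPAP). Ties in amplitude are broken towards the higher
#' pressure. Pulse cycles are delimited by successive peaks of the
#' (optionally band-passed) pulse.
#'
#' @param pressure Cuff-pressure series (mmHg).
#' @param pulse Co-registered pulse series (same length and rate).
#' @param fs Sampling rate (Hz).
#' @param band Pass band (Hz) applied to the pulse (zero-phase, order-2
#'   Butterworth) before amplitude extraction, mimicking AC coupling;
#'   `NULL` to use the raw pulse. Default `c(0.5, 20)`.
#' @param min_cycles Minimum number of detectable pulse cycles. Default 5.
#' @param check_monotone Warn when the pressure segment is not monotonically
#'   non-increasing. Default `TRUE`.
#'
#' @return An object of class `mpap_result`: a list with `mpap` (mmHg),
#'   `envelope` (tibble of `pressure`, `amplitude`), and `n_cycles`.
#' @export
compute_mpap <- function(pressure, pulse, fs, band = c(0.5, 20), min_cycles = 5L,
                         check_monotone = TRUE) {
  stopifnot(length(pressure) == length(pulse))
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  if (check_monotone && any(diff(pressure) > 1e-9)) {
    warn("pressure segment is not monotonically non-increasing; proceeding")
  }
  x <- pulse
  if (!is.null(band)) {
    bf <- signal::butter(2, band / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, pulse - mean(pulse))
  }
  peaks <- find_pulse_peaks(x, fs)
  if (length(peaks) < min_cycles + 1L) {
    abort(sprintf("insufficient pulse cycles (%d) to build an envelope; need >= %d",
                  max(0L, length(peaks) - 1L), min_cycles),
          class = "cardiocuff_insufficient_data")
  }
  n_cyc <- length(peaks) - 1L
  amp <- numeric(n_cyc)
  pres <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    idx <- peaks[i]:(peaks[i + 1L] - 1L)
    amp[i] <- max(x[idx]) - min(x[idx])
    pres[i] <- mean(pressure[idx])
  }
  # argmax of amplitude; ties go to the higher pressure
  best <- 1L
  for (i in seq_len(n_cyc)) {
    if (amp[i] > amp[best] || (amp[i] == amp[best] && pres[i] > pres[best])) {
      best <- i
    }
  }
  structure(
    list(
      mpap = pres[best],
      envelope = tibble(pressure = pres, amplitude = amp),
      n_cycles = n_cyc
    ),
    class = "mpap_result"
  )
}

# local maxima with a refractory separation and a small relative height floor
find_pulse_peaks <- function(x, fs, min_separation = 0.33, min_height = 0.05) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] >= x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  rng <- max(x) - min(x)
  cand <- cand[x[cand] - min(x) >= min_height * rng]
  if (length(cand) == 0L) return(integer(0))
  # greedy: keep the larger of any two peaks closer than the separation
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0L || (i - keep[length(keep)]) >= min_separation * fs) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}

#' @export
print.mpap_result <- function(x, ...) {
  cat(sprintf("<mpap_result> MPAP = %.2f mmHg from %d cycles\n", x$mpap, x$n_cycles))
  invisible(x)
}

#' Export a schedule as JSON
#'
#' @param schedule A `cuff_protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(schedule, path) {
  cfg <- attr(schedule, "config")
  obj <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    segments = lapply(seq_len(nrow(schedule)), function(i) {
      list(
        segment = schedule$segment[i],
        is_rmps = schedule$is_rmps[i],
        pressure_mode = schedule$pressure_mode[i],
        pressure_target = schedule$pressure_target[i],
        cuffs = schedule$cuffs[[i]],
        t_start = schedule$t_start[i],
        t_end = schedule$t_end[i]
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
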