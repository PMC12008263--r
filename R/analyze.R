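#' Analyze a multi-channel recording
#'
#' Runs the full analysis stack on a recording: 5-point smoothing, R-peak
#' detection, calculated-cycle selection by the base-time rule, per-cycle
#' time-domain parameters for every analyzable channel (all but the six
#' cuff-pressure channels), per-segment aggregates (mean/SD/NSD), left-right
#' ratios, oscillometric blood pressure and MPAP from the two deflation
#' segments, SpO2 from the dual-wavelength ratio-of-ratios in the
#' no-pressure segment, occlusion-phase trend statistics (ACR/ROS/NROS),
#' pulse wave velocity from RWMACR timings, and FFT harmonic-band
#' statistics per channel and segment.
#'
#' @param rec A `cuff_recording` (calibrated units) from
#'   [simulate_recording()] or [read_recording()].
#' @param c_sys,c_dia Oscillometric coefficients; per-site overrides via a
#'   tibble with columns `site`, `c_sys`, `c_dia` in `bp_coefficients`.
#' @param bp_coefficients Optional per-site coefficient overrides.
#' @param n_harmonics Harmonics for the band statistics. Default 10.
#' @param compute_bands Compute the frequency-domain block. Default `TRUE`.
#' @param acr_convention Passed to [bodws_trend()].
#' @return An object of class `cuff_analysis`: list with `partition`, `hr`
#'   (per segment), `params` (long per-cycle table), `aggregates`,
#'   `lr_ratios`, `bp`, `spo2`, `bodws_trends`, `pwv`, `band_stats`,
#'   `base_time`.
#' @export
analyze_recording <- function(rec,
                              c_sys = 0.55, c_dia = 0.75,
                              bp_coefficients = NULL,
                              n_harmonics = 10L,
                              compute_bands = TRUE,
                              acr_convention = "as_printed") {
  if (rec$units != "calibrated") {
    abort("recording must be in calibrated units; dequantize first")
  }
  chans <- rec$channels
  ecg_row <- which(chans$kind == "ECG")
  if (length(ecg_row) != 1L) abort("recording must contain exactly one ECG channel")
  ecg_fs <- chans$fs[ecg_row]
  ecg <- smooth5(chans$samples[[ecg_row]])
  r_peaks <- detect_r_peaks(ecg, ecg_fs)
  partition <- select_calculated_cycles(r_peaks, ecg_fs, rec$segments)
  acc <- partition$cycles[partition$cycles$accepted, ]
  hr <- acc |>
    dplyr::group_by(rmps = .data$rmps) |>
    dplyr::summarise(hr_bpm = 60 / mean(.data$rr), n_cycles = dplyr::n(),
                     .groups = "drop")

  smoothed <- lapply(chans$samples, smooth5)
  names(smoothed) <- chans$channel_id

  # ---- per-cycle time-domain parameters ----------------------------------
  params <- purrr::map_dfr(seq_len(nrow(chans)), function(i) {
    kind <- chans$kind[i]
    if (kind == "CUFF_PRESSURE") return(tibble())
    x <- smoothed[[i]]
    fs <- chans$fs[i]
    if (kind == "ECG") {
      per <- purrr::map_dfr(seq_len(nrow(acc)), function(j) {
        ecg_cycle_params(x, fs, acc$r_start[j], acc$r_end[j]) |>
          dplyr::mutate(cycle = acc$cycle[j], rmps = acc$rmps[j])
      })
    } else {
      sl <- slice_cycles(x, fs, partition)
      sl <- sl[!sl$empty, ]
      per <- purrr::map_dfr(seq_len(nrow(sl)), function(j) {
        seg <- x[sl$start_idx[j]:sl$end_idx[j]]
        p <- if (kind %in% c("HS", "LS")) {
          sound_cycle_params(seg, fs, kind)
        } else {
          pulse_cycle_params(seg, fs)
        }
        dplyr::mutate(p, cycle = sl$cycle[j], rmps = sl$rmps[j])
      })
    }
    dplyr::mutate(per,
                  channel_id = chans$channel_id[i], kind = kind,
                  site = chans$site[i], side = chans$side[i],
                  wavelength = chans$wavelength[i])
  })

  aggregates <- aggregate_rmps(params)
  lr <- left_right_ratios(aggregates)

  # ---- oscillometric blood pressure from the two deflations --------------
  coefs_for <- function(site) {
    if (!is.null(bp_coefficients) && site %in% bp_coefficients$site) {
      row <- bp_coefficients[bp_coefficients$site == site, ]
      list(c_sys = row$c_sys[1L], c_dia = row$c_dia[1L])
    } else {
      list(c_sys = c_sys, c_dia = c_dia)
    }
  }
  deflations <- list(RMPS2 = c("wrist", "ankle"), RMPS5 = c("arm", "ankle"))
  bp <- purrr::map_dfr(names(deflations), function(rm) {
    win <- rec$segments[rec$segments$rmps == rm, ]
    purrr::map_dfr(deflations[[rm]], function(site) {
      purrr::map_dfr(c("L", "R"), function(side) {
        pid <- sprintf("pps_%s_%s", site, side)
        cid <- sprintf("cuff_%s_%s", site, side)
        if (!pid %in% chans$channel_id || !cid %in% chans$channel_id) return(tibble())
        fs <- chans$fs[match(pid, chans$channel_id)]
        cf <- coefs_for(site)
        res <- tryCatch(
          oscillometric_bp(smoothed[[cid]], smoothed[[pid]], fs,
                           c(win$t_start, win$t_end),
                           c_sys = cf$c_sys, c_dia = cf$c_dia,
                           site = site, side = side),
          error = function(e) tibble(site = site, side = side,
                                     sbp = NA_real_, dbp = NA_real_,
                                     mpap = NA_real_, n_cycles = 0L,
                                     c_sys = cf$c_sys, c_dia = cf$c_dia,
                                     flag = conditionMessage(e))
        )
        dplyr::mutate(as_tibble(res), rmps = rm)
      })
    })
  })

  # ---- SpO2 from the ratio-of-ratios in the no-pressure segment ----------
  extremities <- chans |>
    dplyr::filter(.data$kind == "BODWS") |>
    dplyr::distinct(.data$site, .data$side)
  spo2 <- purrr::map_dfr(seq_len(nrow(extremities)), function(e) {
    site <- extremities$site[e]; side <- extremities$side[e]
    id660 <- sprintf("bodws_%s_%s_660", site, side)
    id940 <- sprintf("bodws_%s_%s_940", site, side)
    if (!all(c(id660, id940) %in% chans$channel_id)) return(tibble())
    fs <- chans$fs[match(id660, chans$channel_id)]
    rv <- r_value_per_cycle(smoothed[[id660]], smoothed[[id940]], partition, fs) |>
      dplyr::filter(.data$rmps == "RMPS1", is.na(.data$flag))
    if (nrow(rv) == 0L) {
      return(tibble(site = site, side = side, spo2 = NA_real_, n_cycles = 0L))
    }
    tibble(site = site, side = side,
           spo2 = mean(spo2_from_r(rv$r)), n_cycles = nrow(rv))
  })

  # ---- occlusion-phase trends (ACR/ROS/NROS) -----------------------------
  trends <- purrr::map_dfr(seq_len(nrow(extremities)), function(e) {
    site <- extremities$site[e]; side <- extremities$side[e]
    id660 <- sprintf("bodws_%s_%s_660", site, side)
    id940 <- sprintf("bodws_%s_%s_940", site, side)
    if (!all(c(id660, id940) %in% chans$channel_id)) return(tibble())
    fs <- chans$fs[match(id660, chans$channel_id)]
    purrr::map_dfr(c("RMPS4", "RMPS7"), function(rm) {
      win <- rec$segments[rec$segments$rmps == rm, ]
      bodws_trend(chans$samples[[match(id660, chans$channel_id)]],
                  chans$samples[[match(id940, chans$channel_id)]],
                  fs, partition, c(win$t_start, win$t_end),
                  convention = acr_convention) |>
        dplyr::mutate(site = site, side = side, rmps = rm)
    })
  })

  # ---- pulse wave velocity ----------------------------------------------
  rwmacr_times <- function(channel_id, rmps = "RMPS1") {
    rows <- params |>
      dplyr::filter(.data$channel_id == !!channel_id,
                    .data$parameter == "t_RWMACR",
                    .data$rmps == !!rmps, is.finite(.data$value))
    stats::setNames(rows$value, rows$cycle)
  }
  height <- rec$profile$height %||% NA_real_
  pwv_tab <- tibble()
  if (is.finite(height)) {
    pwv_tab <- purrr::map_dfr(c("L", "R"), function(side) {
      dplyr::bind_rows(
        if (sprintf("pps_ankle_%s", side) %in% chans$channel_id) {
          tb <- rwmacr_times(sprintf("pps_ankle_%s", side))
          if (length(tb) > 0) {
            pwv(0, tb, path_length_heart_ankle(height),
                site_a = "heart", site_b = sprintf("ankle_%s", side))
          }
        },
        if (sprintf("pps_arm_%s", side) %in% chans$channel_id) {
          tb <- rwmacr_times(sprintf("pps_arm_%s", side))
          if (length(tb) > 0) {
            pwv(0, tb, path_length_heart_arm(height),
                site_a = "heart", site_b = sprintf("arm_%s", side))
          }
        }
      )
    })
  }

  # ---- frequency-domain block -------------------------------------------
  bands <- tibble()
  if (compute_bands) {
    hr_hz <- stats::setNames(bpm_to_hz(hr$hr_bpm), hr$rmps)
    bands <- purrr::map_dfr(seq_len(nrow(chans)), function(i) {
      if (chans$kind[i] == "CUFF_PRESSURE") return(tibble())
      fs <- chans$fs[i]
      x <- chans$samples[[i]]
      purrr::map_dfr(seq_len(nrow(rec$segments)), function(s) {
        rm <- rec$segments$rmps[s]
        if (!rm %in% names(hr_hz)) return(tibble())
        i1 <- max(1L, floor(rec$segments$t_start[s] * fs) + 1L)
        i2 <- min(length(x), ceiling(rec$segments$t_end[s] * fs))
        spec <- tryCatch(spectrum_fft(x[i1:i2], fs), error = function(e) NULL)
        if (is.null(spec)) return(tibble())
        band_stats(spec, hr_hz[[rm]], n_harmonics = n_harmonics) |>
          dplyr::mutate(channel_id = chans$channel_id[i], rmps = rm)
      })
    })
  }

  structure(
    list(
      partition = partition,
      base_time = partition$base_time,
      hr = hr,
      params = params,
      aggregates = aggregates,
      lr_ratios = lr,
      bp = bp,
      spo2 = spo2,
      bodws_trends = trends,
      pwv = pwv_tab,
      band_stats = bands
    ),
    class = "cuff_analysis"
  )
}

#' @export
print.cuff_analysis <- function(x, ...) {
  cat(sprintf(
    "<cuff_analysis> base time %.3f s, %d accepted cycles, %d parameter rows\n",
    x$base_time, sum(x$partition$cycles$accepted), nrow(x$params)))
  invisible(x)
}

#' @export
tidy.cuff_analysis <- function(x, ...) x$params

#' @export
glance.cuff_analysis <- function(x, ...) {
  tqs <- x$aggregates |>
    dplyr::filter(.data$parameter == "t_QS")
  s21 <- x$aggregates |>
    dplyr::filter(.data$parameter == "s2_over_s1")
  tibble(
    base_time_s = x$base_time,
    hr_bpm = 60 / mean(x$partition$cycles$rr[x$partition$cycles$accepted]),
    n_cycles = sum(x$partition$cycles$accepted),
    t_qs_mean_s = if (nrow(tqs) > 0) mean(tqs$mean) else NA_real_,
    s1_s2_ratio = if (nrow(s21) > 0) 1 / mean(s21$mean) else NA_real_,
    mean_spo2 = if (nrow(x$spo2) > 0) mean(x$spo2$spo2, na.rm = TRUE) else NA_real_
  )
}
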