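#' Fiducial search windows for ECG cycle parameters
#'
#' The windows (seconds relative to the R peak, or to the S point for the T
#' wave) within which the Q, S, P and T fiducials are located.
#'
#' @param q_before Width of the pre-R window searched for the Q minimum.
#' @param s_after Width of the post-R window searched for the S minimum.
#' @param p_window Two-element window (earliest, latest) before R searched
#'   for the P maximum.
#' @param t_window Two-element window after S searched for the T maximum.
#' @return A named list of window constants.
#' @export
ecg_windows <- function(q_before = 0.06, s_after = 0.10,
                        p_window = c(0.25, 0.08), t_window = c(0.08, 0.40)) {
  list(q_before = q_before, s_after = s_after,
       p_window = p_window, t_window = t_window)
}

param_row <- function(parameter, value, flag = NA_character_) {
  tibble(parameter = parameter, value = value, flag = flag)
}

safe_ratio <- function(num, den) {
  if (!is.finite(den) || den == 0) NA_real_ else num / den
}

#' Per-cycle ECG parameters
#'
#' Locates the Q, S, P and T fiducials around one R peak and derives the
#' cycle's amplitude differences (`A_RQ`, `A_SR`, `A_ST`, `A_SP`), their
#' ratios, the timings (`t_RR`, `t_QS`, `t_RP`, `t_RT`, `t_RP/t_RT`) and the
#' normalized maximum amplitude-change rates of the Q-to-R and S-to-R limbs
#' (max |derivative| over the limb divided by the limb's maximum value).
#'
#' @param ecg Full ECG series (smoothed).
#' @param fs ECG sampling rate (Hz).
#' @param r_idx Sample index of the cycle's R peak.
#' @param r_next_idx Sample index of the next R peak.
#' @param windows Fiducial windows from [ecg_windows()].
#' @return Long tibble with columns `parameter`, `value`, `flag`.
#' @export
ecg_cycle_params <- function(ecg, fs, r_idx, r_next_idx, windows = ecg_windows()) {
  n <- length(ecg)
  w <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi < lo) NULL else lo:hi
  }
  t_rr <- (r_next_idx - r_idx) / fs
  q_win <- w(r_idx - round(windows$q_before * fs), r_idx)
  s_win <- w(r_idx, r_idx + round(windows$s_after * fs))
  p_win <- w(r_idx - round(windows$p_window[1] * fs),
             r_idx - round(windows$p_window[2] * fs))
  if (is.null(q_win) || is.null(s_win) || is.null(p_win)) {
    return(param_row("t_RR", t_rr, "short_cycle"))
  }
  i_q <- q_win[which.min(ecg[q_win])]
  i_s <- s_win[which.min(ecg[s_win])]
  i_p <- p_win[which.max(ecg[p_win])]
  t_win <- w(i_s + round(windows$t_window[1] * fs),
             i_s + round(windows$t_window[2] * fs))
  t_win <- t_win[t_win < r_next_idx]
  i_t <- if (length(t_win) > 0) t_win[which.max(ecg[t_win])] else NA_integer_
  a_rq <- ecg[r_idx] - ecg[i_q]
  a_sr <- ecg[r_idx] - ecg[i_s]
  a_st <- if (is.na(i_t)) NA_real_ else ecg[i_t] - ecg[i_s]
  a_sp <- ecg[i_p] - ecg[i_s]
  nmacr_limb <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    mx <- max(ecg[idx])
    if (mx <= 0) return(NA_real_)
    max(abs(derivative(ecg[idx], fs))) / mx
  }
  dplyr::bind_rows(
    param_row("t_RR", t_rr),
    param_row("A_RQ", a_rq),
    param_row("A_SR", a_sr),
    param_row("A_ST", a_st, if (is.na(i_t)) "no_t_wave" else NA_character_),
    param_row("A_SP", a_sp),
    param_row("A_RQ_over_A_SR", safe_ratio(a_rq, a_sr)),
    param_row("A_SP_over_A_ST", if (is.na(a_st)) NA_real_ else safe_ratio(a_sp, a_st)),
    param_row("t_QS", (i_s - i_q) / fs),
    param_row("t_RP", (r_idx - i_p) / fs),
    param_row("t_RT", if (is.na(i_t)) NA_real_ else (i_t - r_idx) / fs),
    param_row("t_RP_over_t_RT",
              if (is.na(i_t)) NA_real_ else safe_ratio((r_idx - i_p), (i_t - r_idx))),
    param_row("NMACR_QR", nmacr_limb(i_q:r_idx)),
    param_row("NMACR_SR", nmacr_limb(i_s:r_idx))
  )
}

#' Per-cycle heart/lung sound parameters
#'
#' Works on the rectified-and-smoothed envelope (20 ms moving average of the
#' absolute value). For heart sound, S1 is the envelope maximum in the first
#' third of the cycle and S2 in the second third. The thirds are
#' equal-duration sub-intervals of the cycle. Parameters include the S1/S2
#' amplitudes and their ratio (HS), the envelope maximum, NMACR (max
#' envelope change rate over envelope maximum), the per-third mean/max
#' ratios, and the segment-2-3-to-segment-1 mean ratios of amplitude and of
#' change rate.
#'
#' @param x One cycle's sound samples.
#' @param fs Sampling rate (Hz).
#' @param kind `"HS"` or `"LS"`.
#' @param env_window Envelope smoothing window (s). Default 0.02.
#' @return Long tibble with columns `parameter`, `value`, `flag`.
#' @export
sound_cycle_params <- function(x, fs, kind = c("HS", "LS"), env_window = 0.02) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 6L) return(param_row("env_max", NA_real_, "short_cycle"))
  env <- moving_average(abs(x), max(3L, round(env_window * fs)))
  if (max(env) <= 0) return(param_row("env_max", NA_real_, "silent"))
  thirds <- list(
    seq_len(floor(n / 3)),
    (floor(n / 3) + 1L):floor(2 * n / 3),
    (floor(2 * n / 3) + 1L):n
  )
  cr <- abs(derivative(env, fs))
  rows <- list(param_row("env_max", max(env)),
               param_row("NMACR", max(cr) / max(env)))
  if (kind == "HS") {
    s1 <- max(env[thirds[[1L]]])
    s2 <- max(env[thirds[[2L]]])
    rows <- c(rows, list(
      param_row("s1_amp", s1),
      param_row("s2_amp", s2),
      param_row("s2_over_s1", safe_ratio(s2, s1),
                if (s1 == 0) "silent_s1" else NA_character_)
    ))
  }
  for (k in 1:3) {
    seg <- thirds[[k]]
    rows <- c(rows, list(
      param_row(sprintf("mean_over_max_seg%d", k),
                safe_ratio(mean(env[seg]), max(env[seg])))
    ))
  }
  seg23 <- c(thirds[[2L]], thirds[[3L]])
  rows <- c(rows, list(
    param_row("amp_mean_seg23_over_seg1",
              safe_ratio(mean(env[seg23]), mean(env[thirds[[1L]]]))),
    param_row("rate_mean_seg23_over_seg1",
              safe_ratio(mean(cr[seg23]), mean(cr[thirds[[1L]]])))
  ))
  dplyr::bind_rows(rows)
}

#' Per-cycle pulse parameters
#'
#' For one cycle of a pulse channel: the max-min amplitude difference
#' (`A_d`), the K value (mean over `A_d`, a waveform roundness index),
#' NMACR (max |derivative| over the maximum value), NMARR (max rising
#' derivative over `A_d`), and the times from the cycle's R peak to the
#' maximum, the minimum and the maximum-change-rate point (the RWMACR time).
#' Derivatives are central differences scaled by `fs`; argmax ties go to
#' the earliest sample.
#'
#' @param x One cycle's samples (the slice starts at the R-peak time on this
#'   channel's clock).
#' @param fs Sampling rate (Hz).
#' @return Long tibble with columns `parameter`, `value`, `flag`.
#' @export
pulse_cycle_params <- function(x, fs) {
  n <- length(x)
  if (n < 3L) return(param_row("A_d", NA_real_, "short_cycle"))
  mx <- max(x); mn <- min(x)
  a_d <- mx - mn
  d <- derivative(x, fs)
  flat <- a_d == 0
  i_max <- which.max(x); i_min <- which.min(x); i_slope <- which.max(d)
  dplyr::bind_rows(
    param_row("A_d", a_d),
    param_row("K", if (flat) NA_real_ else mean(x) / a_d,
              if (flat) "flat_cycle" else NA_character_),
    param_row("NMACR", if (mx <= 0) NA_real_ else max(abs(d)) / mx,
              if (mx <= 0) "nonpositive_max" else NA_character_),
    param_row("NMARR", if (flat || max(d) <= 0) NA_real_ else max(d) / a_d,
              if (flat) "flat_cycle" else NA_character_),
    param_row("t_R_to_max", (i_max - 1L) / fs),
    param_row("t_R_to_min", (i_min - 1L) / fs),
    param_row("t_RWMACR", (i_slope - 1L) / fs)
  )
}

#' Per-segment aggregates of per-cycle parameters
#'
#' Mean, sample standard deviation and normalized standard deviation
#' (NSD = SD/mean) of every parameter over the accepted cycles of each
#' analyzed segment.
#'
#' @param params Long tibble with at least `rmps`, `parameter`, `value`
#'   (and optionally `channel_id`, `site`, `side`).
#' @return Tibble grouped by the identifying columns with `mean`, `sd`,
#'   `nsd`, `n`; NSD is `NA` when the mean is zero.
#' @export
aggregate_rmps <- function(params) {
  keys <- intersect(c("channel_id", "kind", "site", "side", "wavelength",
                      "rmps", "parameter"), names(params))
  params |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) sd(.data$value) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(nsd = dplyr::if_else(.data$mean != 0, .data$sd / abs(.data$mean), NA_real_))
}

#' Left/right ratios of aggregated parameters
#'
#' For every paired channel (site with both sides), parameter and segment,
#' the ratio of the left mean to the right mean.
#'
#' @param agg Aggregate table from [aggregate_rmps()] containing `site`,
#'   `side` (and optionally `kind`, `wavelength`).
#' @return Tibble with the pairing keys, `left`, `right`, `ratio` and `flag`
#'   (`"zero_right"` when the right mean is zero).
#' @export
left_right_ratios <- function(agg) {
  keys <- intersect(c("kind", "site", "wavelength", "rmps", "parameter"), names(agg))
  wide <- agg |>
    dplyr::filter(.data$side %in% c("L", "R")) |>
    dplyr::select(dplyr::all_of(c(keys, "side", "mean"))) |>
    tidyr::pivot_wider(names_from = "side", values_from = "mean")
  if (!all(c("L", "R") %in% names(wide))) {
    return(tibble())
  }
  wide |>
    dplyr::filter(!is.na(.data$L), !is.na(.data$R)) |>
    dplyr::mutate(
      ratio = dplyr::if_else(.data$R != 0, .data$L / .data$R, NA_real_),
      flag = dplyr::if_else(.data$R == 0, "zero_right", NA_character_)
    ) |>
    dplyr::rename(left = "L", right = "R")
}

#' Occlusion-phase trend statistics of a dual-wavelength pair
#'
#' Over one blocking-flow segment, computes per wavelength the last-minus-
#' first difference (`DI`), the mean per-cycle last-minus-first change
#' (`A`), the segment duration (`T`), and the average change rate
#' `ACR = A/(DI * T)`; then `ROS = ACR_660/ACR_940` and the baseline-
#' normalized `NROS = (ACR_940 * MD1_660)/(ACR_660 * MD1_940)`, where
#' `MD1` is the mean per-cycle max-min amplitude during the no-pressure
#' segment. The alternative convention `ACR = DI/T` is available via
#' `convention = "simple"`.
#'
#' @param ch660,ch940 Dual-wavelength series (same rate), raw; both are
#'   5-point smoothed internally.
#' @param fs Sampling rate (Hz).
#' @param partition A `cycle_partition`.
#' @param window Two-element window `c(t_start, t_end)` (s) of the occlusion
#'   segment.
#' @param baseline_rmps Segment label whose accepted cycles provide `MD1`.
#'   Default `"RMPS1"`.
#' @param convention `"as_printed"` (`A/(DI*T)`) or `"simple"` (`DI/T`).
#' @return One-row tibble with `di_660`, `di_940`, `a_660`, `a_940`,
#'   `t_rmps`, `acr_660`, `acr_940`, `ros`, `md1_660`, `md1_940`, `nros`,
#'   `flag`.
#' @export
bodws_trend <- function(ch660, ch940, fs, partition, window,
                        baseline_rmps = "RMPS1",
                        convention = c("as_printed", "simple")) {
  convention <- match.arg(convention)
  s660 <- smooth5(ch660)
  s940 <- smooth5(ch940)
  i1 <- max(1L, floor(window[1L] * fs) + 1L)
  i2 <- min(length(s660), ceiling(window[2L] * fs))
  t_rmps <- window[2L] - window[1L]
  di <- function(x) x[i2] - x[i1]
  sl <- slice_cycles(s660, fs, partition)
  in_win <- sl$start_idx >= i1 & sl$end_idx <= i2 & !sl$empty
  per_cycle_change <- function(x) {
    vapply(which(in_win), function(j) x[sl$end_idx[j]] - x[sl$start_idx[j]], numeric(1))
  }
  a660 <- mean(per_cycle_change(s660))
  a940 <- mean(per_cycle_change(s940))
  di660 <- di(s660); di940 <- di(s940)
  base <- sl$rmps == baseline_rmps & !sl$empty
  md1 <- function(x) {
    mean(vapply(which(base), function(j) {
      seg <- x[sl$start_idx[j]:sl$end_idx[j]]
      max(seg) - min(seg)
    }, numeric(1)))
  }
  md1_660 <- md1(s660); md1_940 <- md1(s940)
  flag <- NA_character_
  if (!is.finite(di660) || !is.finite(di940) || di660 == 0 || di940 == 0) flag <- "zero_di"
  acr <- function(a, d) {
    if (convention == "simple") return(d / t_rmps)
    if (d == 0) return(NA_real_)
    a / (d * t_rmps)
  }
  acr660 <- acr(a660, di660); acr940 <- acr(a940, di940)
  ros <- if (is.na(flag)) acr660 / acr940 else NA_real_
  if (is.na(flag) && (!is.finite(md1_660) || !is.finite(md1_940) ||
                      md1_660 == 0 || md1_940 == 0)) {
    flag <- "zero_md1"
  }
  nros <- if (is.na(flag) && is.finite(acr660) && acr660 != 0) {
    (acr940 * md1_660) / (acr660 * md1_940)
  } else {
    NA_real_
  }
  tibble(
    di_660 = di660, di_940 = di940, a_660 = a660, a_940 = a940,
    t_rmps = t_rmps, acr_660 = acr660, acr_940 = acr940, ros = ros,
    md1_660 = md1_660, md1_940 = md1_940, nros = nros, flag = flag,
    n_cycles = sum(in_win)
  )
}

#' Arterial path lengths from height regressions
#'
#' `L_heart_to_ankle = 0.8129 * H + 12.328` and
#' `L_heart_to_arm = 0.2195 * H - 2.0734`, H in cm.
#'
#' @param height Subject height (cm).
#' @return Length in cm.
#' @export
path_length_heart_ankle <- function(height) 0.8129 * height + 12.328

#' @rdname path_length_heart_ankle
#' @export
path_length_heart_arm <- function(height) 0.2195 * height - 2.0734

#' Pulse wave velocity between two sites
#'
#' `PWV = L_ab / t_ab`, where `t_ab` is the mean over common accepted cycles
#' of the difference of the two sites' R-to-maximum-change-rate (RWMACR)
#' times. For heart-to-site pairs the proximal RWMACR times are zero (the R
#' peak itself is the proximal event).
#'
#' @param t_a,t_b Named numeric vectors of per-cycle RWMACR times (s), names
#'   the cycle ids; only cycles present in both enter. Pass `t_a = 0` with
#'   no names to use the R peak as the proximal event.
#' @param length_cm Path length between the sites (cm).
#' @param site_a,site_b Labels for the output.
#' @return One-row tibble with `site_a`, `site_b`, `length_cm`, `t_ab_s`,
#'   `pwv_m_s`, `n_cycles`, `flag` (`"nonpositive_t"` when `t_ab <= 0`).
#' @export
pwv <- function(t_a, t_b, length_cm, site_a = "a", site_b = "b") {
  if (length(t_a) == 1L && is.null(names(t_a))) {
    t_a <- stats::setNames(rep(t_a, length(t_b)), names(t_b))
  }
  common <- intersect(names(t_a), names(t_b))
  if (length(common) == 0L) abort("no common cycles between the two sites")
  dt <- t_b[common] - t_a[common]
  t_ab <- mean(dt)
  ok <- is.finite(t_ab) && t_ab > 0
  tibble(
    site_a = site_a, site_b = site_b, length_cm = length_cm,
    t_ab_s = t_ab,
    pwv_m_s = if (ok) (length_cm / 100) / t_ab else NA_real_,
    n_cycles = length(common),
    flag = if (ok) NA_character_ else "nonpositive_t"
  )
}

#' Oscillometric blood pressure from a deflation segment
#'
#' Builds the per-cycle amplitude envelope over the deflation (via
#' [compute_mpap()], restricted to the samples after the pressure maximum of
#' the window), normalizes it by its peak, and reads systolic pressure as
#' the interpolated cuff pressure above MPAP where the normalized amplitude
#' falls to `c_sys`, and diastolic below MPAP at `c_dia`.
#'
#' @param pressure Cuff-pressure series (mmHg).
#' @param pulse Co-registered pressure-pulse series.
#' @param fs Sampling rate of both series (Hz).
#' @param window Two-element `c(t_start, t_end)` (s) of the deflation
#'   segment.
#' @param c_sys,c_dia Normalized amplitude coefficients. Defaults 0.55 and
#'   0.75.
#' @param min_cycles Minimum accepted envelope cycles. Default 8.
#' @param site,side Labels for the output.
#' @return An object of class `bp_result`: one-row tibble with `site`,
#'   `side`, `sbp`, `dbp`, `mpap`, `n_cycles`, `c_sys`, `c_dia`, `flag`;
#'   the envelope is attached as attribute `envelope`.
#' @export
oscillometric_bp <- function(pressure, pulse, fs, window,
                             c_sys = 0.55, c_dia = 0.75,
                             min_cycles = 8L, site = NA_character_,
                             side = NA_character_) {
  i1 <- max(1L, floor(window[1L] * fs) + 1L)
  i2 <- min(length(pressure), ceiling(window[2L] * fs))
  p <- pressure[i1:i2]
  x <- pulse[i1:i2]
  # deflation part only: drop the inflation ramp up to the pressure maximum
  start <- which.max(p)
  p <- p[start:length(p)]
  x <- x[start:length(x)]
  mp <- compute_mpap(smooth5(p), x, fs, min_cycles = min_cycles,
                     check_monotone = FALSE)
  env <- mp$envelope
  ord <- order(env$pressure)
  pr <- env$pressure[ord]
  am <- moving_average(env$amplitude[ord], 3L)  # light envelope smoothing
  am <- am / max(am)
  mpap <- pr[which.max(am)]
  # walk outward from MPAP until the normalized amplitude falls through the
  # coefficient level, then interpolate the cuff pressure linearly
  cross_level <- function(idx, level) {
    if (length(idx) < 2L) return(NA_real_)
    pp <- pr[idx]; aa <- am[idx]
    for (j in seq_len(length(idx) - 1L)) {
      if (aa[j] >= level && aa[j + 1L] <= level) {
        if (aa[j] == aa[j + 1L]) return(pp[j])
        return(pp[j] + (pp[j + 1L] - pp[j]) * (aa[j] - level) / (aa[j] - aa[j + 1L]))
      }
    }
    NA_real_
  }
  sbp <- cross_level(which(pr >= mpap), c_sys)
  dbp <- cross_level(rev(which(pr <= mpap)), c_dia)
  flag <- dplyr::case_when(
    is.na(sbp) && is.na(dbp) ~ "no_envelope_crossing",
    is.na(sbp) ~ "no_systolic_crossing",
    is.na(dbp) ~ "no_diastolic_crossing",
    TRUE ~ NA_character_
  )
  out <- tibble(
    site = site, side = side, sbp = sbp, dbp = dbp, mpap = mpap,
    n_cycles = mp$n_cycles, c_sys = c_sys, c_dia = c_dia, flag = flag
  )
  attr(out, "envelope") <- tibble(pressure = pr, amplitude = am)
  class(out) <- c("bp_result", class(out))
  out
}
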