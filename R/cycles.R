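#' Five-point smoothing filter
#'
#' Centered 5-point moving average applied to every raw channel before
#' analysis. At the edges the window shrinks to the samples available
#' (e.g. the first output is the mean of samples 1-3), so the length is
#' preserved.
#'
#' @param x Numeric series.
#' @return Smoothed series of the same length. Inputs shorter than 5 samples
#'   are passed through with a warning.
#' @export
smooth5 <- function(x) {
  if (length(x) < 5L) {
    warn("series shorter than 5 samples; returning it unsmoothed")
    return(x)
  }
  moving_average(x, 5L)
}

#' Detect ECG R peaks by the differential-threshold method
#'
#' Squares the first difference of the ECG, thresholds it at a fraction of a
#' high percentile computed per block, groups the supra-threshold runs, and
#' refines each group to the local ECG maximum within a small window. A
#' refractory period suppresses double detections.
#'
#' @param ecg ECG series (preferably smoothed with [smooth5()]).
#' @param fs Sampling rate (Hz).
#' @param threshold_quantile Percentile of the squared derivative used as the
#'   threshold reference. Default 0.98.
#' @param threshold_factor Fraction of that percentile used as the threshold.
#'   Default 0.4.
#' @param refractory Minimum R-R separation in seconds. Default 0.25.
#' @param refine_window Half-width (s) of the window searched for the local
#'   ECG maximum around each candidate. Default 0.05.
#' @param block Block length (s) over which the threshold is computed.
#'   Default 10.
#' @return Integer vector of R-peak sample indices (empty, with a warning,
#'   when nothing crosses the threshold).
#' @export
detect_r_peaks <- function(ecg, fs,
                           threshold_quantile = 0.98,
                           threshold_factor = 0.4,
                           refractory = 0.25,
                           refine_window = 0.05,
                           block = 10) {
  if (length(ecg) < 2 * fs) abort("need at least 2 s of ECG")
  n <- length(ecg)
  sq <- c(diff(ecg) * fs, 0)^2
  # per-block adaptive threshold
  nb <- max(1L, ceiling(n / (block * fs)))
  thr <- numeric(n)
  for (b in seq_len(nb)) {
    i1 <- (b - 1L) * block * fs + 1L
    i2 <- min(n, b * block * fs)
    thr[i1:i2] <- threshold_factor * quantile(sq[i1:i2], threshold_quantile, names = FALSE)
  }
  cand <- which(sq > thr & thr > 0)
  if (length(cand) == 0L) {
    warn("no R peaks detected")
    return(integer(0))
  }
  # group candidates separated by less than the refractory period
  grp <- cumsum(c(1L, diff(cand) > refractory * fs))
  half <- round(refine_window * fs)
  peaks <- vapply(split(cand, grp), function(g) {
    lo <- max(1L, min(g) - as.integer(half))
    hi <- min(n, max(g) + as.integer(half))
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory on the refined peaks, keeping the taller
  if (length(peaks) > 1L) {
    keep <- peaks[1L]
    for (p in peaks[-1L]) {
      last <- keep[length(keep)]
      if (p - last >= refractory * fs) {
        keep <- c(keep, p)
      } else if (ecg[p] > ecg[last]) {
        keep[length(keep)] <- p
      }
    }
    peaks <- keep
  }
  unname(peaks)
}

#' Select calculated cycles by the base-time rule
#'
#' Sorts all R-R intervals ascending, takes the mean of the middle 50 %
#' (trimming `ceiling(N/4)` intervals from each end) as the base time, and
#' accepts an interval as a calculated cycle iff it lies within 0.7 to 1.6
#' times the base time (closed interval). Each cycle is assigned to the
#' analyzed segment containing its starting R peak; when `rmps_windows` is
#' supplied, intervals starting outside every window are excluded from the
#' base-time computation and rejected with reason `"outside_rmps"`.
#'
#' @param r_peaks R-peak sample indices on the ECG clock.
#' @param fs ECG sampling rate (Hz).
#' @param rmps_windows Optional tibble (`rmps`, `t_start`, `t_end`) from
#'   [rmps_windows()]; `NULL` treats the whole series as one window.
#' @param lower,upper Acceptance bounds as multiples of the base time.
#'   Defaults 0.7 and 1.6.
#' @return An object of class `cycle_partition`: list with `r_peaks`, `fs`,
#'   `base_time` (s) and `cycles`, a tibble with one row per R-R interval
#'   (`cycle`, `r_start`, `r_end`, `t_start`, `rr`, `rmps`, `accepted`,
#'   `reason`).
#' @export
select_calculated_cycles <- function(r_peaks, fs, rmps_windows = NULL,
                                     lower = 0.7, upper = 1.6) {
  if (length(r_peaks) < 5L) abort("need at least 4 R-R intervals")
  if (any(diff(r_peaks) <= 0)) abort("`r_peaks` must be strictly increasing")
  rr <- diff(r_peaks) / fs
  t_start <- (r_peaks[-length(r_peaks)] - 1) / fs
  rmps <- rep(NA_character_, length(rr))
  if (!is.null(rmps_windows)) {
    for (i in seq_len(nrow(rmps_windows))) {
      inside <- t_start >= rmps_windows$t_start[i] & t_start < rmps_windows$t_end[i]
      rmps[inside] <- rmps_windows$rmps[i]
    }
    in_rmps <- !is.na(rmps)
  } else {
    in_rmps <- rep(TRUE, length(rr))
  }
  if (sum(in_rmps) < 4L) abort("need at least 4 R-R intervals inside analyzed segments")
  srt <- sort(rr[in_rmps])
  n <- length(srt)
  k <- ceiling(n / 4)
  mid <- srt[(k + 1L):(n - k)]
  if (length(mid) == 0L) mid <- srt
  base_time <- mean(mid)
  accepted <- in_rmps & rr >= lower * base_time & rr <= upper * base_time
  reason <- dplyr::case_when(
    !in_rmps ~ "outside_rmps",
    rr < lower * base_time ~ "below_lower_bound",
    rr > upper * base_time ~ "above_upper_bound",
    TRUE ~ NA_character_
  )
  structure(
    list(
      r_peaks = r_peaks,
      fs = fs,
      base_time = base_time,
      cycles = tibble(
        cycle = seq_along(rr),
        r_start = r_peaks[-length(r_peaks)],
        r_end = r_peaks[-1L],
        t_start = t_start,
        rr = rr,
        rmps = rmps,
        accepted = accepted,
        reason = reason
      )
    ),
    class = "cycle_partition"
  )
}

#' @export
print.cycle_partition <- function(x, ...) {
  cat(sprintf("<cycle_partition> %d R peaks, base time %.3f s, %d/%d cycles accepted\n",
              length(x$r_peaks), x$base_time, sum(x$cycles$accepted), nrow(x$cycles)))
  invisible(x)
}

#' @export
tidy.cycle_partition <- function(x, ...) x$cycles

#' Slice a channel into per-cycle segments
#'
#' Maps each accepted cycle's half-open time window `[t(R_i), t(R_i+1))` onto
#' a channel sampled at its own rate and returns the index ranges. Sample k
#' of a channel has time `(k - 1)/fs`.
#'
#' @param x Channel series.
#' @param fs Sampling rate of `x` (Hz).
#' @param partition A `cycle_partition`.
#' @param accepted_only Keep only accepted cycles. Default `TRUE`.
#' @return Tibble with columns `cycle`, `rmps`, `r_time` (time of the
#'   starting R peak, s), `start_idx`, `end_idx` (1-based, inclusive) and
#'   `empty` (flag for zero-length slices).
#' @export
slice_cycles <- function(x, fs, partition, accepted_only = TRUE) {
  cyc <- partition$cycles
  if (accepted_only) cyc <- cyc[cyc$accepted, ]
  t0 <- (cyc$r_start - 1) / partition$fs
  t1 <- (cyc$r_end - 1) / partition$fs
  eps <- 1e-9
  start_idx <- pmax(1L, as.integer(ceiling(t0 * fs - eps)) + 1L)
  end_idx <- pmin(length(x), as.integer(ceiling(t1 * fs - eps)))
  tibble(
    cycle = cyc$cycle,
    rmps = cyc$rmps,
    r_time = t0,
    start_idx = start_idx,
    end_idx = end_idx,
    empty = end_idx < start_idx
  )
}

#' Export a cycle partition as CSV
#' @param partition A `cycle_partition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  utils::write.csv(partition$cycles, path, row.names = FALSE, na = "")
  invisible(path)
}
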