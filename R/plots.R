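#' Plot the cuff-pressure schedule
#'
#' Ideal pressure waveform of each cuff over the whole schedule, faceted by
#' cuff site.
#'
#' @param object A `cuff_protocol`.
#' @param mpap MPAP (mmHg) used for the constant-MPAP holds. Default 93.
#' @param fs Sampling rate of the plotted traces. Default 10 (plots only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cuff_protocol <- function(object, mpap = 93, fs = 10, ...) {
  df <- purrr::map_dfr(cuff_sites(), function(cs) {
    p <- cuff_pressure_trace(object, cs, mpap = mpap, fs = fs)
    tibble(cuff = cs, time = (seq_along(p) - 1) / fs, pressure = p)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~cuff, ncol = 2) +
    ggplot2::labs(x = "time (s)", y = "cuff pressure (mmHg)")
}

#' Plot an oscillometric envelope
#'
#' Per-cycle pulse amplitude against mean cuff pressure, with the MPAP
#' marked.
#'
#' @param object An `mpap_result` from [compute_mpap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mpap_result <- function(object, ...) {
  ggplot2::ggplot(object$envelope,
                  ggplot2::aes(x = .data$pressure, y = .data$amplitude)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$mpap, linetype = 2) +
    ggplot2::labs(x = "cuff pressure (mmHg)", y = "pulse amplitude (a.u.)")
}

#' Plot channels of a recording
#'
#' @param rec A `cuff_recording`.
#' @param channel_ids Channels to plot (default the first four).
#' @param window Optional `c(t_start, t_end)` window in seconds.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, channel_ids = utils::head(rec$channels$channel_id, 4L),
                           window = NULL) {
  df <- purrr::map_dfr(channel_ids, function(id) {
    i <- match(id, rec$channels$channel_id)
    x <- rec$channels$samples[[i]]
    fs <- rec$channels$fs[i]
    t <- (seq_along(x) - 1) / fs
    keep <- if (is.null(window)) TRUE else t >= window[1L] & t < window[2L]
    tibble(channel = id, time = t[keep], value = x[keep])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot harmonic-band statistics
#'
#' RAMF (band mean over band maximum) per harmonic, one line per channel.
#'
#' @param bands Band-statistics tibble from [analyze_recording()] or
#'   [band_stats()] (with a `channel_id` column).
#' @param rmps Segment to show. Default `"RMPS1"`.
#' @return A ggplot object.
#' @export
plot_band_stats <- function(bands, rmps = "RMPS1") {
  df <- bands[bands$rmps == rmps & is.na(bands$flag), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$ramf,
                                   colour = .data$channel_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "harmonic of heart rate", y = "RAMF", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
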