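RECORDING_SCHEMA_VERSION <- "1.0"

#' Write a recording to a directory container
#'
#' Canonical on-disk form: one two-column CSV per channel (`sample`,
#' `value`) plus a `recording.json` sidecar holding the schema version,
#' channel table, sampling rates, units, analyzed-segment windows, seed and
#' subject metadata. Values are serialized with full precision, so a
#' write/read round trip is lossless.
#'
#' @param rec A `cuff_recording`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  chans <- rec$channels
  files <- paste0(chans$channel_id, ".csv")
  for (i in seq_len(nrow(chans))) {
    x <- chans$samples[[i]]
    df <- data.frame(sample = seq_along(x), value = x)
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     file.path(path, files[i]), row.names = FALSE, quote = FALSE)
  }
  profile <- rec$profile
  sidecar <- list(
    schema_version = RECORDING_SCHEMA_VERSION,
    units = rec$units,
    seed = rec$seed,
    channels = lapply(seq_len(nrow(chans)), function(i) {
      ch <- list(channel_id = chans$channel_id[i], kind = chans$kind[i],
                 site = chans$site[i], side = chans$side[i],
                 wavelength = if (is.na(chans$wavelength[i])) NULL else chans$wavelength[i],
                 fs = chans$fs[i], file = files[i], n = length(chans$samples[[i]]))
      ch[!vapply(ch, is.null, logical(1))]
    }),
    segments = lapply(seq_len(nrow(rec$segments)), function(i) {
      list(rmps = rec$segments$rmps[i],
           t_start = rec$segments$t_start[i],
           t_end = rec$segments$t_end[i])
    }),
    profile = if (!is.null(profile)) {
      list(heart_rate = profile$heart_rate, height = profile$height,
           seed = profile$seed)
    }
  )
  jsonlite::write_json(sidecar, file.path(path, "recording.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording from a directory container
#'
#' Validates the sidecar against the files present: every listed channel
#' file must exist, have the declared number of samples, and the schema
#' version must be known.
#'
#' @param path Recording directory containing `recording.json`.
#' @return A `cuff_recording`.
#' @export
read_recording <- function(path) {
  sidecar_path <- file.path(path, "recording.json")
  if (!file.exists(sidecar_path)) {
    abort(sprintf("no recording.json in `%s`", path))
  }
  sc <- jsonlite::read_json(sidecar_path)
  if (!identical(sc$schema_version, RECORDING_SCHEMA_VERSION)) {
    abort(sprintf("unsupported schema version `%s` (expected %s)",
                  sc$schema_version %||% "<missing>", RECORDING_SCHEMA_VERSION))
  }
  chans <- purrr::map_dfr(sc$channels, function(ch) {
    wl <- ch$wavelength
    if (is.null(wl) || length(wl) == 0L) wl <- NA_real_
    tibble(channel_id = ch$channel_id, kind = ch$kind, site = ch$site,
           side = ch$side, wavelength = as.numeric(wl),
           fs = ch$fs, file = ch$file, n = ch$n)
  })
  samples <- vector("list", nrow(chans))
  for (i in seq_len(nrow(chans))) {
    f <- file.path(path, chans$file[i])
    if (!file.exists(f)) {
      abort(sprintf("channel `%s`: file %s is missing", chans$channel_id[i],
                    chans$file[i]))
    }
    df <- utils::read.csv(f)
    if (nrow(df) != chans$n[i]) {
      abort(sprintf("channel `%s`: %d samples on disk but sidecar declares %d",
                    chans$channel_id[i], nrow(df), chans$n[i]))
    }
    samples[[i]] <- as.numeric(df$value)
  }
  segments <- purrr::map_dfr(sc$segments, function(s) {
    tibble(rmps = s$rmps, t_start = s$t_start, t_end = s$t_end)
  })
  chans$samples <- samples
  chans$file <- NULL
  chans$n <- NULL
  structure(
    list(
      channels = chans,
      segments = segments,
      schedule = NULL,
      profile = if (!is.null(sc$profile)) {
        list(heart_rate = sc$profile$heart_rate, height = sc$profile$height,
             seed = sc$profile$seed)
      },
      units = sc$units,
      seed = sc$seed %||% NA_integer_,
      r_times = NULL
    ),
    class = "cuff_recording"
  )
}

#' Write analysis results to report files
#'
#' Emits machine-readable tables (`params.csv`, `aggregates.csv`,
#' `lr_ratios.csv`, `bp.csv`, `band_stats.csv`) and a human-oriented
#' `summary.json` listing heart rate, per-site blood pressure, the mean
#' Q-to-S time, the mean S1/S2 amplitude ratio, pulse wave velocity, SpO2
#' and the occlusion trend ratios.
#'
#' @param analysis A `cuff_analysis`.
#' @param path Directory to write into.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(path, name), row.names = FALSE, na = "")
  }
  wr(analysis$params, "params.csv")
  wr(analysis$aggregates, "aggregates.csv")
  if (nrow(analysis$lr_ratios) > 0) wr(analysis$lr_ratios, "lr_ratios.csv")
  if (nrow(analysis$bp) > 0) wr(analysis$bp, "bp.csv")
  if (nrow(analysis$band_stats) > 0) wr(analysis$band_stats, "band_stats.csv")
  g <- glance(analysis)
  num_or_null <- function(v) if (length(v) == 1L && is.finite(v)) v else NULL
  summary <- list(
    heart_rate_bpm = num_or_null(g$hr_bpm),
    base_time_s = num_or_null(g$base_time_s),
    n_accepted_cycles = num_or_null(as.numeric(g$n_cycles)),
    t_qs_mean_s = num_or_null(g$t_qs_mean_s),
    s1_s2_amplitude_ratio = num_or_null(g$s1_s2_ratio),
    blood_pressure = if (nrow(analysis$bp) > 0) {
      lapply(seq_len(nrow(analysis$bp)), function(i) {
        list(site = analysis$bp$site[i], side = analysis$bp$side[i],
             rmps = analysis$bp$rmps[i],
             sbp = num_or_null(analysis$bp$sbp[i]),
             dbp = num_or_null(analysis$bp$dbp[i]),
             mpap = num_or_null(analysis$bp$mpap[i]))
      })
    },
    spo2 = if (nrow(analysis$spo2) > 0) {
      lapply(seq_len(nrow(analysis$spo2)), function(i) {
        list(site = analysis$spo2$site[i], side = analysis$spo2$side[i],
             spo2 = num_or_null(analysis$spo2$spo2[i]))
      })
    },
    pwv = if (nrow(analysis$pwv) > 0) {
      lapply(seq_len(nrow(analysis$pwv)), function(i) {
        list(site_a = analysis$pwv$site_a[i], site_b = analysis$pwv$site_b[i],
             pwv_m_s = num_or_null(analysis$pwv$pwv_m_s[i]))
      })
    },
    occlusion_trends = if (nrow(analysis$bodws_trends) > 0) {
      lapply(seq_len(nrow(analysis$bodws_trends)), function(i) {
        tr <- analysis$bodws_trends[i, ]
        list(site = tr$site, side = tr$side, rmps = tr$rmps,
             ros = num_or_null(tr$ros), nros = num_or_null(tr$nros))
      })
    }
  )
  jsonlite::write_json(summary, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
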