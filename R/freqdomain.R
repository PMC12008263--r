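#' Magnitude spectrum of a segment
#'
#' Magnitude of the discrete Fourier transform of the mean-removed window,
#' with no zero padding: the transform length equals the window length. Bin
#' `m` (0-based) corresponds to frequency `m * FN` with `FN = fs/N`; only
#' bins up to `N/2` are physically one-sided, which is where the harmonic
#' bands live.
#'
#' @param x Channel samples over one analyzed segment.
#' @param fs Sampling rate (Hz).
#' @param min_duration Minimum window length in seconds. Default 4.
#' @return Object of class `cc_spectrum`: list with `magnitude` (full
#'   length-N modulus vector; element `m + 1` is bin `m`), `fn` (Hz per
#'   bin), `n`, `fs`.
#' @export
spectrum_fft <- function(x, fs, min_duration = 4) {
  n <- length(x)
  if (n < min_duration * fs) {
    abort(sprintf("window too short: %.2f s < %g s", n / fs, min_duration))
  }
  structure(
    list(magnitude = Mod(fft(x - mean(x))), fn = fs / n, n = n, fs = fs),
    class = "cc_spectrum"
  )
}

#' @export
print.cc_spectrum <- function(x, ...) {
  cat(sprintf("<cc_spectrum> N = %d, FN = %.5g Hz/bin, fs = %g Hz\n",
              x$n, x$fn, x$fs))
  invisible(x)
}

#' Harmonic-band bin indices
#'
#' The band around harmonic `n` of the heart rate spans bins
#' `Round((n - w) * HR/FN)` to `Round((n + w) * HR/FN)` inclusive
#' (`w = 0.2` by default), with Round = half away from zero. Bin indices are
#' 0-based (bin `m` is frequency `m * FN`). The band rule is applied with
#' the dimensionally consistent `HR/FN`; `literal = TRUE` evaluates the
#' multiplicative form `(n +- w) * FN * HR` instead, for audit.
#'
#' @param n_harmonic Harmonic number (1-10).
#' @param hr Heart rate in Hz (use [bpm_to_hz()] for bpm).
#' @param fn Frequency resolution of the spectrum (Hz per bin).
#' @param half_width Relative band half-width. Default 0.2.
#' @param n_max Optional largest valid bin index; bands reaching beyond are
#'   truncated with a warning.
#' @param literal Use the multiplicative form. Default `FALSE`.
#' @return Integer vector of 0-based bin indices.
#' @export
harmonic_band <- function(n_harmonic, hr, fn, half_width = 0.2,
                          n_max = NULL, literal = FALSE) {
  check_number(n_harmonic, "n_harmonic", min = 1, max = 10)
  check_number(hr, "hr", min = 0, strict_min = TRUE)
  check_number(fn, "fn", min = 0, strict_min = TRUE)
  scale <- if (literal) fn * hr else hr / fn
  lo <- round_half_away((n_harmonic - half_width) * scale)
  hi <- round_half_away((n_harmonic + half_width) * scale)
  if (!is.null(n_max) && hi > n_max) {
    warn(sprintf("harmonic band %g truncated at bin %d", n_harmonic, n_max))
    hi <- n_max
  }
  if (hi < lo) return(integer(0))
  as.integer(lo:hi)
}

#' Convert beats per minute to Hz
#' @param bpm Heart rate in beats per minute.
#' @return Frequency in Hz.
#' @export
bpm_to_hz <- function(bpm) bpm / 60

#' Harmonic-band statistics of a spectrum
#'
#' For each harmonic `n` of the heart rate: the mean (`AveF`) and maximum
#' (`MaxF`) spectral magnitude over the band, their ratio
#' `RAMF = AveF/MaxF`, and the first-harmonic-normalized maximum
#' `RMMF = MaxF_n / MaxF_1`.
#'
#' @param spec A `cc_spectrum` from [spectrum_fft()].
#' @param hr Heart rate in Hz.
#' @param n_harmonics Number of harmonics. Default 10.
#' @param half_width,literal Passed to [harmonic_band()].
#' @return Tibble with columns `n`, `bin_lo`, `bin_hi`, `ave_f`, `max_f`,
#'   `ramf`, `rmmf`, `flag` (`"empty_band"` for out-of-range bands).
#' @export
band_stats <- function(spec, hr, n_harmonics = 10L, half_width = 0.2,
                       literal = FALSE) {
  n_max <- floor(spec$n / 2)
  rows <- purrr::map_dfr(seq_len(n_harmonics), function(nh) {
    idx <- suppressWarnings(
      harmonic_band(nh, hr, spec$fn, half_width, n_max = n_max, literal = literal)
    )
    idx <- idx[idx >= 0L & idx <= n_max]
    if (length(idx) == 0L) {
      return(tibble(n = nh, bin_lo = NA_integer_, bin_hi = NA_integer_,
                    ave_f = NA_real_, max_f = NA_real_, ramf = NA_real_,
                    flag = "empty_band"))
    }
    mag <- spec$magnitude[idx + 1L]
    tibble(n = nh, bin_lo = min(idx), bin_hi = max(idx),
           ave_f = mean(mag), max_f = max(mag), ramf = mean(mag) / max(mag),
           flag = NA_character_)
  })
  rows$rmmf <- rows$max_f / rows$max_f[1L]
  rows
}
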