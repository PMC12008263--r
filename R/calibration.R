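#' ECG voltage calibration
#'
#' Linear map from acquisition values (ADCV) to ECG voltage in mV. The
#' default coefficients are the system's bench calibration against a
#' reference ECG simulator.
#'
#' @param intercept Intercept in mV. Default -0.01042.
#' @param slope Slope in mV per ADCV unit. Default 4.30532e-4.
#' @return An object of class `ecg_calibration`.
#' @export
ecg_calibration <- function(intercept = -0.01042, slope = 4.30532e-4) {
  check_number(intercept, "intercept")
  check_number(slope, "slope", min = 0, strict_min = TRUE)
  structure(list(intercept = intercept, slope = slope), class = "ecg_calibration")
}

#' Convert ADCV to ECG voltage (mV)
#'
#' @param adcv Acquisition values.
#' @param cal An [ecg_calibration()].
#' @return Voltages in mV.
#' @export
#' @examples
#' adcv_to_ecg_mv(0)  # the intercept
adcv_to_ecg_mv <- function(adcv, cal = ecg_calibration()) {
  if (!all(is.finite(adcv))) abort("`adcv` must be finite")
  cal$intercept + cal$slope * adcv
}

#' SpO2 calibration parabola
#'
#' Quadratic map from the dual-wavelength ratio-of-ratios R (the 660 nm
#' per-cycle AC/DC ratio divided by the 940 nm one) to oxygen saturation in
#' percent. Defaults are the system's eight-point bench calibration
#' (60-98 % reference saturations).
#'
#' @param c0,c1,c2 Parabola coefficients (percent units).
#' @return An object of class `spo2_calibration`.
#' @export
spo2_calibration <- function(c0 = -160.01396, c1 = 1370.04653, c2 = 41.14279) {
  check_number(c0, "c0"); check_number(c1, "c1"); check_number(c2, "c2")
  structure(list(c0 = c0, c1 = c1, c2 = c2), class = "spo2_calibration")
}

#' SpO2 from the ratio-of-ratios R
#'
#' Evaluates `c0 + c1*R + c2*R^2` (percent).
#'
#' @param r Ratio-of-ratios values (must be > 0 when `strict`).
#' @param cal A [spo2_calibration()].
#' @param strict Require `r > 0` (the physical domain). Default `TRUE`.
#' @return SpO2 in percent.
#' @export
spo2_from_r <- function(r, cal = spo2_calibration(), strict = TRUE) {
  if (strict && any(r <= 0)) abort("`r` must be positive")
  cal$c0 + cal$c1 * r + cal$c2 * r^2
}

#' Ratio-of-ratios R from SpO2 (inverse of the calibration parabola)
#'
#' Returns the non-negative root of `c2*R^2 + c1*R + (c0 - spo2) = 0`.
#'
#' @param spo2 Oxygen saturation in percent.
#' @param cal A [spo2_calibration()].
#' @return R values.
#' @export
r_from_spo2 <- function(spo2, cal = spo2_calibration()) {
  disc <- cal$c1^2 - 4 * cal$c2 * (cal$c0 - spo2)
  if (any(disc < 0)) abort("no real root: `spo2` outside the parabola's range")
  r <- (-cal$c1 + sqrt(disc)) / (2 * cal$c2)
  if (any(r < 0)) abort("no non-negative root for the given `spo2`")
  r
}

#' Per-cycle ratio-of-ratios from a dual-wavelength pair
#'
#' For each accepted cardiac cycle, computes the pulsation-to-mean ratio
#' `(max - min)/mean` on each wavelength channel and their quotient
#' `R = ratio_660 / ratio_940`. Cycles with a non-positive mean or a zero
#' 940 nm ratio are flagged and excluded from R.
#'
#' @param ch660,ch940 Co-registered 660 nm and 940 nm series (same rate).
#' @param partition A `cycle_partition` from [select_calculated_cycles()].
#' @param fs Sampling rate of the two channels (Hz). Default 400.
#' @return Tibble with columns `cycle`, `rmps`, `ratio660`, `ratio940`, `r`,
#'   `flag` (`NA` when valid).
#' @export
r_value_per_cycle <- function(ch660, ch940, partition, fs = 400) {
  stopifnot(length(ch660) == length(ch940))
  sl <- slice_cycles(ch660, fs, partition)
  if (nrow(sl) == 0L) abort("no accepted cycles")
  ratio_of <- function(x) {
    m <- mean(x)
    if (!is.finite(m) || m <= 0) return(NA_real_)
    (max(x) - min(x)) / m
  }
  out <- purrr::map_dfr(seq_len(nrow(sl)), function(i) {
    idx <- sl$start_idx[i]:sl$end_idx[i]
    r660 <- ratio_of(ch660[idx])
    r940 <- ratio_of(ch940[idx])
    flag <- NA_character_
    r <- NA_real_
    if (is.na(r660) || is.na(r940)) {
      flag <- "nonpositive_mean"
    } else if (r940 == 0) {
      flag <- "zero_940_ratio"
    } else {
      r <- r660 / r940
    }
    tibble(cycle = sl$cycle[i], rmps = sl$rmps[i],
           ratio660 = r660, ratio940 = r940, r = r, flag = flag)
  })
  out
}

#' Fit a linear calibration line
#'
#' Least-squares line `y = intercept + slope * x` with the adjusted R-squared
#' as the fit diagnostic, as used for the per-channel cuff-pressure
#' calibration against a reference pressure source.
#'
#' @param x Acquisition values (ADCV).
#' @param y Reference values (e.g. mmHg).
#' @return An object of class `cal_fit` with `intercept`, `slope`,
#'   `adj_r_squared` and the underlying `lm` fit. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_linear_calibration <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3L) abort("need at least 3 calibration points")
  if (sd(x) == 0) abort("`x` has zero variance; cannot fit a line")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  structure(
    list(
      intercept = unname(coef(fit)[1L]),
      slope = unname(coef(fit)[2L]),
      adj_r_squared = suppressWarnings(summary(fit))$adj.r.squared,
      fit = fit
    ),
    class = "cal_fit"
  )
}

#' Fit the SpO2 calibration parabola
#'
#' Least-squares quadratic of reference saturations on mean R values, as in
#' the system's eight-point bench calibration.
#'
#' @param r_means Mean ratio-of-ratios per calibration point.
#' @param spo2_refs Reference saturations (percent).
#' @return A [spo2_calibration()] carrying the adjusted R-squared as
#'   attribute `adj_r_squared`.
#' @export
fit_spo2_parabola <- function(r_means, spo2_refs) {
  if (length(r_means) != length(spo2_refs)) abort("inputs must have equal length")
  if (length(unique(r_means)) < 3L) abort("need at least 3 distinct R values")
  fit <- lm(y ~ x + I(x^2), data = data.frame(x = r_means, y = spo2_refs))
  cc <- unname(coef(fit))
  out <- spo2_calibration(c0 = cc[1L], c1 = cc[2L], c2 = cc[3L])
  attr(out, "adj_r_squared") <- suppressWarnings(summary(fit))$adj.r.squared
  out
}

#' @export
print.cal_fit <- function(x, ...) {
  cat(sprintf("<cal_fit> y = %.5g + %.5g x (adj R^2 = %.5f)\n",
              x$intercept, x$slope, x$adj_r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cal_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = suppressWarnings(summary(x$fit))$coefficients[, "Std. Error"]
  )
}

#' @export
glance.cal_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble(
    adj.r.squared = x$adj_r_squared,
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = length(x$fit$residuals)
  )
}

#' Write calibration coefficients to JSON
#' @param cal An `ecg_calibration`, `spo2_calibration` or `cal_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(cal, path) {
  obj <- unclass(cal)
  obj$fit <- NULL
  obj$type <- class(cal)[1L]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
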