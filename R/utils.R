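#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats fft lm coef rnorm runif quantile sd median approx
#' @importFrom utils head tail
NULL

# round half away from zero (the acquisition convention; R's round() is
# round-half-even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# centered moving average with shrinking windows at the edges
moving_average <- function(x, width) {
  n <- length(x)
  if (n == 0L || width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# central differences scaled by fs; one-sided at the endpoints
derivative <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1L] <- x[2L] - x[1L]
  d[n] <- x[n] - x[n - 1L]
  d * fs
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "cardiocuff_validation_error")
}

check_number <- function(value, field, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_min && value <= min) stop_field(field, sprintf("must be > %g", min))
  if (!strict_min && value < min) stop_field(field, sprintf("must be >= %g", min))
  if (value > max) stop_field(field, sprintf("must be <= %g", max))
  invisible(value)
}
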