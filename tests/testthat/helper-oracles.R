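# Independent brute-force oracles, written as literal loops so they stay
# independent of the implementation paths they check.

# verbatim base-time rule: sort ascending, mean of the middle 50 %
# (trim ceiling(N/4) from each end), accept RR in [0.7, 1.6] x base
oracle_select_rr <- function(rr, lower = 0.7, upper = 1.6) {
  srt <- rr[order(rr)]
  n <- length(srt)
  k <- ceiling(n / 4)
  mid <- c()
  for (i in seq_len(n)) {
    if (i >= k + 1 && i <= n - k) mid <- c(mid, srt[i])
  }
  if (length(mid) == 0) mid <- srt
  base <- sum(mid) / length(mid)
  accepted <- logical(length(rr))
  for (i in seq_along(rr)) {
    accepted[i] <- rr[i] >= lower * base && rr[i] <= upper * base
  }
  list(base = base, accepted = accepted)
}

# O(n^2)-style envelope scan: naive local-maxima peak finder with explicit
# loops, then per-cycle max/min/mean scans
oracle_envelope <- function(pressure, pulse, fs,
                            min_separation = 0.33, min_height = 0.05) {
  n <- length(pulse)
  rng <- max(pulse) - min(pulse)
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (pulse[i] >= pulse[i - 1] && pulse[i] > pulse[i + 1] &&
        (pulse[i] - min(pulse)) >= min_height * rng) {
      if (length(peaks) == 0) {
        peaks <- i
      } else if ((i - peaks[length(peaks)]) >= min_separation * fs) {
        peaks <- c(peaks, i)
      } else if (pulse[i] > pulse[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
      }
    }
  }
  if (length(peaks) < 2) return(NULL)
  amp <- c(); pres <- c()
  for (c_i in seq_len(length(peaks) - 1)) {
    lo <- peaks[c_i]; hi <- peaks[c_i + 1] - 1
    mx <- -Inf; mn <- Inf; s <- 0
    for (j in lo:hi) {
      if (pulse[j] > mx) mx <- pulse[j]
      if (pulse[j] < mn) mn <- pulse[j]
      s <- s + pressure[j]
    }
    amp <- c(amp, mx - mn)
    pres <- c(pres, s / (hi - lo + 1))
  }
  best <- 1
  for (c_i in seq_along(amp)) {
    if (amp[c_i] > amp[best] ||
        (amp[c_i] == amp[best] && pres[c_i] > pres[best])) best <- c_i
  }
  list(mpap = pres[best], amp = amp, pres = pres)
}

# direct shrinking-window convolution for the 5-point smoother
oracle_smooth5 <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - 2); hi <- min(n, i + 2)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# explicit-loop harmonic band statistics on a magnitude vector
# (bins 0-based: magnitude[m + 1] is bin m)
oracle_band_stats <- function(magnitude, hr, fn, n_harmonics = 10,
                              half_width = 0.2) {
  half_away <- function(v) sign(v) * floor(abs(v) + 0.5)
  n_max <- floor((length(magnitude)) / 2)
  ave <- c(); mx <- c()
  for (nh in 1:n_harmonics) {
    lo <- half_away((nh - half_width) * hr / fn)
    hi <- min(half_away((nh + half_width) * hr / fn), n_max)
    s <- 0; m <- -Inf; cnt <- 0
    for (b in lo:hi) {
      v <- magnitude[b + 1]
      s <- s + v
      if (v > m) m <- v
      cnt <- cnt + 1
    }
    ave <- c(ave, s / cnt); mx <- c(mx, m)
  }
  list(ave_f = ave, max_f = mx, ramf = ave / mx, rmmf = mx / mx[1])
}
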