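# Independent oracles and small fixture builders used across the suite.

# Brute-force exact two-sided Wilcoxon signed-rank p: enumerate all 2^n sign
# assignments of the observed |d| midranks directly.
brute_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wp_obs <- sum(r[d > 0])
  wm_obs <- sum(r[d < 0])
  wmin <- min(wp_obs, wm_obs)
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(w_all <= wmin + 1e-9 | w_all >= total - wmin - 1e-9)
}

# Brute-force inclusion oracle: plain interval-overlap logic, written
# independently of the package implementation.
brute_inclusion <- function(events, rec_dur, artifacts, flank = 300) {
  ov <- function(a1, a2, b1, b2) a1 < b2 & a2 > b1
  vapply(seq_len(nrow(events)), function(i) {
    on <- events$onset_s[i]; en <- events$end_s[i]
    el <- events$electrode[i]
    if (on - flank < 0 || en + flank > rec_dur) return(FALSE)
    others <- events[-i, , drop = FALSE]
    others <- others[others$electrode == el, , drop = FALSE]
    bad <- FALSE
    if (nrow(others)) {
      bad <- any(ov(others$onset_s, others$end_s, on - flank, on)) ||
        any(ov(others$onset_s, others$end_s, en, en + flank))
    }
    if (!bad && nrow(artifacts)) {
      art <- artifacts[is.na(artifacts$channel) | artifacts$channel == el, ,
                       drop = FALSE]
      if (nrow(art)) {
        bad <- any(ov(art$start_s, art$end_s, on - flank, on)) ||
          any(ov(art$start_s, art$end_s, en, en + flank))
      }
    }
    !bad
  }, logical(1))
}

# single-channel recording holding a pure sinusoid
sine_recording <- function(freq, amp = 1, fs = 200, dur = 60,
                           label = "E1L") {
  t <- (0:(fs * dur - 1)) / fs
  recording(stats::setNames(list(amp * sin(2 * pi * freq * t)), label),
            fs = fs)
}

# raised-cosine trapezoid with half-depth width d (ramp-midpoint to
# ramp-midpoint), built analytically
trapezoid_signal <- function(n, fs, onset, d, ramp, depth) {
  tt <- (0:(n - 1)) / fs - (onset - ramp / 2)
  plateau <- d - ramp
  y <- numeric(n)
  r1 <- tt >= 0 & tt < ramp
  y[r1] <- -0.5 * (1 - cos(pi * tt[r1] / ramp))
  pl <- tt >= ramp & tt < ramp + plateau
  y[pl] <- -1
  r2 <- tt >= ramp + plateau & tt < 2 * ramp + plateau
  y[r2] <- -0.5 * (1 + cos(pi * (tt[r2] - ramp - plateau) / ramp))
  depth * y
}

# RMS helper
rms <- function(x) sqrt(mean(x^2))
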