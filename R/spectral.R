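#' Hanning window
#'
#' Symmetric Hann weights `w[k] = 0.5 (1 - cos(2 pi k / (n-1)))`,
#' `k = 0 ... n-1` (endpoints zero).
#'
#' @param n window length (>= 2).
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) {
  if (n < 2) stop("n must be >= 2")
  k <- 0:(n - 1)
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' Averaged one-sided power spectrum of a segment
#'
#' The segment is split into windows of `cfg$n_fft` samples at the configured
#' overlap; each window is demeaned (if `cfg$detrend`), weighted
#' (Hann or rectangular), and transformed with the FFT. Per-bin power density
#' is `|X|^2 / (fs * sum(w^2))` with one-sided doubling (except the DC and
#' Nyquist bins), averaged across windows. Frequencies are `k * fs / n_fft`,
#' `k = 0 ... n_fft/2`. Integrating the result over frequency
#' (`sum(power) * fs / n_fft`) recovers the mean square of the (demeaned)
#' signal.
#'
#' @param x numeric segment (µV), length >= `cfg$n_fft`.
#' @param fs sampling rate, Hz.
#' @param cfg a [spectral_config()].
#' @return list with `freq` (Hz), `power` (µV²/Hz), `n_windows`.
#' @export
power_spectrum <- function(x, fs, cfg = spectral_config()) {
  nf <- cfg$n_fft
  if (length(x) < nf)
    stop("segment shorter than n_fft (", length(x), " < ", nf, ")")
  hop <- max(1L, as.integer(round(nf * (1 - cfg$overlap))))
  starts <- seq(1L, length(x) - nf + 1L, by = hop)
  w <- if (cfg$window == "hann") hann_window(nf) else rep(1, nf)
  segs <- vapply(starts, function(s) x[s:(s + nf - 1L)], numeric(nf))
  if (cfg$detrend) segs <- sweep(segs, 2, colMeans(segs))
  X <- stats::mvfft(segs * w)
  nh <- nf %/% 2 + 1L
  P <- rowMeans(abs(X[seq_len(nh), , drop = FALSE])^2) / (fs * sum(w^2))
  if (nh > 2) P[2:(nh - 1)] <- 2 * P[2:(nh - 1)]
  list(freq = (seq_len(nh) - 1) * fs / nf, power = P,
       n_windows = length(starts))
}

#' Mean spectral power per frequency band
#'
#' A spectral bin belongs to band `[lo, hi)` when its center frequency `f`
#' satisfies `lo <= f < hi`; bins in inter-band gaps belong to no band and
#' the DC bin is below every band's lower edge. The band value is the mean of
#' its bins' power densities.
#'
#' @param freq ascending uniform frequency grid, Hz.
#' @param power one-sided power densities on that grid.
#' @param scheme a [band_scheme()].
#' @return data.frame with `band`, `mean_power`, `n_bins` (`mean_power` is
#'   `NA` for a band containing no bins).
#' @export
band_mean_power <- function(freq, power, scheme = band_scheme()) {
  out <- scheme[, "band", drop = FALSE]
  out$mean_power <- NA_real_
  out$n_bins <- 0L
  for (i in seq_len(nrow(scheme))) {
    sel <- freq >= scheme$lo_hz[i] & freq < scheme$hi_hz[i]
    out$n_bins[i] <- sum(sel)
    if (out$n_bins[i] > 0) out$mean_power[i] <- mean(power[sel])
  }
  class(out) <- "data.frame"
  rownames(out) <- NULL
  out
}

.timepoint_offsets <- c(baseline = -300, `0h` = 0, `4h` = 14400,
                        `8h` = 28800, `12h` = 43200)

#' Five-minute analysis epochs around the occlusion marker
#'
#' Per channel: baseline `[m-300, m)`, 0 h `[m, m+300)`, then 4/8/12 h
#' analogous windows offset from the MCAo time `m`. Epochs that overlap an
#' annotated artifact interval are flagged; epochs not covered by the
#' recording are reported as missing, never fabricated.
#'
#' @param rec an [recording()] with `mcao_time` set.
#' @param epoch_length_s epoch duration, s (default 300).
#' @return list with `epochs` (data.frame `channel,label,t_start,t_end,
#'   artifact`) and `missing` (data.frame `channel,label,reason`).
#' @export
extract_timepoint_epochs <- function(rec, epoch_length_s = 300) {
  if (is.null(rec$mcao_time)) stop("recording has no mcao_time marker")
  m <- rec$mcao_time
  dur <- rec_duration(rec)
  ep <- list(); miss <- list()
  for (ch in rec$channel_labels) {
    ai <- artifact_intervals_for(rec, ch)
    for (lab in names(.timepoint_offsets)) {
      t0 <- m + .timepoint_offsets[[lab]]
      t1 <- t0 + epoch_length_s
      if (t0 < 0 || t1 > dur) {
        miss[[length(miss) + 1]] <- data.frame(
          channel = ch, label = lab,
          reason = "outside recording", stringsAsFactors = FALSE)
        next
      }
      has_art <- nrow(ai) > 0 && any(ai$start_s < t1 & ai$end_s > t0)
      ep[[length(ep) + 1]] <- data.frame(
        channel = ch, label = lab, t_start = t0, t_end = t1,
        artifact = has_art, stringsAsFactors = FALSE)
    }
  }
  list(
    epochs = if (length(ep)) do.call(rbind, ep) else
      data.frame(channel = character(0), label = character(0),
                 t_start = numeric(0), t_end = numeric(0),
                 artifact = logical(0)),
    missing = if (length(miss)) do.call(rbind, miss) else
      data.frame(channel = character(0), label = character(0),
                 reason = character(0))
  )
}

#' Band-power table over a set of epochs
#'
#' One record per (channel, epoch, band): mean spectral power density of the
#' band over the epoch, computed with [power_spectrum()] and
#' [band_mean_power()].
#'
#' @param rec an [recording()] object.
#' @param epochs data.frame with `channel`, `label`, `t_start`, `t_end`
#'   (e.g. `extract_timepoint_epochs(rec)$epochs`).
#' @param cfg a [spectral_config()].
#' @param scheme a [band_scheme()].
#' @return data.frame `channel,epoch,band,mean_power,n_windows`.
#' @export
bandpower_table <- function(rec, epochs, cfg = spectral_config(),
                            scheme = band_scheme()) {
  if (!nrow(epochs))
    return(data.frame(channel = character(0), epoch = character(0),
                      band = character(0), mean_power = numeric(0),
                      n_windows = integer(0)))
  rows <- vector("list", nrow(epochs))
  for (i in seq_len(nrow(epochs))) {
    seg <- rec_segment(rec, epochs$channel[i], epochs$t_start[i],
                       epochs$t_end[i])
    ps <- power_spectrum(seg, rec$fs, cfg)
    bp <- band_mean_power(ps$freq, ps$power, scheme)
    rows[[i]] <- data.frame(
      channel = epochs$channel[i], epoch = epochs$label[i],
      band = bp$band, mean_power = bp$mean_power,
      n_windows = ps$n_windows, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
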