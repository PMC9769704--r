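# Zero-phase IIR filtering with explicit odd-reflection edge padding.
# Filters are applied forward and backward (squared magnitude response,
# zero phase), after extending the signal by reflection about its endpoint
# values over roughly three time constants of the slowest pole.

.apply_ba <- function(b, a, x) as.numeric(signal::filter(b, a, x))

# Butterworth designs as second-order sections, built analytically from the
# prototype poles and the bilinear transform. High-order narrow-band
# recursions run far more accurately as a biquad cascade than in the
# expanded direct form (where pole clustering near z = 1 loses precision).
.butter_sos <- function(order, fc, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  proto <- exp(1i * pi * (2 * seq_len(order) - 1 + order) / (2 * order))
  bilin <- function(s) (1 + s) / (1 - s)
  sec_from_pair <- function(p, b, ref_z) {
    a <- c(1, -2 * Re(p), Mod(p)^2)
    ev <- function(cf) sum(cf * ref_z^-(seq_along(cf) - 1))
    list(b = b * Mod(ev(a) / ev(b)), a = a)
  }
  if (type %in% c("low", "high")) {
    w <- tan(pi * fc / fs)
    sp <- if (type == "low") w * proto else w / proto
    zp <- bilin(sp)
    bq <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
    ref <- if (type == "low") 1 + 0i else -1 + 0i
    sos <- list()
    for (k in seq_len(order %/% 2))
      sos[[k]] <- sec_from_pair(zp[k], bq, ref)
    if (order %% 2 == 1) {
      p <- Re(zp[(order + 1) %/% 2])
      a <- c(1, -p)
      b <- if (type == "low") c(1, 1) else c(1, -1)
      ev <- function(cf) sum(cf * ref^-(seq_along(cf) - 1))
      sos[[length(sos) + 1]] <- list(b = b * abs(ev(a) / ev(b)), a = a)
    }
    return(sos)
  }
  w1 <- tan(pi * fc[1] / fs)
  w2 <- tan(pi * fc[2] / fs)
  B <- w2 - w1
  w0sq <- w1 * w2
  f0 <- atan(sqrt(w0sq)) * fs / pi          # center on the warped axis
  ref <- exp(2i * pi * f0 / fs)
  sos <- list()
  for (k in seq_len(order)) {
    disc <- sqrt(as.complex((B * proto[k])^2 - 4 * w0sq))
    for (s_bp in c((B * proto[k] + disc) / 2, (B * proto[k] - disc) / 2)) {
      p <- bilin(s_bp)
      if (Im(p) >= 0)                        # keep one of each conjugate pair
        sos[[length(sos) + 1]] <- sec_from_pair(p, c(1, 0, -1), ref)
    }
  }
  sos
}

.apply_sos <- function(sos, x) {
  for (s in sos) x <- .apply_ba(s$b, s$a, x)
  x
}

.zerophase_sos <- function(sos, x, pad) {
  n <- length(x)
  pad <- min(as.integer(pad), n - 1)
  if (pad > 0) {
    head_ref <- 2 * x[1] - x[(pad + 1):2]
    tail_ref <- 2 * x[n] - x[(n - 1):(n - pad)]
    xp <- c(head_ref, x, tail_ref)
  } else xp <- x
  y <- .apply_sos(sos, xp)
  y <- rev(.apply_sos(sos, rev(y)))
  if (pad > 0) y <- y[(pad + 1):(pad + n)] else y
  y
}

#' Zero-phase (forward-backward) IIR filtering with reflection padding
#'
#' @param b,a filter coefficients (numerator, denominator).
#' @param x numeric signal.
#' @param pad number of samples of odd reflection prepended/appended before
#'   filtering (trimmed afterwards); capped at `length(x) - 1`.
#' @return filtered signal, same length as `x`.
#' @export
zerophase_filter <- function(b, a, x, pad) {
  .zerophase_sos(list(list(b = b, a = a)), x, pad)
}

.pad_for <- function(fc, fs) ceiling(3 * fs / (2 * pi * fc))

#' Notch filter for line noise
#'
#' Zero-phase second-order IIR notch (constrained biquad) at
#' `cfg$notch_hz` with quality factor `cfg$notch_q`. Attenuation at the line
#' frequency exceeds 30 dB while the passband more than 5 Hz away is left
#' essentially untouched.
#'
#' @param rec an [recording()] object.
#' @param cfg a [filter_config()].
#' @return filtered recording.
#' @export
notch_filter <- function(rec, cfg = filter_config()) {
  f0 <- cfg$notch_hz
  if (f0 >= rec$fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * cfg$notch_q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  pad <- ceiling(3 * rec$fs * cfg$notch_q / (pi * f0))
  rec_map(rec, function(x) zerophase_filter(b, a, x, pad))
}

#' High-pass view emulating AC coupling
#'
#' Zero-phase Butterworth high-pass at `cfg$ac_highpass_hz` (default 0.1 Hz):
#' removes DC and infra-slow drift, reproducing what an AC-coupled recorder
#' retains of the signal.
#'
#' @inheritParams notch_filter
#' @return filtered recording.
#' @export
ac_highpass <- function(rec, cfg = filter_config()) {
  fc <- cfg$ac_highpass_hz
  if (fc >= rec$fs / 2) stop("cutoff must be below Nyquist")
  sos <- .butter_sos(cfg$filter_order, fc, rec$fs, "high")
  pad <- .pad_for(fc, rec$fs)
  rec_map(rec, function(x) .zerophase_sos(sos, x, pad))
}

#' Near-DC view for NDCS inspection and detection
#'
#' Zero-phase Butterworth low-pass at `cfg$dc_view_lowpass_hz` (default
#' 0.5 Hz). Spontaneous band activity is rejected; the shape of negative
#' near-DC shifts is preserved.
#'
#' @inheritParams notch_filter
#' @return filtered recording.
#' @export
dc_view <- function(rec, cfg = filter_config()) {
  fc <- cfg$dc_view_lowpass_hz
  if (fc >= rec$fs / 2) stop("cutoff must be below Nyquist")
  sos <- .butter_sos(cfg$filter_order, fc, rec$fs, "low")
  pad <- .pad_for(fc, rec$fs)
  rec_map(rec, function(x) .zerophase_sos(sos, x, pad))
}

# First-order RC high-pass (bilinear transform) used as the AC-coupling
# hardware model, and its exact discrete inverse.
.rc_coeff <- function(fs, fc) {
  t <- tan(pi * fc / fs)
  a1 <- (1 - t) / (1 + t)
  list(a1 = a1, g = (1 + a1) / 2)
}

#' Simulate first-order AC coupling (causal)
#'
#' One-pass first-order RC high-pass at `fc_hz`, the discrete bilinear model
#' of an AC-coupled recorder front end. Used by the simulator to render the
#' recorded view of injected DC shifts; exactly inverted by [dc_restore()].
#'
#' @param x numeric signal (or use [rec_map()] for recordings).
#' @param fs sampling rate, Hz.
#' @param fc_hz coupling corner frequency, Hz (default 0.1).
#' @return coupled signal.
#' @export
ac_couple <- function(x, fs, fc_hz = 0.1) {
  co <- .rc_coeff(fs, fc_hz)
  .apply_ba(c(co$g, -co$g), c(1, -co$a1), x)
}

#' Model-based DC restoration of an AC-coupled recording
#'
#' Inverts the documented first-order AC-coupling model (corner
#' `cfg$ac_highpass_hz`) by leaky-integrator deconvolution, recovering the
#' near-DC waveform whose half-depth width defines the NDCS duration. This is
#' the standard full-band reconstruction used when spreading depolarizations
#' must be quantified from AC-coupled recordings; content genuinely absent
#' from the recording (true DC offsets) is not recovered, transient shifts
#' are.
#'
#' @inheritParams notch_filter
#' @return recording with restored near-DC content.
#' @export
dc_restore <- function(rec, cfg = filter_config()) {
  co <- .rc_coeff(rec$fs, cfg$ac_highpass_hz)
  b <- c(1, -co$a1) / co$g
  a <- c(1, -1)
  rec_map(rec, function(x) {
    y <- .apply_ba(b, a, x)
    y - stats::median(y)
  })
}

#' Band-power envelope ("powered signal") view
#'
#' Zero-phase Butterworth band-pass (corners at the band edges, order
#' `cfg$filter_order`, run as second-order sections), squared, then
#' running-mean smoothed over `smooth_window_s`. The result is a nonnegative
#' instantaneous-power trace in µV² that highlights depressions of
#' spontaneous activity.
#'
#' @param rec an [recording()] object.
#' @param band numeric `c(lo_hz, hi_hz)`.
#' @param smooth_window_s smoothing window, s (default 60).
#' @param cfg a [filter_config()].
#' @return recording whose channels hold the envelope (µV²).
#' @export
power_envelope <- function(rec, band, smooth_window_s = 60,
                           cfg = filter_config()) {
  if (band[1] <= 0 || band[2] >= rec$fs / 2 || band[1] >= band[2])
    stop("band must lie within (0, fs/2)")
  if (smooth_window_s <= 0) stop("smooth_window_s must be positive")
  sos <- .butter_sos(cfg$filter_order, band, rec$fs, "pass")
  pad <- .pad_for(band[1], rec$fs)
  w <- max(1L, as.integer(round(smooth_window_s * rec$fs)))
  rec_map(rec, function(x) {
    y <- .zerophase_sos(sos, x, pad)
    running_mean(y^2, w)
  })
}

#' Centered running mean (O(n), shrinking windows at the edges)
#'
#' @param x numeric vector.
#' @param w window length in samples.
#' @return numeric vector, same length.
#' @export
running_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 1) return(x)
  cs <- c(0, cumsum(x))
  h1 <- (w - 1) %/% 2
  h2 <- w - 1 - h1
  lo <- pmax(seq_len(n) - h1, 1)
  hi <- pmin(seq_len(n) + h2, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
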