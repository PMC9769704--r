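#' Canonical ECoG frequency-band scheme
#'
#' The five-band partition used throughout the pipeline: delta 0.1--4 Hz,
#' theta 4--7 Hz, alpha 8--12 Hz, beta 13--31 Hz, gamma 32--45 Hz. Bands are
#' half-open `[lo, hi)` on the frequency axis; spectral bins falling in the
#' inter-band gaps (7--8, 12--13, 31--32, >45 Hz) belong to no band.
#'
#' @param bands data.frame with columns `band`, `lo_hz`, `hi_hz`. Defaults to
#'   the standard scheme above.
#' @return data.frame of class `band_scheme`, rows in ascending frequency.
#' @export
band_scheme <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      band  = c("delta", "theta", "alpha", "beta", "gamma"),
      lo_hz = c(0.1, 4, 8, 13, 32),
      hi_hz = c(4, 7, 12, 31, 45),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("band", "lo_hz", "hi_hz") %in% names(bands)))
  if (any(bands$lo_hz >= bands$hi_hz)) stop("band edges must satisfy lo < hi")
  o <- order(bands$lo_hz)
  bands <- bands[o, , drop = FALSE]
  if (nrow(bands) > 1 &&
      any(bands$lo_hz[-1] < bands$hi_hz[-nrow(bands)])) {
    stop("bands must be non-overlapping")
  }
  rownames(bands) <- NULL
  class(bands) <- c("band_scheme", "data.frame")
  bands
}

#' Filter configuration
#'
#' Cutoffs and orders for the preprocessing views. `notch_hz` removes line
#' noise; `ac_highpass_hz` is the recorder's AC-coupling corner (also the
#' model inverted by [dc_restore()]); `dc_view_lowpass_hz` is the low-pass
#' used to inspect and detect near-DC shifts.
#'
#' @param notch_hz line frequency, Hz (default 50).
#' @param notch_q quality factor of the IIR notch (default 30).
#' @param ac_highpass_hz AC-coupling corner frequency, Hz (default 0.1).
#' @param dc_view_lowpass_hz low-pass cutoff of the near-DC view, Hz
#'   (default 0.5).
#' @param filter_order Butterworth order for high/low-pass views (default 4).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(notch_hz = 50, notch_q = 30,
                          ac_highpass_hz = 0.1,
                          dc_view_lowpass_hz = 0.5,
                          filter_order = 4) {
  stopifnot(notch_hz > 0, notch_q > 0, ac_highpass_hz > 0,
            dc_view_lowpass_hz > 0, filter_order >= 1)
  structure(list(notch_hz = notch_hz, notch_q = notch_q,
                 ac_highpass_hz = ac_highpass_hz,
                 dc_view_lowpass_hz = dc_view_lowpass_hz,
                 filter_order = filter_order),
            class = "filter_config")
}

#' Spectral estimation configuration
#'
#' Welch-style averaging of 512-point Hanning-windowed DFTs. Each window is
#' demeaned (when `detrend = TRUE`), weighted, transformed; one-sided power
#' densities are averaged across windows.
#'
#' @param n_fft window length in samples; must be a power of two (default 512).
#' @param window `"hann"` or `"rect"`.
#' @param overlap fractional window overlap in `[0, 1)` (default 0).
#' @param detrend remove the per-window mean before windowing (default TRUE).
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(n_fft = 512, window = c("hann", "rect"),
                            overlap = 0, detrend = TRUE) {
  window <- match.arg(window)
  if (n_fft < 2 || bitwAnd(n_fft, n_fft - 1L) != 0)
    stop("n_fft must be a power of two >= 2")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  structure(list(n_fft = as.integer(n_fft), window = window,
                 overlap = overlap, detrend = isTRUE(detrend)),
            class = "spectral_config")
}

#' Electrode strip layout
#'
#' Two five-contact strips, one per hemisphere, contacts 10 mm apart. Index 1
#' is rostral (anterior-cerebral-artery territory), index 5 caudal (middle-
#' cerebral-artery territory).
#'
#' @param spacing_mm inter-electrode distance (default 10).
#' @return data.frame of class `strip_layout` with columns `electrode`,
#'   `hemisphere`, `index`, `position_mm`.
#' @export
strip_layout <- function(spacing_mm = 10) {
  idx <- 1:5
  data <- rbind(
    data.frame(electrode = paste0("E", idx, "R"), hemisphere = "R",
               index = idx, stringsAsFactors = FALSE),
    data.frame(electrode = paste0("E", idx, "L"), hemisphere = "L",
               index = idx, stringsAsFactors = FALSE)
  )
  data$position_mm <- (data$index - 1) * spacing_mm
  class(data) <- c("strip_layout", "data.frame")
  data
}

#' Detector parameters for negative near-DC shifts
#'
#' The detector thresholds the restored, low-passed near-DC view at
#' `depth_threshold_factor` times a robust rolling estimate of the baseline
#' scale (scaled median absolute deviation over `baseline_window_s` blocks),
#' merges candidate excursions separated by less than `merge_gap_s`, measures
#' onset/end at half-depth crossings, and keeps events whose duration lies in
#' `[min_duration_s, max_duration_s]`.
#'
#' @param depth_threshold_factor multiple of the robust baseline scale
#'   (default 6).
#' @param min_duration_s,max_duration_s admissible half-depth durations, s
#'   (defaults 15 and 300).
#' @param baseline_window_s window for the rolling MAD baseline scale, s
#'   (default 600).
#' @param merge_gap_s below-threshold gaps shorter than this are merged, s
#'   (default 30).
#' @param propagation_delay_bounds_s onset-lag window within which events on
#'   adjacent electrodes are chained into one propagating wave (default
#'   `c(60, 420)`).
#' @param detect_fs internal decimated rate for detection, Hz (default 10;
#'   far above the 0.5 Hz content of the near-DC view).
#' @return list of class `detector_params`.
#' @export
detector_params <- function(depth_threshold_factor = 6,
                            min_duration_s = 15, max_duration_s = 300,
                            baseline_window_s = 600, merge_gap_s = 30,
                            propagation_delay_bounds_s = c(60, 420),
                            detect_fs = 10) {
  stopifnot(depth_threshold_factor > 0,
            min_duration_s > 0, max_duration_s > min_duration_s,
            baseline_window_s > 0, merge_gap_s >= 0,
            length(propagation_delay_bounds_s) == 2,
            propagation_delay_bounds_s[1] > 0,
            propagation_delay_bounds_s[1] < propagation_delay_bounds_s[2],
            detect_fs > 0)
  structure(list(depth_threshold_factor = depth_threshold_factor,
                 min_duration_s = min_duration_s,
                 max_duration_s = max_duration_s,
                 baseline_window_s = baseline_window_s,
                 merge_gap_s = merge_gap_s,
                 propagation_delay_bounds_s = propagation_delay_bounds_s,
                 detect_fs = detect_fs),
            class = "detector_params")
}
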