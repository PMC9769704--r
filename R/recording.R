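#' Multichannel ECoG recording
#'
#' In-memory container for a multichannel recording: equal-length per-channel
#' sample vectors in microvolts, a sampling rate, an optional occlusion
#' (MCAo) time marker and optional artifact-interval annotations. Time is in
#' seconds from recording start; all intervals are half-open `[start, end)`.
#'
#' @param data named list of numeric vectors (one per channel, equal length),
#'   in microvolts, or a numeric matrix with one column per channel.
#' @param fs sampling rate, Hz.
#' @param channel_labels channel names; defaults to `names(data)`.
#' @param t0 recording start time, s (default 0).
#' @param mcao_time occlusion marker in seconds from start, or `NULL`.
#' @param artifact_intervals `NULL` or data.frame with columns `channel`
#'   (`NA` for all channels), `start_s`, `end_s`.
#' @return object of class `ecog_recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, t0 = 0,
                      mcao_time = NULL, artifact_intervals = NULL) {
  if (is.matrix(data)) {
    data <- lapply(seq_len(ncol(data)), function(j) data[, j])
    names(data) <- channel_labels %||% paste0("ch", seq_along(data))
  }
  if (is.null(channel_labels)) channel_labels <- names(data)
  if (is.null(channel_labels) || any(!nzchar(channel_labels)))
    stop("channel labels are required")
  names(data) <- channel_labels
  lens <- vapply(data, length, integer(1))
  if (length(unique(lens)) != 1) stop("all channels must have equal length")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive")
  dur <- lens[[1]] / fs
  if (!is.null(mcao_time)) {
    if (mcao_time < 0 || mcao_time > dur)
      stop("mcao_time outside recording [0, ", dur, "]")
  }
  if (!is.null(artifact_intervals)) {
    ai <- artifact_intervals
    stopifnot(all(c("start_s", "end_s") %in% names(ai)))
    if (is.null(ai$channel)) ai$channel <- NA_character_
    if (any(ai$start_s >= ai$end_s)) stop("artifact intervals need start < end")
    if (any(ai$start_s < 0 | ai$end_s > dur))
      stop("artifact intervals outside recording")
    known <- is.na(ai$channel) | ai$channel %in% channel_labels
    if (!all(known)) stop("artifact interval on unknown channel")
    artifact_intervals <- ai[, c("channel", "start_s", "end_s")]
  }
  structure(list(channel_labels = channel_labels, fs = fs, data = data,
                 t0 = t0, mcao_time = mcao_time,
                 artifact_intervals = artifact_intervals),
            class = "ecog_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf("<ecog_recording> %d channel(s), fs = %g Hz, %.1f s\n",
              length(x$data), x$fs, rec_duration(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  if (!is.null(x$mcao_time)) cat(sprintf("  MCAo at %.1f s\n", x$mcao_time))
  n_art <- if (is.null(x$artifact_intervals)) 0 else nrow(x$artifact_intervals)
  if (n_art) cat(sprintf("  %d artifact interval(s)\n", n_art))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `ecog_recording`.
#' @return duration, s.
#' @export
rec_duration <- function(rec) length(rec$data[[1]]) / rec$fs

#' Extract a channel segment over a half-open time interval
#'
#' Sample `i` (1-based) covers time `[(i-1)/fs, i/fs)`; the segment for
#' `[t_start, t_end)` is samples `floor(t_start*fs)+1 .. floor(t_end*fs)`.
#'
#' @param rec an `ecog_recording`.
#' @param channel channel label.
#' @param t_start,t_end interval bounds in seconds (half-open).
#' @return numeric vector of samples.
#' @export
rec_segment <- function(rec, channel, t_start, t_end) {
  if (!channel %in% rec$channel_labels) stop("unknown channel: ", channel)
  if (t_end <= t_start) stop("need t_start < t_end")
  n <- length(rec$data[[channel]])
  i1 <- floor(t_start * rec$fs + 1e-9) + 1
  i2 <- floor(t_end * rec$fs + 1e-9)
  if (i1 < 1 || i2 > n) stop("segment outside recording")
  rec$data[[channel]][i1:i2]
}

#' Apply a function to every channel of a recording
#'
#' @param rec an `ecog_recording`.
#' @param f function mapping a numeric vector to a numeric vector of the same
#'   length.
#' @return a new `ecog_recording` with transformed channels.
#' @export
rec_map <- function(rec, f) {
  out <- rec
  out$data <- lapply(rec$data, f)
  lens <- vapply(out$data, length, integer(1))
  if (any(lens != length(rec$data[[1]])))
    stop("channel transform changed signal length")
  out
}

#' Artifact intervals applying to one channel
#'
#' @param rec an `ecog_recording`.
#' @param channel channel label.
#' @return data.frame with `start_s`, `end_s` (possibly zero rows): the
#'   channel-specific plus global annotations.
#' @export
artifact_intervals_for <- function(rec, channel) {
  ai <- rec$artifact_intervals
  if (is.null(ai) || nrow(ai) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  sel <- is.na(ai$channel) | ai$channel == channel
  ai[sel, c("start_s", "end_s"), drop = FALSE]
}
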