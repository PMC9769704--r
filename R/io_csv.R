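#' Read a recording from CSV or EDF
#'
#' CSV layout: a `time` column in seconds plus one column per channel in
#' microvolts. The sampling rate is inferred from the time column, which must
#' be uniform to within 1e-6 relative. EDF files are read with the built-in
#' reader ([read_edf()]).
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param mcao_time optional occlusion marker, s (not stored in either format).
#' @return an [recording()] object with channel order preserved.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           mcao_time = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") {
    rec <- read_edf(path)
    rec$mcao_time <- mcao_time
    return(rec)
  }
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("CSV must have a 'time' column")
  tt <- df$time
  if (length(tt) < 2) stop("CSV must have at least 2 samples")
  dt <- diff(tt)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("non-uniform time grid in CSV (must be uniform within 1e-6 relative)")
  fs <- 1 / dt[1]
  ch <- setdiff(names(df), "time")
  if (!length(ch)) stop("CSV has no channel columns")
  recording(as.list(df[ch]), fs = fs, channel_labels = ch,
            mcao_time = mcao_time)
}

#' Write a recording to CSV
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- length(rec$data[[1]])
  df <- data.frame(time = (seq_len(n) - 1) / rec$fs)
  for (ch in rec$channel_labels) df[[ch]] <- rec$data[[ch]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.event_cols <- c("electrode", "onset_s", "end_s", "duration_s", "depth_uv",
                 "group", "included")

#' Write / read spreading-depolarization event tables
#'
#' Column order is fixed
#' (`electrode,onset_s,end_s,duration_s,depth_uv,group,included`); rows are
#' written sorted by onset then electrode, and re-reading reproduces the
#' fields exactly.
#'
#' @param events data.frame of events (see [detect_ndcs()]).
#' @param path file path.
#' @return `path` (write) or the events data.frame (read).
#' @export
write_events_csv <- function(events, path) {
  ev <- as.data.frame(events)
  for (col in .event_cols) if (is.null(ev[[col]])) {
    ev[[col]] <- if (col == "included") NA else
      if (col %in% c("electrode")) NA_character_ else NA_real_
  }
  ev <- ev[.event_cols]
  if (nrow(ev)) ev <- ev[order(ev$onset_s, ev$electrode), , drop = FALSE]
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(identical(names(ev), .event_cols))
  ev$included <- as.logical(ev$included)
  ev
}

#' Write / read band-power tables
#'
#' Fixed header `channel,epoch,band,mean_power,n_windows` (plus an `animal`
#' column when present).
#'
#' @param records band-power data.frame (see [bandpower_table()]).
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_bandpower_csv <- function(records, path) {
  cols <- c("channel", "epoch", "band", "mean_power", "n_windows")
  if ("animal" %in% names(records)) cols <- c("animal", cols)
  utils::write.csv(as.data.frame(records)[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bandpower_csv
#' @export
read_bandpower_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an incidence histogram as CSV
#'
#' Long format `electrode,bin_start_h,count`, with `bin_start_h` hours after
#' the occlusion marker.
#'
#' @param hist an [incidence_histogram()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(hist, path) {
  m <- hist$counts
  df <- data.frame(
    electrode = rep(rownames(m), each = ncol(m)),
    bin_start_h = rep((seq_len(ncol(m)) - 1) * hist$bin_width_s / 3600,
                      times = nrow(m)),
    count = as.vector(t(m))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
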