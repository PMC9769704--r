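#' Detect negative near-DC shifts (NDCS)
#'
#' Per channel the detector (1) restores near-DC content from the AC-coupled
#' recording ([dc_restore()]), (2) takes the low-pass near-DC view
#' ([dc_view()]) and decimates it to `params$detect_fs`, (3) estimates a
#' rolling robust baseline scale (scaled MAD over
#' `params$baseline_window_s` blocks), (4) marks maximal intervals where the
#' signal falls below `-factor * scale`, merging intervals separated by less
#' than `params$merge_gap_s`, and (5) measures onset and end at the
#' outermost half-depth crossings of the excursion (linearly interpolated),
#' the depth being the magnitude of its minimum. Events with duration outside
#' `[min_duration_s, max_duration_s]` are discarded.
#'
#' @param rec an [recording()] object (>= 20 min for baseline estimation).
#' @param params a [detector_params()].
#' @param cfg a [filter_config()].
#' @return data.frame of events, sorted by onset:
#'   `electrode,onset_s,end_s,duration_s,depth_uv,group,included`
#'   (`group`/`included` are `NA` until [link_propagation()] /
#'   [apply_inclusion_filter()] run).
#' @export
detect_ndcs <- function(rec, params = detector_params(),
                        cfg = filter_config()) {
  if (rec_duration(rec) < 1200)
    stop("recording must be at least 20 min long for baseline estimation")
  dec <- max(1L, as.integer(round(rec$fs / params$detect_fs)))
  fsd <- rec$fs / dec
  rows <- list()
  for (ch in rec$channel_labels) {
    # restore + low-pass one channel at a time: full-length intermediates
    # for a 24-h channel are ~140 MB each, so whole-montage copies are
    # avoided deliberately
    one <- recording(rec$data[ch], fs = rec$fs)
    vf <- dc_view(dc_restore(one, cfg), cfg)$data[[1]]
    v <- vf[seq(1L, length(vf), by = dec)]
    rm(one, vf)
    thr <- params$depth_threshold_factor *
      .block_scale(v, max(1L, as.integer(round(params$baseline_window_s * fsd))))
    runs <- .threshold_runs(v < -thr, as.integer(round(params$merge_gap_s * fsd)))
    for (r in seq_len(nrow(runs))) {
      ev <- .half_depth_event(v, runs$start[r], runs$end[r], fsd)
      if (is.null(ev)) next
      if (ev$duration < params$min_duration_s ||
          ev$duration > params$max_duration_s) next
      rows[[length(rows) + 1]] <- data.frame(
        electrode = ch, onset_s = ev$onset, end_s = ev$end,
        duration_s = ev$duration, depth_uv = ev$depth,
        group = NA_integer_, included = NA, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(electrode = character(0), onset_s = numeric(0),
               end_s = numeric(0), duration_s = numeric(0),
               depth_uv = numeric(0), group = integer(0),
               included = logical(0))
  out <- out[order(out$onset_s, out$electrode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# robust per-block scale (MAD scaled to Gaussian sigma), step-interpolated
.block_scale <- function(v, block_len) {
  n <- length(v)
  n_blocks <- max(1L, n %/% block_len)
  scale <- numeric(n)
  for (b in seq_len(n_blocks)) {
    i1 <- (b - 1L) * block_len + 1L
    i2 <- if (b == n_blocks) n else b * block_len
    scale[i1:i2] <- stats::mad(v[i1:i2])
  }
  scale
}

# maximal TRUE runs, with gaps shorter than merge_gap samples merged
.threshold_runs <- function(below, merge_gap) {
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  if (!length(s)) return(data.frame(start = integer(0), end = integer(0)))
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] - me - 1L < merge_gap) me <- e[i]
    else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

# half-depth onset/end bracketing the outermost below-half samples of one
# (possibly merged) candidate run
.half_depth_event <- function(v, i1, i2, fsd) {
  seg <- v[i1:i2]
  depth <- -min(seg)
  if (depth <= 0) return(NULL)
  half <- -depth / 2
  below <- which(seg < half)
  a <- i1 - 1L + below[1L]
  b <- i1 - 1L + below[length(below)]
  while (a > 1L && v[a - 1L] < half) a <- a - 1L
  n <- length(v)
  while (b < n && v[b + 1L] < half) b <- b + 1L
  # linear interpolation of the crossing instants
  t_on <- if (a > 1L) (a - 1L) - (half - v[a]) / (v[a - 1L] - v[a]) else a - 1L
  t_off <- if (b < n) (b - 1L) + (half - v[b]) / (v[b + 1L] - v[b]) else b - 1L
  onset <- t_on / fsd
  end <- t_off / fsd
  list(onset = onset, end = end, duration = end - onset, depth = depth)
}

#' Link propagating events across adjacent electrodes
#'
#' Two events on adjacent electrodes of the same strip whose onset lag lies
#' within `params$propagation_delay_bounds_s` are chained into one
#' propagation group (transitive closure); every other event forms a
#' singleton group. Grouping never deduplicates per-electrode counts.
#'
#' @param events events data.frame (sorted by onset).
#' @param layout a [strip_layout()].
#' @param params a [detector_params()].
#' @return `events` with the `group` column filled in.
#' @export
link_propagation <- function(events, layout = strip_layout(),
                             params = detector_params()) {
  n <- nrow(events)
  if (!n) { events$group <- integer(0); return(events) }
  li <- match(events$electrode, layout$electrode)
  if (anyNA(li)) stop("event electrode missing from layout")
  hemi <- layout$hemisphere[li]
  idx <- layout$index[li]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  lo <- params$propagation_delay_bounds_s[1]
  hi <- params$propagation_delay_bounds_s[2]
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dt <- abs(events$onset_s[j] - events$onset_s[i])
      if (dt > hi) next
      if (dt < lo) next
      if (hemi[i] != hemi[j]) next
      if (abs(idx[i] - idx[j]) != 1L) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  events$group <- match(roots, unique(roots))
  events
}

#' Flag events usable for spectral phase analysis
#'
#' An event is included iff its 5-min flanks `[onset-300, onset)` and
#' `(end, end+300]` on the same electrode lie within the recording and
#' contain neither another event's interval nor an artifact interval.
#'
#' @param events events data.frame.
#' @param rec the [recording()] the events were detected on.
#' @param flank_s flank length, s (default 300).
#' @return `events` with the `included` column filled in.
#' @export
apply_inclusion_filter <- function(events, rec, flank_s = 300) {
  n <- nrow(events)
  if (!n) { events$included <- logical(0); return(events) }
  dur <- rec_duration(rec)
  inc <- logical(n)
  for (i in seq_len(n)) {
    pre <- c(events$onset_s[i] - flank_s, events$onset_s[i])
    post <- c(events$end_s[i], events$end_s[i] + flank_s)
    if (pre[1] < 0 || post[2] > dur) { inc[i] <- FALSE; next }
    same <- which(events$electrode == events$electrode[i])
    same <- setdiff(same, i)
    clash <- FALSE
    for (j in same) {
      if (events$onset_s[j] < pre[2] && events$end_s[j] > pre[1]) clash <- TRUE
      if (events$onset_s[j] < post[2] && events$end_s[j] > post[1]) clash <- TRUE
    }
    if (!clash) {
      ai <- artifact_intervals_for(rec, events$electrode[i])
      if (nrow(ai)) {
        if (any(ai$start_s < pre[2] & ai$end_s > pre[1])) clash <- TRUE
        if (any(ai$start_s < post[2] & ai$end_s > post[1])) clash <- TRUE
      }
    }
    inc[i] <- !clash
  }
  events$included <- inc
  events
}

#' Segment an included event into preSD / SD / postSD windows
#'
#' @param event one row of an events data.frame (must be included).
#' @param flank_s flank length, s (default 300).
#' @return data.frame with `phase,t_start,t_end` rows preSD `[onset-300,
#'   onset)`, SD `[onset, end)`, postSD `[end, end+300)`.
#' @export
segment_sd_phases <- function(event, flank_s = 300) {
  if (!isTRUE(event$included))
    stop("only included events are phase-analyzed")
  data.frame(
    phase = c("preSD", "SD", "postSD"),
    t_start = c(event$onset_s - flank_s, event$onset_s, event$end_s),
    t_end = c(event$onset_s, event$end_s, event$end_s + flank_s),
    stringsAsFactors = FALSE)
}

#' Per-electrode SD incidence in 3-hour bins
#'
#' All detected events (included or not) with onset in
#' `[mcao_time, mcao_time + n_bins * bin_width_s)` are binned per electrode.
#' Events before the occlusion are dropped with a warning.
#'
#' @param events events data.frame.
#' @param mcao_time occlusion marker, s.
#' @param electrodes electrode set for the rows (default: those present).
#' @param bin_width_s bin width, s (default 10800 = 3 h).
#' @param n_bins number of bins (default 8).
#' @return list of class `incidence_histogram` with `counts` (matrix
#'   electrode x bin), `bin_width_s`, `n_bins`, `origin`, `n_dropped`.
#' @export
incidence_histogram <- function(events, mcao_time, electrodes = NULL,
                                bin_width_s = 10800, n_bins = 8) {
  if (is.null(mcao_time)) stop("mcao_time must be set")
  if (is.null(electrodes)) electrodes <- sort(unique(events$electrode))
  counts <- matrix(0L, nrow = length(electrodes), ncol = n_bins,
                   dimnames = list(electrodes, NULL))
  pre <- events$onset_s < mcao_time
  if (any(pre))
    warning(sum(pre), " event(s) before mcao_time dropped")
  ev <- events[!pre & events$onset_s < mcao_time + n_bins * bin_width_s, ,
               drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    b <- floor((ev$onset_s[i] - mcao_time) / bin_width_s) + 1L
    e <- ev$electrode[i]
    if (e %in% electrodes) counts[e, b] <- counts[e, b] + 1L
  }
  structure(list(counts = counts, bin_width_s = bin_width_s,
                 n_bins = n_bins, origin = mcao_time,
                 n_dropped = sum(pre)),
            class = "incidence_histogram")
}

#' @export
print.incidence_histogram <- function(x, ...) {
  cat(sprintf("<incidence_histogram> %d electrode(s), %d bins of %g h\n",
              nrow(x$counts), x$n_bins, x$bin_width_s / 3600))
  print(x$counts)
  invisible(x)
}

#' Band power for every phase of every included event
#'
#' For each included event, the preSD/SD/postSD segments are decomposed with
#' [power_spectrum()] and [band_mean_power()]. SD segments shorter than the
#' configured FFT length use the largest power of two that fits. Each event
#' is tagged with its 3-h time lapse after the occlusion.
#'
#' @param rec an [recording()] with `mcao_time` set.
#' @param events events data.frame with the `included` flag filled in.
#' @param cfg a [spectral_config()].
#' @param scheme a [band_scheme()].
#' @param lapse_width_s lapse width, s (default 10800).
#' @return data.frame
#'   `electrode,event,lapse,phase,band,mean_power,n_windows`.
#' @export
sd_phase_bandpower <- function(rec, events, cfg = spectral_config(),
                               scheme = band_scheme(),
                               lapse_width_s = 10800) {
  if (is.null(rec$mcao_time)) stop("recording has no mcao_time marker")
  ev <- events[isTRUE_vec(events$included), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ev))) {
    ph <- segment_sd_phases(ev[i, ])
    lapse <- floor((ev$onset_s[i] - rec$mcao_time) / lapse_width_s) + 1L
    for (p in seq_len(nrow(ph))) {
      seg <- rec_segment(rec, ev$electrode[i], ph$t_start[p], ph$t_end[p])
      cfg_p <- cfg
      if (length(seg) < cfg$n_fft)
        cfg_p$n_fft <- 2L^max(1L, floor(log2(length(seg))))
      ps <- power_spectrum(seg, rec$fs, cfg_p)
      bp <- band_mean_power(ps$freq, ps$power, scheme)
      rows[[length(rows) + 1]] <- data.frame(
        electrode = ev$electrode[i], event = i, lapse = lapse,
        phase = ph$phase[p], band = bp$band, mean_power = bp$mean_power,
        n_windows = ps$n_windows, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(electrode = character(0), event = integer(0),
               lapse = integer(0), phase = character(0), band = character(0),
               mean_power = numeric(0), n_windows = integer(0))
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Mean band power per (electrode, lapse, phase, band)
#'
#' Averages [sd_phase_bandpower()] records over the events of each 3-h
#' lapse, yielding the paired per-lapse values used by
#' [compare_sd_phases()].
#'
#' @param phase_bp output of [sd_phase_bandpower()].
#' @return aggregated data.frame `electrode,lapse,phase,band,mean_power,
#'   n_events`.
#' @export
lapse_means <- function(phase_bp) {
  if (!nrow(phase_bp))
    return(data.frame(electrode = character(0), lapse = integer(0),
                      phase = character(0), band = character(0),
                      mean_power = numeric(0), n_events = integer(0)))
  agg <- stats::aggregate(mean_power ~ electrode + lapse + phase + band,
                          data = phase_bp, FUN = mean)
  cnt <- stats::aggregate(mean_power ~ electrode + lapse + phase + band,
                          data = phase_bp, FUN = length)
  agg$n_events <- cnt$mean_power
  agg[order(agg$electrode, agg$lapse, agg$phase, agg$band), ]
}
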