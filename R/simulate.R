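#' Simulation configuration
#'
#' Defaults emulate the study conditions: 24-h recordings (1 h before the
#' occlusion marker) at 200 Hz, a ten-contact bilateral montage, band-limited
#' Gaussian background per channel, step-like per-band power depression after
#' occlusion following the core/penumbra/remote presets, and SD events whose
#' near-DC shifts have durations drawn from Normal(51.3, 14.1^2) s truncated
#' to [20, 120] s.
#'
#' Depression multipliers act on amplitude; band power therefore scales with
#' the square of the multiplier.
#'
#' @param duration_s recording length, s (default 86400).
#' @param fs sampling rate, Hz (default 200).
#' @param seed RNG seed for this recording.
#' @param channels channel labels (default the full E1R--E5R, E1L--E5L
#'   montage).
#' @param band_rms named per-band background RMS amplitudes, µV.
#' @param mcao_time occlusion marker, s (default 3600; `NULL` for none).
#' @param depression `"fig_patterns"` (the core/penumbra/remote presets),
#'   `"none"`, or a data.frame `electrode,band,time_s,multiplier` (amplitude
#'   multiplier in force from `time_s` on).
#' @param sd_schedule `NULL` or data.frame `electrode,onset_s` with optional
#'   `duration_s` (`NA` = draw from the duration distribution) and
#'   `propagate` (logical; propagating events spawn delayed copies on
#'   adjacent electrodes).
#' @param sd_params list: `duration_mean` (51.3), `duration_sd` (14.1),
#'   `duration_range` (c(20, 120)), `depth_uv` (1000), `ramp_s` (10),
#'   `depression_factor` (0.1, amplitude during the SD),
#'   `recovery` ("full" or "impaired"), `recovery_factor` (0.4, amplitude
#'   held through the 300-s postSD window in impaired mode),
#'   `post_window_s` (300), `post_ramp_s` (60), `speed_mm_min` (3),
#'   `min_gap_s` (360).
#' @param artifact_schedule `NULL` or data.frame `channel,start_s,end_s`
#'   with optional `amplitude_uv` (default 200): broadband bursts.
#' @param ac_coupling_hz corner of the simulated first-order AC coupling
#'   applied to injected DC shifts (default 0.1; `NA` to inject uncoupled).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(duration_s = 86400, fs = 200, seed = 1,
                       channels = strip_layout()$electrode,
                       band_rms = c(delta = 20, theta = 10, alpha = 8,
                                    beta = 5, gamma = 3),
                       mcao_time = 3600,
                       depression = "fig_patterns",
                       sd_schedule = NULL,
                       sd_params = list(),
                       artifact_schedule = NULL,
                       ac_coupling_hz = 0.1) {
  sp <- utils::modifyList(
    list(duration_mean = 51.3, duration_sd = 14.1,
         duration_range = c(20, 120), depth_uv = 1000, ramp_s = 10,
         depression_factor = 0.1, recovery = "full", recovery_factor = 0.4,
         post_window_s = 300, post_ramp_s = 60, speed_mm_min = 3,
         min_gap_s = 360),
    sd_params)
  stopifnot(duration_s > 0, fs > 0,
            sp$min_gap_s > sp$duration_range[2],
            sp$duration_range[1] < sp$duration_range[2])
  if (!is.null(mcao_time) && (mcao_time < 0 || mcao_time > duration_s))
    stop("mcao_time outside recording")
  if (!is.null(sd_schedule)) {
    stopifnot(all(c("electrode", "onset_s") %in% names(sd_schedule)))
    if (is.null(sd_schedule$duration_s)) sd_schedule$duration_s <- NA_real_
    if (is.null(sd_schedule$propagate)) sd_schedule$propagate <- FALSE
    if (any(!sd_schedule$electrode %in% channels))
      stop("sd_schedule on unknown channel")
    if (any(sd_schedule$onset_s < 0 | sd_schedule$onset_s > duration_s))
      stop("sd_schedule onset outside recording")
    for (el in unique(sd_schedule$electrode)) {
      on <- sort(sd_schedule$onset_s[sd_schedule$electrode == el])
      if (length(on) > 1 && min(diff(on)) < sp$min_gap_s)
        stop("SD schedule conflict on ", el, ": onsets closer than min_gap_s")
    }
  }
  structure(list(duration_s = duration_s, fs = fs, seed = seed,
                 channels = channels, band_rms = band_rms,
                 mcao_time = mcao_time, depression = depression,
                 sd_schedule = sd_schedule, sd_params = sp,
                 artifact_schedule = artifact_schedule,
                 ac_coupling_hz = ac_coupling_hz),
            class = "sim_config")
}

# The per-(electrode, band) depression presets: amplitude multipliers in
# force from time_s on. Core electrodes (E4L, E5L) lose all bands at the
# occlusion; penumbral electrodes (E2L, E3L) lose fast bands immediately and
# delta 8 h later; the remote/ACA electrode (E1L) loses all but gamma 8 h
# later; the right hemisphere is unaffected.
.depression_presets <- function(mcao_time) {
  bands <- c("delta", "theta", "alpha", "beta", "gamma")
  rows <- list()
  add <- function(el, bd, t, m)
    rows[[length(rows) + 1]] <<- data.frame(
      electrode = el, band = bd, time_s = t, multiplier = m,
      stringsAsFactors = FALSE)
  for (el in c("E4L", "E5L")) for (bd in bands) add(el, bd, mcao_time, 0.05)
  for (el in c("E2L", "E3L")) {
    for (bd in c("theta", "alpha", "beta", "gamma"))
      add(el, bd, mcao_time, 0.3)
    add(el, "delta", mcao_time + 8 * 3600, 0.3)
  }
  for (bd in c("delta", "theta", "alpha", "beta"))
    add("E1L", bd, mcao_time + 8 * 3600, 0.3)
  do.call(rbind, rows)
}

# band-limited Gaussian noise components from one white-noise FFT;
# empirical RMS normalization, per-band depression applied in time domain
.channel_background <- function(N, fs, band_rms, scheme, dep_rows) {
  W <- stats::fft(stats::rnorm(N))
  x <- numeric(N)
  for (i in seq_len(nrow(scheme))) {
    bd <- scheme$band[i]
    rms <- band_rms[[bd]]
    if (is.null(rms) || rms <= 0) next
    k1 <- max(1L, ceiling(scheme$lo_hz[i] * N / fs))
    k2 <- min(N %/% 2, floor(scheme$hi_hz[i] * N / fs))
    if (k2 < k1) next
    Wb <- complex(real = numeric(N))
    idx <- (k1:k2) + 1L
    Wb[idx] <- W[idx]
    Wb[N - (k1:k2) + 1L] <- W[N - (k1:k2) + 1L]
    xb <- Re(stats::fft(Wb, inverse = TRUE)) / N
    xb <- xb * (rms / stats::sd(xb))
    if (!is.null(dep_rows)) {
      dr <- dep_rows[dep_rows$band == bd, , drop = FALSE]
      if (nrow(dr)) {
        dr <- dr[order(dr$time_s), , drop = FALSE]
        for (j in seq_len(nrow(dr))) {
          i1 <- max(1L, floor(dr$time_s[j] * fs) + 1L)
          i2 <- if (j < nrow(dr)) floor(dr$time_s[j + 1] * fs) else N
          if (i2 >= i1) xb[i1:i2] <- xb[i1:i2] * dr$multiplier[j]
        }
      }
    }
    x <- x + xb
  }
  x
}

# raised-cosine-edged trapezoidal negative DC shift; half-depth width = d
.rc_trapezoid <- function(N, fs, onset, d, ramp, depth) {
  t0 <- onset - ramp / 2
  plateau <- d - ramp
  i1 <- max(1L, floor(t0 * fs) + 1L)
  i2 <- min(N, ceiling((t0 + 2 * ramp + plateau) * fs))
  tt <- ((i1:i2) - 1) / fs - t0
  y <- numeric(length(tt))
  r1 <- tt >= 0 & tt < ramp
  y[r1] <- -0.5 * (1 - cos(pi * tt[r1] / ramp))
  pl <- tt >= ramp & tt < ramp + plateau
  y[pl] <- -1
  r2 <- tt >= ramp + plateau & tt < 2 * ramp + plateau
  y[r2] <- -0.5 * (1 + cos(pi * (tt[r2] - ramp - plateau) / ramp))
  list(i1 = i1, i2 = i2, y = depth * y)
}

#' Simulate a ground-truthed multichannel recording
#'
#' Background: per channel, the five band-limited Gaussian noise components
#' are synthesized in the frequency domain at the configured RMS amplitudes
#' and modulated by the depression schedule (amplitude multipliers, i.e.
#' power scales with the square). Each SD contributes (a) a raised-cosine
#' trapezoidal negative DC shift whose half-depth width equals the event
#' duration, and (b) a
#' broadband amplitude suppression of the background during the event, with
#' full or impaired recovery over the postSD window. Propagating events
#' spawn delayed copies on adjacent electrodes (10 mm at
#' `speed_mm_min`). Artifacts are high-amplitude broadband bursts, also
#' annotated on the returned recording. The complete electrode signal
#' (background, DC shifts, artifacts) is finally passed through the
#' first-order AC-coupling model (`ac_coupling_hz`), as a real AC recorder
#' front end would do; [dc_restore()] inverts exactly this model.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an [recording()]), `truth` (data.frame
#'   `electrode,onset_s,end_s,duration_s,depth_uv,propagating,group`) and
#'   `config`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  N <- as.integer(round(cfg$duration_s * cfg$fs))
  fs <- cfg$fs
  scheme <- band_scheme()
  sp <- cfg$sd_params

  dep <- NULL
  if (identical(cfg$depression, "fig_patterns") && !is.null(cfg$mcao_time)) {
    dep <- .depression_presets(cfg$mcao_time)
  } else if (is.data.frame(cfg$depression)) {
    dep <- cfg$depression
  }

  truth <- .resolve_events(cfg)

  data <- vector("list", length(cfg$channels))
  names(data) <- cfg$channels
  for (ch in cfg$channels) {
    dep_ch <- if (is.null(dep)) NULL else dep[dep$electrode == ch, ,
                                              drop = FALSE]
    x <- .channel_background(N, fs, cfg$band_rms, scheme, dep_ch)
    ev <- truth[truth$electrode == ch, , drop = FALSE]
    if (nrow(ev)) {
      # broadband suppression of spontaneous activity around each SD
      for (i in seq_len(nrow(ev))) {
        i1 <- max(1L, floor(ev$onset_s[i] * fs) + 1L)
        i2 <- min(N, ceiling(ev$end_s[i] * fs))
        x[i1:i2] <- x[i1:i2] * sp$depression_factor
        if (sp$recovery == "impaired") {
          j1 <- min(N, i2 + 1L)
          j2 <- min(N, i2 + as.integer(sp$post_window_s * fs))
          if (j2 >= j1) x[j1:j2] <- x[j1:j2] * sp$recovery_factor
          k1 <- min(N, j2 + 1L)
          k2 <- min(N, j2 + as.integer(sp$post_ramp_s * fs))
          if (k2 >= k1)
            x[k1:k2] <- x[k1:k2] *
              seq(sp$recovery_factor, 1, length.out = k2 - k1 + 1L)
        }
      }
      for (i in seq_len(nrow(ev))) {
        tz <- .rc_trapezoid(N, fs, ev$onset_s[i], ev$duration_s[i],
                            sp$ramp_s, ev$depth_uv[i])
        x[tz$i1:tz$i2] <- x[tz$i1:tz$i2] + tz$y
      }
    }
    if (!is.null(cfg$artifact_schedule)) {
      as_ <- cfg$artifact_schedule
      sel <- is.na(as_$channel) | as_$channel == ch
      for (i in which(sel)) {
        i1 <- max(1L, floor(as_$start_s[i] * fs) + 1L)
        i2 <- min(N, ceiling(as_$end_s[i] * fs))
        amp <- if (is.null(as_$amplitude_uv)) 200 else as_$amplitude_uv[i]
        x[i1:i2] <- x[i1:i2] + stats::rnorm(i2 - i1 + 1L, 0, amp)
      }
    }
    # the recorder front end AC-couples the whole electrode signal
    if (!is.na(cfg$ac_coupling_hz))
      x <- ac_couple(x, fs, cfg$ac_coupling_hz)
    data[[ch]] <- x
    rm(x)
    gc(FALSE)   # full-length temporaries; keep the footprint flat
  }
  art <- NULL
  if (!is.null(cfg$artifact_schedule)) {
    art <- cfg$artifact_schedule
    if (is.null(art$channel)) art$channel <- NA_character_
    art <- art[, c("channel", "start_s", "end_s")]
  }
  rec <- recording(data, fs = fs, channel_labels = cfg$channels,
                   mcao_time = cfg$mcao_time, artifact_intervals = art)
  list(recording = rec, truth = truth, config = cfg)
}

# ground-truth event table: draw missing durations, spawn propagated copies
.resolve_events <- function(cfg) {
  empty <- data.frame(electrode = character(0), onset_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      depth_uv = numeric(0), propagating = logical(0),
                      group = integer(0))
  sched <- cfg$sd_schedule
  if (is.null(sched) || !nrow(sched)) return(empty)
  sp <- cfg$sd_params
  sched <- sched[order(sched$onset_s, sched$electrode), , drop = FALSE]
  dur <- sched$duration_s
  need <- is.na(dur)
  dur[need] <- rtruncnorm(sum(need), sp$duration_mean, sp$duration_sd,
                          sp$duration_range[1], sp$duration_range[2])
  layout <- strip_layout()
  delay <- layout$position_mm[2] / sp$speed_mm_min * 60  # s per 10 mm hop
  rows <- list()
  for (i in seq_len(nrow(sched))) {
    rows[[length(rows) + 1]] <- data.frame(
      electrode = sched$electrode[i], onset_s = sched$onset_s[i],
      end_s = sched$onset_s[i] + dur[i], duration_s = dur[i],
      depth_uv = sp$depth_uv, propagating = isTRUE(sched$propagate[i]),
      group = i, stringsAsFactors = FALSE)
    if (isTRUE(sched$propagate[i])) {
      li <- match(sched$electrode[i], layout$electrode)
      nb <- layout$electrode[layout$hemisphere == layout$hemisphere[li] &
                               abs(layout$index - layout$index[li]) == 1]
      nb <- nb[nb %in% cfg$channels]
      for (el in nb) {
        on <- sched$onset_s[i] + delay
        if (on + dur[i] + sp$ramp_s >= cfg$duration_s) next
        rows[[length(rows) + 1]] <- data.frame(
          electrode = el, onset_s = on, end_s = on + dur[i],
          duration_s = dur[i], depth_uv = sp$depth_uv, propagating = TRUE,
          group = i, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s, out$electrode), , drop = FALSE]
  if (any(out$end_s + sp$ramp_s > cfg$duration_s))
    stop("SD event extends past end of recording")
  rownames(out) <- NULL
  out
}

#' Truncated-normal deviates (rejection sampling)
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lo,hi truncation bounds.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Evenly spread event onsets with jitter and a minimum gap
#'
#' Deterministic given the RNG state: `n` onsets in `[t0, t1]`, base spacing
#' `(t1 - t0) / n`, each jittered uniformly by up to 40\% of the slack above
#' `min_gap`.
#'
#' @param n number of onsets.
#' @param t0,t1 window bounds, s.
#' @param min_gap minimum inter-onset gap, s.
#' @return sorted numeric vector of onsets.
#' @export
place_onsets <- function(n, t0, t1, min_gap) {
  span <- t1 - t0
  if (n < 1) return(numeric(0))
  spacing <- span / n
  if (spacing < min_gap) stop("cannot place ", n, " onsets with gap ", min_gap)
  base <- t0 + spacing * (seq_len(n) - 0.5)
  jit <- stats::runif(n, -1, 1) * 0.4 * (spacing - min_gap)
  sort(base + jit)
}

#' Per-animal configurations for a cohort
#'
#' Identical schedule templates with independent seeds `base_seed + i` and
#' per-animal background band RMS amplitudes jittered by ±10\%. Useful for
#' simulating a cohort one animal at a time when recordings are large.
#'
#' @param cfg a [sim_config()] template.
#' @param n_animals cohort size (default 6).
#' @param base_seed base RNG seed (default `cfg$seed`).
#' @return list of [sim_config()] objects.
#' @export
cohort_configs <- function(cfg, n_animals = 6, base_seed = cfg$seed) {
  stopifnot(n_animals >= 1)
  set.seed(base_seed)
  jit <- matrix(stats::runif(n_animals * length(cfg$band_rms), 0.9, 1.1),
                nrow = n_animals)
  lapply(seq_len(n_animals), function(i) {
    ci <- cfg
    ci$seed <- base_seed + i
    ci$band_rms <- cfg$band_rms * jit[i, ]
    ci
  })
}

#' Simulate a cohort of animals
#'
#' Independent recordings per [cohort_configs()].
#'
#' @inheritParams cohort_configs
#' @return list of `simulate_recording()` results, one per animal.
#' @export
make_cohort <- function(cfg, n_animals = 6, base_seed = cfg$seed) {
  lapply(cohort_configs(cfg, n_animals, base_seed), simulate_recording)
}
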