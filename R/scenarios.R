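# Pre-built simulation scenarios mirroring the study conditions. These are
# the configurations that the acceptance checks and the analysis scripts
# run; they are ordinary sim_config objects and can be modified like any
# other.

#' Scenario: duration-recovery run
#'
#' 200 isolated SDs on one electrode, onsets 8 min apart, durations drawn
#' from the truncated Normal(51.3, 14.1^2) distribution on [20, 120] s. Used
#' to check that the detector's half-depth duration estimate recovers the
#' generating duration scale.
#'
#' @param seed RNG seed.
#' @param n_events number of events (default 200).
#' @param gap_s onset spacing, s (default 480).
#' @param electrode channel to use (default "E2L").
#' @param fs sampling rate (default 200).
#' @return a [sim_config()].
#' @export
scenario_duration_recovery <- function(seed = 42, n_events = 200,
                                       gap_s = 480, electrode = "E2L",
                                       fs = 200) {
  lead <- 1800
  duration <- lead + n_events * gap_s + 900
  sched <- data.frame(electrode = electrode,
                      onset_s = lead + gap_s * (seq_len(n_events) - 1))
  sim_config(duration_s = duration, fs = fs, seed = seed,
             channels = electrode, mcao_time = 900,
             depression = "none", sd_schedule = sched,
             sd_params = list(min_gap_s = min(gap_s, 480)))
}

#' Scenario: reference per-electrode SD totals
#'
#' A 24-h left-strip recording (occlusion at 1 h) in which the generator
#' injects, per electrode, the reference SD totals the pipeline is
#' validated against -- E1L 99, E2L 163, E3L 120, E4L 12, E5L 26 -- with
#' at least 6-min inter-onset gaps,
#' onsets confined to the 23 h after occlusion, and the depression presets
#' active (isoelectric background on the core electrodes E4L/E5L).
#'
#' @param seed RNG seed.
#' @param counts named per-electrode event counts.
#' @param fs sampling rate (default 200).
#' @param min_gap_s minimum inter-onset gap, s (default 360).
#' @return a [sim_config()].
#' @export
scenario_reported_counts <- function(seed = 42,
                                     counts = c(E1L = 99, E2L = 163,
                                                E3L = 120, E4L = 12,
                                                E5L = 26),
                                     fs = 200, min_gap_s = 360) {
  duration <- 86400
  m <- 3600
  set.seed(seed)
  sched <- do.call(rbind, lapply(names(counts), function(el) {
    data.frame(electrode = el,
               onset_s = place_onsets(counts[[el]], m + min_gap_s,
                                      duration - 900, min_gap_s))
  }))
  sim_config(duration_s = duration, fs = fs, seed = seed,
             channels = names(counts), mcao_time = m,
             depression = "fig_patterns", sd_schedule = sched,
             sd_params = list(min_gap_s = min_gap_s))
}

#' Scenario: postSD recovery modes
#'
#' A 25-h single-electrode recording with two SDs in each of the eight 3-h
#' lapses after occlusion, widely spaced so every event passes the inclusion
#' filter. `mode = "full"` restores the background immediately after each SD
#' (the unaffected-zone pattern); `mode = "impaired"` holds it at the
#' recovery amplitude factor through the postSD window (the penumbral
#' pattern).
#'
#' @param seed RNG seed.
#' @param mode `"full"` or `"impaired"`.
#' @param electrode channel label (default "E2L").
#' @param sd_per_lapse events per 3-h lapse (default 2).
#' @param fs sampling rate (default 200).
#' @return a [sim_config()].
#' @export
scenario_recovery <- function(seed = 42, mode = c("full", "impaired"),
                              electrode = "E2L", sd_per_lapse = 2,
                              fs = 200) {
  mode <- match.arg(mode)
  m <- 3600
  duration <- m + 8 * 10800 + 600
  set.seed(seed)
  sched <- do.call(rbind, lapply(1:8, function(l) {
    t0 <- m + (l - 1) * 10800
    data.frame(electrode = electrode,
               onset_s = place_onsets(sd_per_lapse, t0 + 900,
                                      t0 + 10800 - 900, 1800))
  }))
  sim_config(duration_s = duration, fs = fs, seed = seed,
             channels = electrode, mcao_time = m, depression = "none",
             sd_schedule = sched,
             sd_params = list(recovery = mode, min_gap_s = 1500))
}

#' Scenario: default 24-h study recording
#'
#' Full ten-channel montage over 24 h with the depression presets, a modest
#' well-separated SD schedule on the left strip (including one propagating
#' wave) and a few annotated artifact bursts. The default end-to-end
#' demonstration and detector-validation condition.
#'
#' @param seed RNG seed.
#' @param fs sampling rate (default 200).
#' @return a [sim_config()].
#' @export
scenario_study_default <- function(seed = 42, fs = 200) {
  m <- 3600
  sched <- rbind(
    data.frame(electrode = "E5L", onset_s = m + c(1800, 7200)),
    data.frame(electrode = "E4L", onset_s = m + c(3600, 10800)),
    data.frame(electrode = "E3L", onset_s = m + c(21600, 28800, 36000)),
    data.frame(electrode = "E2L", onset_s = m + c(23400, 43200, 50400)),
    data.frame(electrode = "E1L", onset_s = m + c(46800, 61200))
  )
  sched$propagate <- FALSE
  # one wave propagating E3L -> adjacent electrodes
  sched$propagate[sched$electrode == "E3L" &
                    sched$onset_s == m + 28800] <- TRUE
  art <- data.frame(channel = c(NA, "E1L", "E2R"),
                    start_s = c(20000, 50000, 70000),
                    end_s = c(20010, 50008, 70005),
                    amplitude_uv = 200)
  sim_config(duration_s = 86400, fs = fs, seed = seed,
             mcao_time = m, depression = "fig_patterns",
             sd_schedule = sched, artifact_schedule = art)
}

#' Match detected events to ground truth
#'
#' A detected event matches a truth event when they share an electrode and
#' their intervals overlap. Recall is the fraction of truth events matched;
#' false positives are detected events matching no truth event.
#'
#' @param detected,truth event data.frames with `electrode,onset_s,end_s`.
#' @return list with `recall`, `n_truth`, `n_detected`, `false_positives`,
#'   `matched` (logical per truth row), `duration_error_s` (detected minus
#'   truth duration for uniquely matched pairs).
#' @export
match_events <- function(detected, truth) {
  matched <- logical(nrow(truth))
  det_hit <- logical(nrow(detected))
  dur_err <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- which(detected$electrode == truth$electrode[i] &
                    detected$onset_s < truth$end_s[i] &
                    detected$end_s > truth$onset_s[i])
    if (length(cand)) {
      matched[i] <- TRUE
      det_hit[cand] <- TRUE
      j <- cand[which.min(abs(detected$onset_s[cand] - truth$onset_s[i]))]
      dur_err[i] <- detected$duration_s[j] - truth$duration_s[i]
    }
  }
  list(recall = if (nrow(truth)) mean(matched) else NA_real_,
       n_truth = nrow(truth), n_detected = nrow(detected),
       false_positives = sum(!det_hit), matched = matched,
       duration_error_s = dur_err)
}
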