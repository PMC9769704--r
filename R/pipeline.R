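#' Run the full analysis pipeline
#'
#' Orchestrates, in order: (1) preprocessing, (2) SD detection, propagation
#' linking and incidence binning, (3) timepoint band powers (design A,
#' across animals when a cohort is simulated), (4) inclusion filtering and
#' SD-phase band powers with per-lapse means, (5) design-A and design-B
#' statistics. All tables are written as CSV into `out_dir`, together with
#' the echoed configuration and a run log (config hash, seed, package
#' version). Deterministic given the configuration.
#'
#' The configuration is a YAML file path or an equivalent nested list with
#' either a `simulate:` block (fields of [sim_config()], plus optional
#' `scenario:` naming one of the `scenario_*` builders and `n_animals:`) or
#' an `input:` block (`files:`, `format:`, `mcao_time:`). Detector,
#' spectral and statistical defaults can be overridden under `detector:`,
#' `spectral:` and `stats:`.
#'
#' @param config YAML path or list.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the main tables
#'   (`events`, `incidence`, `bandpower_timepoints`, `stats_timepoints`,
#'   `sdphase_lapse_means`, `stats_sdphases`).
#' @export
run_full <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  } else cfg_path <- NULL
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  echo_path <- file.path(out_dir, "config.yml")
  yaml::write_yaml(config, echo_path)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
    writeLines(line, log_con)
    message(line)
  }
  logmsg("config hash: %s", unname(tools::md5sum(echo_path)))
  logmsg("ecogsd version: %s", as.character(utils::packageVersion("ecogsd")))

  fc <- do.call(filter_config, config$filter %||% list())
  sc <- do.call(spectral_config, config$spectral %||% list())
  dp <- do.call(detector_params, config$detector %||% list())
  scheme <- band_scheme()

  # ---- stage 0: acquire recordings ---------------------------------------
  runs <- .acquire_recordings(config, logmsg)

  # ---- stage 1-2: preprocess + detect ------------------------------------
  all_events <- list(); all_bp <- list(); all_phase <- list()
  layout <- strip_layout()
  for (i in seq_along(runs)) {
    rec <- runs[[i]]$recording
    logmsg("[detect] animal %d: %d channel(s), %.1f h", i,
           length(rec$data), rec_duration(rec) / 3600)
    rec_clean <- notch_filter(rec, fc)
    runs[[i]]$recording <- rec_clean   # raw copy no longer needed
    rm(rec)
    ev <- detect_ndcs(rec_clean, dp, fc)
    ev <- tryCatch(link_propagation(ev, layout, dp), error = function(e) ev)
    ev <- apply_inclusion_filter(ev, rec_clean)
    logmsg("[detect] animal %d: %d event(s), %d included", i, nrow(ev),
           sum(ev$included))
    runs[[i]]$clean <- rec_clean
    runs[[i]]$events <- ev
    ev$animal <- i
    all_events[[i]] <- ev
  }
  events <- do.call(rbind, all_events)
  write_events_csv(events, file.path(out_dir, "events.csv"))

  first <- runs[[1]]
  if (!is.null(first$recording$mcao_time)) {
    hist <- incidence_histogram(runs[[1]]$events,
                                first$recording$mcao_time,
                                electrodes = first$recording$channel_labels)
    write_incidence_csv(hist, file.path(out_dir, "incidence.csv"))
  } else {
    hist <- NULL
    logmsg("[incidence] skipped: no mcao_time")
  }

  # ---- stage 3: timepoint band powers ------------------------------------
  for (i in seq_along(runs)) {
    rec <- runs[[i]]$clean
    if (is.null(rec$mcao_time))
      stop("stage bandpower: recording ", i, " is missing the field ",
           "'mcao_time'")
    eps <- extract_timepoint_epochs(rec)
    if (nrow(eps$missing))
      logmsg("[bandpower] animal %d: %d epoch(s) missing", i,
             nrow(eps$missing))
    bp <- bandpower_table(rec, eps$epochs, sc, scheme)
    bp$animal <- i
    all_bp[[i]] <- bp
  }
  bp_all <- do.call(rbind, all_bp)
  write_bandpower_csv(bp_all, file.path(out_dir, "bandpower_timepoints.csv"))

  # ---- stage 4: SD-phase band powers -------------------------------------
  for (i in seq_along(runs)) {
    ph <- sd_phase_bandpower(runs[[i]]$clean, runs[[i]]$events, sc, scheme)
    if (nrow(ph)) { ph$animal <- i; all_phase[[length(all_phase) + 1]] <- ph }
  }
  phase_all <- if (length(all_phase)) do.call(rbind, all_phase) else NULL
  lm <- if (!is.null(phase_all)) lapse_means(phase_all) else NULL
  if (!is.null(lm))
    utils::write.csv(lm, file.path(out_dir, "sdphase_bandpower.csv"),
                     row.names = FALSE)

  # ---- stage 5: statistics -----------------------------------------------
  st_cfg <- config$stats %||% list()
  alpha <- st_cfg$alpha %||% 0.05
  stats_tp <- NULL
  if (length(runs) >= 2) {
    stats_tp <- compare_timepoints(bp_all, alpha = alpha,
                                   adjust = st_cfg$adjust %||% "none")
    write_stats_csv(stats_tp, file.path(out_dir, "stats_timepoints.csv"))
  } else {
    logmsg("[stats] design A skipped: cohort of 1 cannot be paired across animals")
  }
  stats_ph <- NULL
  if (!is.null(lm) && nrow(lm)) {
    stats_ph <- compare_sd_phases(lm, alpha = alpha)
    write_stats_csv(stats_ph, file.path(out_dir, "stats_sdphases.csv"))
  } else {
    logmsg("[stats] design B skipped: no included events")
  }
  logmsg("done")
  invisible(list(events = events, incidence = hist,
                 bandpower_timepoints = bp_all, stats_timepoints = stats_tp,
                 sdphase_lapse_means = lm, stats_sdphases = stats_ph))
}

.acquire_recordings <- function(config, logmsg) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_animals <- sim$n_animals %||% 1
    sim$n_animals <- NULL
    if (!is.null(sim$scenario)) {
      builder <- switch(sim$scenario,
        study_default = scenario_study_default,
        reported_counts = scenario_reported_counts,
        duration_recovery = scenario_duration_recovery,
        recovery = scenario_recovery,
        stop("unknown scenario: ", sim$scenario))
      args <- sim[setdiff(names(sim), "scenario")]
      cfg <- do.call(builder, args)
    } else {
      if (!is.null(sim$band_rms)) sim$band_rms <- unlist(sim$band_rms)
      if (!is.null(sim$channels)) sim$channels <- unlist(sim$channels)
      if (!is.null(sim$sd_schedule))
        sim$sd_schedule <- as.data.frame(lapply(sim$sd_schedule, unlist))
      if (!is.null(sim$artifact_schedule))
        sim$artifact_schedule <-
          as.data.frame(lapply(sim$artifact_schedule, unlist))
      cfg <- do.call(sim_config, sim)
    }
    logmsg("[simulate] seed %d, %d animal(s)", cfg$seed, n_animals)
    if (n_animals > 1) return(make_cohort(cfg, n_animals))
    return(list(simulate_recording(cfg)))
  }
  if (!is.null(config$input)) {
    inp <- config$input
    if (is.null(inp$mcao_time))
      stop("config is missing the field 'mcao_time' for input recordings")
    recs <- lapply(inp$files, function(f) {
      logmsg("[read] %s", f)
      list(recording = read_recording(f, inp$format %||% "auto",
                                      mcao_time = inp$mcao_time))
    })
    return(recs)
  }
  stop("config needs a 'simulate' or an 'input' block")
}
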