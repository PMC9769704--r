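#!/usr/bin/env Rscript
# Step 1: generate the demonstration cohort.
#
# Six synthetic animals (the smallest paired cohort in which the exact
# signed-rank test can reach p <= 0.05), 13.25-h recordings — 1 h before
# arterial occlusion and 12.25 h after, the shortest span exposing every
# timepoint epoch up to 12 h — over the full ten-electrode bilateral
# montage at 100 Hz (demo scale; all analysis bands sit below the 50 Hz
# Nyquist). The left strip carries the core/penumbra/remote depression
# presets, a well-separated SD schedule with one propagating wave and
# impaired postSD recovery, plus annotated artifact bursts; the right
# strip is unaffected. Animals are written one at a time under
# results/analysis/animals/ so memory stays flat.

suppressMessages(library(ecogsd))

out_dir <- "results/analysis"
dir.create(file.path(out_dir, "animals"), recursive = TRUE,
           showWarnings = FALSE)

m <- 3600
sched <- rbind(
  data.frame(electrode = "E5L", onset_s = m + c(1800, 5400)),
  data.frame(electrode = "E4L", onset_s = m + c(3600, 9000)),
  data.frame(electrode = "E3L", onset_s = m + c(12600, 21600, 30600)),
  data.frame(electrode = "E2L", onset_s = m + c(14400, 25200, 36000)),
  data.frame(electrode = "E1L", onset_s = m + c(28800, 41400))
)
sched$propagate <- sched$electrode == "E3L" & sched$onset_s == m + 21600

cfg <- sim_config(
  duration_s = 47700, fs = 100, seed = 2024, mcao_time = m,
  depression = "fig_patterns", sd_schedule = sched,
  artifact_schedule = data.frame(channel = c(NA, "E1L"),
                                 start_s = c(20000, 40000),
                                 end_s = c(20010, 40008),
                                 amplitude_uv = 200),
  sd_params = list(recovery = "impaired")
)

truth <- list()
for (i in seq_along(configs <- cohort_configs(cfg, n_animals = 6))) {
  sim <- simulate_recording(configs[[i]])
  saveRDS(sim, file.path(out_dir, "animals", sprintf("animal_%d.rds", i)))
  sim$truth$animal <- i
  truth[[i]] <- sim$truth
  message(sprintf("animal %d: %.1f h x %d channels, %d SDs injected", i,
                  configs[[i]]$duration_s / 3600,
                  length(configs[[i]]$channels), nrow(sim$truth)))
  rm(sim); gc(FALSE)
}
utils::write.csv(do.call(rbind, truth),
                 file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
message("wrote ", out_dir, "/animals/*.rds and ground_truth.csv")
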