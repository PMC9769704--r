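test_that("identical config and seed reproduce the signal bit for bit", {
  cfg <- sim_config(duration_s = 1500, fs = 200, seed = 51,
                    channels = c("E2L", "E3L"), mcao_time = 600,
                    sd_schedule = data.frame(electrode = "E2L",
                                             onset_s = 900))
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth, b$truth)
})

test_that("ground truth lists exactly the scheduled events", {
  cfg <- sim_config(duration_s = 1500, fs = 200, seed = 52,
                    channels = c("E1L", "E2L"), mcao_time = 600,
                    depression = "none",
                    sd_schedule = data.frame(electrode = "E2L",
                                             onset_s = 900))
  sim <- simulate_recording(cfg)
  expect_identical(nrow(sim$truth), 1L)
  expect_identical(sim$truth$electrode, "E2L")
  expect_true(sim$truth$duration_s >= 20 && sim$truth$duration_s <= 120)
})

test_that("propagating events spawn delayed copies on adjacent electrodes", {
  cfg <- sim_config(duration_s = 2400, fs = 100,
                    channels = c("E1L", "E2L", "E3L"), seed = 53,
                    mcao_time = 600, depression = "none",
                    sd_schedule = data.frame(electrode = "E2L",
                                             onset_s = 900,
                                             duration_s = 50,
                                             propagate = TRUE))
  sim <- simulate_recording(cfg)
  expect_identical(nrow(sim$truth), 3L)
  expect_setequal(sim$truth$electrode, c("E1L", "E2L", "E3L"))
  lag <- sim$truth$onset_s[sim$truth$electrode == "E1L"] -
    sim$truth$onset_s[sim$truth$electrode == "E2L"]
  expect_equal(lag, 10 / 3 * 60)  # 10 mm at 3 mm/min
  expect_identical(length(unique(sim$truth$group)), 1L)
})

test_that("conflicting schedules are rejected", {
  expect_error(
    sim_config(duration_s = 3000, fs = 100, channels = "E2L", seed = 1,
               mcao_time = 600,
               sd_schedule = data.frame(electrode = "E2L",
                                        onset_s = c(900, 1100))),
    "min_gap")
})

test_that("background band powers are stationary and match configured RMS", {
  cfg <- sim_config(duration_s = 600, fs = 200, seed = 54, channels = "E1R",
                    mcao_time = NULL, depression = "none",
                    ac_coupling_hz = NA)
  sim <- simulate_recording(cfg)
  rec <- sim$recording
  eps <- data.frame(channel = "E1R", label = c("a", "b"),
                    t_start = c(0, 300), t_end = c(300, 600))
  bp <- bandpower_table(rec, eps)
  a <- bp[bp$epoch == "a", ]
  b <- bp[bp$epoch == "b", ]
  expect_true(all(abs(b$mean_power / a$mean_power - 1) < 0.1))
  # integrated band power (density x bins x df) matches configured RMS^2
  # over the frequency range the half-open bin grid actually covers
  scheme <- band_scheme()
  ps <- power_spectrum(rec$data[[1]], 200)
  bm <- band_mean_power(ps$freq, ps$power, scheme)
  df <- 200 / 512
  covered <- vapply(seq_len(nrow(scheme)), function(i) {
    f <- ps$freq[ps$freq >= scheme$lo_hz[i] & ps$freq < scheme$hi_hz[i]]
    min(scheme$hi_hz[i], max(f) + df / 2) -
      max(scheme$lo_hz[i], min(f) - df / 2)
  }, numeric(1))
  integ <- bm$mean_power * bm$n_bins * df
  expected <- cfg$band_rms[bm$band]^2 * covered /
    (scheme$hi_hz - scheme$lo_hz)
  expect_true(all(abs(integ / expected - 1) < 0.1))
})

test_that("core-preset depression scales 0h power by the squared multiplier", {
  cfg <- sim_config(duration_s = 4200, fs = 200, seed = 55,
                    channels = "E5L", mcao_time = 3600,
                    depression = "fig_patterns")
  sim <- simulate_recording(cfg)
  eps <- data.frame(channel = "E5L", label = c("baseline", "0h"),
                    t_start = c(3300, 3600), t_end = c(3600, 3900))
  bp <- bandpower_table(sim$recording, eps)
  ratio <- bp$mean_power[bp$epoch == "0h"] /
    bp$mean_power[bp$epoch == "baseline"]
  expect_true(all(ratio > 0.0025 * 0.7 & ratio < 0.0025 * 1.4))
})

test_that("cohorts are reproducible, distinct across animals", {
  cfg <- sim_config(duration_s = 300, fs = 200, seed = 56, channels = "E1R",
                    mcao_time = NULL, depression = "none")
  co1 <- make_cohort(cfg, n_animals = 6, base_seed = 56)
  co2 <- make_cohort(cfg, n_animals = 6, base_seed = 56)
  expect_identical(length(co1), 6L)
  for (i in 1:6)
    expect_identical(co1[[i]]$recording$data, co2[[i]]$recording$data)
  sigs <- vapply(co1, function(s) s$recording$data[[1]][1], numeric(1))
  expect_identical(length(unique(sigs)), 6L)
  single <- make_cohort(cfg, n_animals = 1)
  expect_identical(length(single), 1L)
})
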