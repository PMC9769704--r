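# Detection fixtures are built through the generator (or by hand with the
# same AC-coupling model) at reduced durations; the full study-scale checks
# live in test-acceptance.R.

test_that("background noise alone yields no events", {
  cfg <- sim_config(duration_s = 1500, fs = 200, seed = 41,
                    channels = "E2L", mcao_time = 600, depression = "none")
  sim <- simulate_recording(cfg)
  ev <- detect_ndcs(sim$recording)
  expect_identical(nrow(ev), 0L)
})

test_that("an injected 50-s trapezoid is detected with its half-depth width", {
  cfg <- sim_config(duration_s = 1800, fs = 200, seed = 42,
                    channels = "E2L", mcao_time = 600, depression = "none",
                    sd_schedule = data.frame(electrode = "E2L",
                                             onset_s = 900,
                                             duration_s = 50))
  sim <- simulate_recording(cfg)
  ev <- detect_ndcs(sim$recording)
  expect_identical(nrow(ev), 1L)
  expect_gt(ev$duration_s, 45)
  expect_lt(ev$duration_s, 55)
  expect_lt(abs(ev$onset_s - 900), 2)
  expect_gt(ev$depth_uv, 900)
})

test_that("deflections separated by less than the merge gap fuse", {
  fs <- 200
  n <- 1800 * fs
  set.seed(43)
  bg <- as.numeric(signal::filter(signal::butter(2, c(0.001, 0.4)),
                                  rnorm(n))) * 10
  x <- bg +
    trapezoid_signal(n, fs, onset = 900, d = 40, ramp = 10, depth = 1000) +
    trapezoid_signal(n, fs, onset = 960, d = 40, ramp = 10, depth = 1000)
  rec <- recording(list(E2L = ac_couple(x, fs, 0.1)), fs = fs)
  ev <- detect_ndcs(rec)
  expect_identical(nrow(ev), 1L)          # 20-s gap < 30-s merge rule
  expect_gt(ev$duration_s, 90)
})

test_that("duration estimates track the generating durations closely", {
  cfg <- scenario_duration_recovery(seed = 44, n_events = 15, gap_s = 480)
  sim <- simulate_recording(cfg)
  ev <- detect_ndcs(sim$recording)
  m <- match_events(ev, sim$truth)
  expect_equal(m$recall, 1)
  expect_identical(m$false_positives, 0L)
  expect_lt(mean(abs(m$duration_error_s)), 1)
})

test_that("propagation linking chains adjacent-electrode onsets", {
  ev <- data.frame(
    electrode = c("E3L", "E2L", "E2L", "E3R", "E5L"),
    onset_s = c(1000, 1180, 5000, 1000, 1185),
    end_s = c(1050, 1230, 5050, 1050, 1235),
    duration_s = 50, depth_uv = 1000, group = NA_integer_, included = NA)
  ev <- ev[order(ev$onset_s), ]
  out <- link_propagation(ev)
  g <- function(el, on) out$group[out$electrode == el & out$onset_s == on]
  expect_identical(g("E3L", 1000), g("E2L", 1180))   # 180 s in [60, 420]
  expect_false(g("E3L", 1000) == g("E2L", 5000))     # too late
  expect_false(g("E3L", 1000) == g("E3R", 1000))     # other strip
  expect_false(g("E3L", 1000) == g("E5L", 1185))     # not adjacent

  near <- data.frame(electrode = c("E3L", "E2L"), onset_s = c(1000, 1030),
                     end_s = c(1050, 1080), duration_s = 50,
                     depth_uv = 1000, group = NA_integer_, included = NA)
  out2 <- link_propagation(near)
  expect_identical(length(unique(out2$group)), 2L)   # 30 s below lower bound
})

test_that("inclusion filter enforces clean 5-min flanks", {
  rec <- recording(list(E1L = numeric(7200), E2L = numeric(7200)), fs = 1,
                   artifact_intervals = data.frame(channel = "E2L",
                                                   start_s = 3750,
                                                   end_s = 3760))
  iso <- data.frame(electrode = "E1L", onset_s = 3000, end_s = 3050,
                    duration_s = 50, depth_uv = 1000,
                    group = NA_integer_, included = NA)
  expect_true(apply_inclusion_filter(iso, rec)$included)

  pair <- rbind(iso, data.frame(electrode = "E1L", onset_s = 3250,
                                end_s = 3300, duration_s = 50,
                                depth_uv = 1000, group = NA_integer_,
                                included = NA))
  expect_identical(apply_inclusion_filter(pair, rec)$included,
                   c(FALSE, FALSE))      # mutual flank violation at 200 s

  art <- data.frame(electrode = "E2L", onset_s = 3600, end_s = 3650,
                    duration_s = 50, depth_uv = 1000, group = NA_integer_,
                    included = NA)
  expect_false(apply_inclusion_filter(art, rec)$included)  # artifact at +100 s

  edge <- data.frame(electrode = "E1L", onset_s = 100, end_s = 150,
                     duration_s = 50, depth_uv = 1000, group = NA_integer_,
                     included = NA)
  expect_false(apply_inclusion_filter(edge, rec)$included) # preSD off-record
})

test_that("inclusion filter matches a brute-force interval oracle", {
  rec_dur <- 86400
  for (s in 1:5) {
    set.seed(100 + s)
    n <- sample(5:50, 1)
    on <- sort(runif(n, 0, rec_dur - 100))
    ev <- data.frame(
      electrode = sample(c("E1L", "E2L", "E3L"), n, replace = TRUE),
      onset_s = on, end_s = on + runif(n, 20, 120))
    ev$duration_s <- ev$end_s - ev$onset_s
    ev$depth_uv <- 1000; ev$group <- NA_integer_; ev$included <- NA
    arts <- data.frame(channel = sample(c(NA, "E1L", "E2L"), 4,
                                        replace = TRUE),
                       start_s = runif(4, 0, rec_dur - 50))
    arts$end_s <- arts$start_s + runif(4, 1, 30)
    rec <- recording(list(E1L = numeric(864), E2L = numeric(864),
                          E3L = numeric(864)), fs = 0.01,
                     artifact_intervals = arts)
    got <- apply_inclusion_filter(ev, rec)$included
    want <- brute_inclusion(ev, rec_dur, arts)
    expect_identical(got, want)
  }
})

test_that("phase segmentation covers preSD / SD / postSD and refuses excluded events", {
  ev <- data.frame(electrode = "E1L", onset_s = 5000, end_s = 5050,
                   duration_s = 50, depth_uv = 1000, group = NA_integer_,
                   included = TRUE)
  ph <- segment_sd_phases(ev)
  expect_equal(ph$t_start, c(4700, 5000, 5050))
  expect_equal(ph$t_end, c(5000, 5050, 5350))
  ev$included <- FALSE
  expect_error(segment_sd_phases(ev), "included")
})

test_that("incidence histogram bins per electrode with half-open 3-h bins", {
  m <- 3600
  ev <- data.frame(electrode = "E1L",
                   onset_s = m + c(3600, 4 * 3600, 23.5 * 3600),
                   end_s = m + c(3650, 4 * 3600 + 50, 23.5 * 3600 + 50))
  h <- incidence_histogram(ev, m)
  expect_equal(as.vector(h$counts["E1L", ]), c(1, 1, 0, 0, 0, 0, 0, 1))
  expect_identical(sum(h$counts), 3L)

  h0 <- incidence_histogram(ev[0, ], m, electrodes = "E1L")
  expect_true(all(h0$counts == 0))

  bnd <- data.frame(electrode = "E1L", onset_s = m + 3 * 3600,
                    end_s = m + 3 * 3600 + 40)
  expect_equal(which(incidence_histogram(bnd, m)$counts["E1L", ] == 1), 2L)

  pre <- data.frame(electrode = "E1L", onset_s = m - 100, end_s = m - 60)
  expect_warning(hp <- incidence_histogram(rbind(ev, pre), m), "dropped")
  expect_identical(sum(hp$counts), 3L)
})
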