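test_that("most extreme sign patterns give the exact attainable p-values", {
  t6 <- wilcoxon_signed_rank(11:16, 1:6)
  expect_equal(t6$p_two_sided, 0.03125)
  expect_identical(t6$method, "wilcoxon_exact")
  expect_identical(t6$n_effective, 6L)
  t8 <- wilcoxon_signed_rank(11:18, 1:8)
  expect_equal(t8$p_two_sided, 0.0078125)
  expect_equal(t8$statistic, 0)
})

test_that("exact p matches brute-force sign-flip enumeration, with ties", {
  for (s in 1:20) {
    set.seed(200 + s)
    n <- sample(4:12, 1)
    x <- round(rnorm(n), if (s %% 2) 1 else 3)  # coarse rounding forces ties
    y <- round(rnorm(n), if (s %% 2) 1 else 3)
    if (all(x == y)) next
    got <- wilcoxon_signed_rank(x, y, mode = "exact")
    expect_equal(got$p_two_sided, brute_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("exact p agrees with stats::wilcox.test when ties are absent", {
  set.seed(210)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(wilcoxon_signed_rank(x, y)$p_two_sided,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
})

test_that("degenerate Wilcoxon inputs raise errors", {
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "equal length")
})

test_that("normal approximation tracks the exact test at moderate n", {
  set.seed(211)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  pe <- wilcoxon_signed_rank(x, y, mode = "exact")$p_two_sided
  pa <- wilcoxon_signed_rank(x, y, mode = "approx")$p_two_sided
  expect_identical(wilcoxon_signed_rank(x, y)$method,
                   "wilcoxon_normal_approx")
  expect_lt(abs(pa - pe), 0.01)
})

test_that("exact Wilcoxon keeps the type-I error at its attainable level", {
  # n = 6: the only attainable two-sided level <= 0.05 is 0.03125
  set.seed(212)
  n_rep <- 2000
  rej <- 0L
  for (i in seq_len(n_rep)) {
    x <- rnorm(6); y <- rnorm(6)
    if (wilcoxon_signed_rank(x, y)$p_two_sided <= 0.05) rej <- rej + 1L
  }
  # the binomial 99% CI around the observed rate must cover the attainable
  # level 1/32, and the rate must stay below the nominal 0.05 + MC margin
  phat <- rej / n_rep
  se <- sqrt(phat * (1 - phat) / n_rep)
  expect_lte(abs(phat - 1 / 32), 2.576 * se)
  expect_lte(phat, 0.07)
})

test_that("Wilcoxon p is invariant under order-preserving affine rescaling", {
  set.seed(213)
  x <- rnorm(9); y <- rnorm(9)
  p1 <- wilcoxon_signed_rank(x, y)$p_two_sided
  p2 <- wilcoxon_signed_rank(10 + 3 * x, 10 + 3 * y)$p_two_sided
  expect_equal(p1, p2)
})

test_that("Friedman Q matches the worked monotone case and base R", {
  mono <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  mono <- mono + seq_len(8) / 100  # distinct rows, same within-row order
  f <- friedman_rank_test(mono)
  expect_equal(f$statistic, 16)
  expect_equal(f$p_two_sided, stats::pchisq(16, 2, lower.tail = FALSE))

  alleq <- matrix(5, 8, 3)
  f0 <- friedman_rank_test(alleq)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p_two_sided, 1)

  set.seed(220)
  m <- matrix(rnorm(24), 8, 3)
  ours <- friedman_rank_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_two_sided, ref$p.value)
  # with ties
  mt <- round(m, 0)
  expect_equal(friedman_rank_test(mt)$statistic,
               unname(stats::friedman.test(mt)$statistic))
})

test_that("Friedman p is invariant under monotone transformation", {
  set.seed(221)
  m <- matrix(rexp(24), 8, 3)
  expect_equal(friedman_rank_test(m)$statistic,
               friedman_rank_test(log(m))$statistic)
})

test_that("design-A comparisons produce one result per electrode x band x timepoint", {
  set.seed(230)
  grid <- expand.grid(animal = 1:6,
                      channel = paste0("E", 1:5, "L"),
                      epoch = c("baseline", "0h", "4h", "8h", "12h"),
                      band = c("delta", "theta", "alpha", "beta", "gamma"),
                      stringsAsFactors = FALSE)
  grid$mean_power <- rlnorm(nrow(grid))
  # forced effect: alpha at 0h on E5L reduced 70% below baseline in every pig
  base <- grid$epoch == "baseline" & grid$channel == "E5L" &
    grid$band == "alpha"
  at0 <- grid$epoch == "0h" & grid$channel == "E5L" & grid$band == "alpha"
  grid$mean_power[at0] <- 0.3 * grid$mean_power[base]
  res <- compare_timepoints(grid)
  expect_identical(nrow(res), 100L)  # 5 electrodes x 5 bands x 4 contrasts
  hit <- res[res$electrode == "E5L" & res$band == "alpha" &
               res$contrast == "baseline_vs_0h", ]
  expect_equal(hit$p, 0.03125)
  expect_true(hit$significant)
})

test_that("identical paired values surface as untestable entries", {
  grid <- expand.grid(animal = 1:6, channel = "E1L",
                      epoch = c("baseline", "4h"), band = "delta",
                      stringsAsFactors = FALSE)
  grid$mean_power <- rep(1:6, 2)
  res <- compare_timepoints(grid, timepoints = "4h")
  expect_true(is.na(res$p))
  expect_true(is.na(res$significant))
})

test_that("design-B comparisons cover both contrasts per electrode and band", {
  set.seed(231)
  lm <- expand.grid(electrode = c("E1L", "E2L", "E3L"), lapse = 1:8,
                    phase = c("preSD", "SD", "postSD"),
                    band = c("delta", "theta", "alpha", "beta", "gamma"),
                    stringsAsFactors = FALSE)
  lm$mean_power <- rlnorm(nrow(lm))
  res <- compare_sd_phases(lm)
  expect_identical(nrow(res), 30L)  # 3 electrodes x 5 bands x 2 contrasts
  expect_true(all(res$n == 8))
  expect_setequal(unique(res$contrast), c("preSD_vs_SD", "preSD_vs_postSD"))
})
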