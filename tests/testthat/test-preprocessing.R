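test_that("notch removes 50 Hz by >= 30 dB and spares the passband", {
  fs <- 200
  rec50 <- sine_recording(50, amp = 10, fs = fs, dur = 60)
  out <- notch_filter(rec50)
  core <- out$data[[1]][(5 * fs):(55 * fs)]  # trim filter transients
  expect_lt(rms(core), 0.32)

  rec10 <- sine_recording(10, amp = 10, fs = fs, dur = 60)
  out10 <- notch_filter(rec10)$data[[1]][(5 * fs):(55 * fs)]
  in10 <- rec10$data[[1]][(5 * fs):(55 * fs)]
  expect_lt(abs(rms(out10) / rms(in10) - 1), 0.01)

  zero <- recording(list(E1L = numeric(2000)), fs = fs)
  expect_equal(notch_filter(zero)$data[[1]], numeric(2000))
})

test_that("AC high-pass removes DC and infra-slow content, keeps 1 Hz", {
  fs <- 50
  const <- recording(list(E1L = rep(100, 600 * fs)), fs = fs)
  out <- ac_highpass(const)$data[[1]]
  expect_lt(max(abs(out[(60 * fs):(540 * fs)])), 1)

  r1 <- sine_recording(1, amp = 1, fs = fs, dur = 600)
  y1 <- ac_highpass(r1)$data[[1]][(60 * fs):(540 * fs)]
  expect_lt(abs(rms(y1) / rms(r1$data[[1]][(60 * fs):(540 * fs)]) - 1), 0.02)

  rslow <- sine_recording(0.01, amp = 1, fs = fs, dur = 600)
  yslow <- ac_highpass(rslow)$data[[1]][(60 * fs):(540 * fs)]
  expect_lt(rms(yslow) / rms(rslow$data[[1]][(60 * fs):(540 * fs)]), 0.1)
})

test_that("near-DC view rejects band activity and keeps NDCS shape", {
  fs <- 200
  r45 <- sine_recording(45, amp = 1, fs = fs, dur = 60)
  y45 <- dc_view(r45)$data[[1]][(10 * fs):(50 * fs)]
  expect_lt(rms(y45) / rms(r45$data[[1]][(10 * fs):(50 * fs)]), 0.01)

  n <- 600 * fs
  trap <- trapezoid_signal(n, fs, onset = 300, d = 50, ramp = 10,
                           depth = 1000)
  v <- dc_view(recording(list(E1L = trap), fs = fs))$data[[1]]
  expect_lt(abs(min(v) - min(trap)) / 1000, 0.05)

  zero <- recording(list(E1L = numeric(2000)), fs = fs)
  expect_equal(dc_view(zero)$data[[1]], numeric(2000))
})

test_that("power envelope tracks band power of stationary and stepped sines", {
  fs <- 200
  rec <- sine_recording(10, amp = 1, fs = fs, dur = 300)
  env <- power_envelope(rec, c(8, 12), smooth_window_s = 10)$data[[1]]
  mid <- env[(60 * fs):(240 * fs)]
  expect_lt(abs(mean(mid) - 0.5), 0.025)
  expect_true(all(env >= 0))

  t <- (0:(300 * fs - 1)) / fs
  amp <- ifelse(t < 150, 1, 0.5)
  stepped <- recording(list(E1L = amp * sin(2 * pi * 10 * t)), fs = fs)
  env2 <- power_envelope(stepped, c(8, 12), smooth_window_s = 10)$data[[1]]
  before <- mean(env2[(60 * fs):(130 * fs)])
  after <- mean(env2[(170 * fs):(240 * fs)])
  expect_lt(abs(after / before - 0.25), 0.02)
})

test_that("envelope of white noise matches the in-band power fraction", {
  fs <- 200
  set.seed(21)
  x <- rnorm(300 * fs)
  rec <- recording(list(E1L = x), fs = fs)
  env <- power_envelope(rec, c(8, 12), smooth_window_s = 30)$data[[1]]
  got <- mean(env[(30 * fs):(270 * fs)])
  # oracle: unit-variance white noise has flat PSD 1/(fs/2); the envelope
  # mean equals that density integrated through the squared (zero-phase)
  # band-pass magnitude response
  bp <- signal::butter(4, c(8, 12) / (fs / 2), type = "pass")
  hf <- signal::freqz(bp$b, bp$a, n = 8192, Fs = fs)
  expected <- mean(Mod(hf$h)^4)
  expect_lt(abs(got - expected) / expected, 0.05)
  # and stays near the ideal in-band fraction of the noise power
  expect_lt(abs(got - 4 / (fs / 2)) / (4 / (fs / 2)), 0.2)
})

test_that("preprocessing filters are linear and zero-phase", {
  fs <- 200
  set.seed(22)
  # broadband but passband-weighted probe so each filter's output retains
  # enough shared variance for a sharp cross-correlation peak
  slow <- as.numeric(signal::filter(signal::butter(2, 0.3 / (fs / 2)),
                                    rnorm(240 * fs))) * 5
  x <- slow + rnorm(240 * fs)
  y <- as.numeric(signal::filter(signal::butter(2, 0.3 / (fs / 2)),
                                 rnorm(240 * fs))) * 5 + rnorm(240 * fs)
  for (f in list(notch_filter, dc_view, ac_highpass)) {
    fx <- f(recording(list(a = x), fs = fs))$data[[1]]
    fy <- f(recording(list(a = y), fs = fs))$data[[1]]
    fxy <- f(recording(list(a = 2 * x + 3 * y), fs = fs))$data[[1]]
    expect_lt(max(abs(fxy - 2 * fx - 3 * fy)) /
                max(abs(c(2 * x + 3 * y))), 1e-9)
    # cross-correlation peak between input and output at zero lag
    cc <- stats::ccf(fx, x, lag.max = 20, plot = FALSE)
    expect_identical(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("dc_restore exactly inverts the simulated AC coupling", {
  fs <- 200
  set.seed(23)
  x <- as.numeric(signal::filter(signal::butter(2, 0.2), rnorm(20 * fs))) * 50
  x <- x + trapezoid_signal(20 * fs, fs, onset = 10, d = 5, ramp = 1,
                            depth = 500)
  y <- ac_couple(x, fs, 0.1)
  xr <- dc_restore(recording(list(a = y), fs = fs))$data[[1]]
  err <- (xr - median(xr)) - (x - median(x))
  expect_lt(max(abs(err)), 1e-6)
})
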