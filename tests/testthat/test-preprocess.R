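test_that("the moving average removes DC and drift but spares the rhythms", {
  # constant offset vanishes
  const <- raw_from_matrix(matrix(3.7, 2, 5000))
  out <- remove_baseline(const)
  expect_lt(max(abs(out$data)), 1e-9)
  # 10 Hz sinusoid (integer cycles per window) passes essentially intact
  s <- sine_raw(10, dur = 10)
  kept <- remove_baseline(s, window_s = 1.0)
  expect_gte(sqrt(mean(kept$data^2)), 0.99 * sqrt(mean(s$data^2)))
  # linear ramp: the centered mean reproduces the ramp in the interior
  m <- 2.5
  ramp <- raw_from_matrix(matrix(m * (0:9999) / 1000, 1))
  res <- remove_baseline(ramp)$data[1, 2000:8000]
  expect_lt(max(abs(res)), m * 1.0 / 2)
  expect_error(remove_baseline(raw_from_matrix(matrix(1, 1, 500)),
                               window_s = 1), "longer than")
})

test_that("the adaptive canceller removes 50 Hz and spares other bands", {
  s50 <- sine_raw(50, dur = 10)
  out <- remove_line_noise(s50)
  post <- out$raw$data[1, 2001:10000]
  expect_lt(sqrt(mean(post^2)), 0.05 * sqrt(mean(s50$data^2)))
  expect_true(all(out$report$metrics$power_after <=
                  out$report$metrics$power_before + 1e-12))
  # a 10 Hz tone is orthogonal to the quadrature reference
  s10 <- sine_raw(10, dur = 10)
  kept <- remove_line_noise(s10)$raw$data
  expect_lt(abs(sqrt(mean(kept^2) / mean(s10$data^2)) - 1), 0.01)
  # zero in, zero out; invalid step rejected
  z <- raw_from_matrix(matrix(0, 1, 3000))
  expect_equal(max(abs(remove_line_noise(z)$raw$data)), 0)
  expect_error(remove_line_noise(s10, lms_step = 0), "positive")
  expect_error(remove_line_noise(s10, f0 = 600), "Nyquist")
})

test_that("ICA flags and removes blink components against the reference", {
  sched <- build_assessment_schedule(1, 2, seed = 21)
  clean <- simulate_session(sched, seed = 22)
  dirty <- inject_artifacts(clean, blink_rate_hz = 1.5, seed = 23)
  ref <- dirty$aux_blink_ref
  fc <- which(make_montage()$labels == "FC1")
  before <- abs(cor(dirty$data[fc, ], ref))
  res <- remove_eog(dirty, seed = 24)
  expect_gt(length(res$report$metrics$flagged), 0)
  after <- abs(cor(res$raw$data[fc, ], ref))
  expect_lt(after, 0.2 * before)

  # no blinks present: reference criterion flags nothing
  clean$aux_blink_ref <- ref   # a reference uncorrelated with the data
  none <- remove_eog(clean, seed = 25)
  expect_length(none$report$metrics$flagged, 0)

  short <- raw_from_matrix(matrix(rnorm(19 * 10), 19, 10))
  expect_error(remove_eog(short), "more samples than channels")
})

test_that("the band-pass matches the sixth-order zero-phase contract", {
  gain_at <- function(freq) {
    s <- sine_raw(freq, dur = 20)
    y <- bandpass(s)$data[1, 5000:15000]
    x <- s$data[1, 5000:15000]
    sqrt(mean(y^2) / mean(x^2))
  }
  expect_lt(abs(gain_at(8) - 0.5), 0.01)
  expect_lt(abs(gain_at(32) - 0.5), 0.01)
  expect_gt(gain_at(20), 0.98)
  # stop-band leakage at 50 Hz equals the analytic two-pass response
  bf <- signal::butter(3, c(8, 32) / 500, type = "pass")
  resp <- function(f) {
    z <- exp(-1i * 2 * pi * f / 1000)
    abs(sum(bf$b * z^(0:6)) / sum(bf$a * z^(0:6)))^2
  }
  expect_lt(abs(gain_at(50) - resp(50)), 0.005)
  expect_lt(gain_at(50), 0.03)
  expect_error(bandpass(sine_raw(10), low = 40, high = 30), "band edges")
})

test_that("epoch extraction matches the paradigm windows", {
  sched <- build_assessment_schedule(3, 30, seed = 26)
  raw <- simulate_session(sched, subject_params(pink_noise_sd = 0),
                          seed = 27)
  ep <- extract_epochs(raw)
  expect_equal(dim(ep$data), c(90, 19, 5000))
  expect_equal(as.character(ep$labels), sched$events$label)

  tr <- build_training_schedule(1, 1, 4, seed = 28)[[1]]
  rawt <- simulate_session(tr, seed = 29)
  expect_equal(dim(extract_epochs(rawt)$data)[3], 4000)

  none <- extract_epochs(simulate_session(
    build_assessment_schedule(1, 0, seed = 1), seed = 2))
  expect_equal(dim(none$data)[1], 0)

  truncated <- raw
  truncated$data <- truncated$data[, 1:100000]
  expect_error(extract_epochs(truncated), "trial 10")
})

test_that("the full chain suppresses all three artifact classes", {
  sched <- build_assessment_schedule(1, 6, seed = 31)   # 60 s
  clean <- simulate_session(sched, seed = 32)
  dirty <- inject_artifacts(clean, drift_sd = 20, line_amp = 15,
                            blink_rate_hz = 0.5, seed = 33)
  pre50 <- mean(vapply(seq_len(19), function(c)
    mibci:::tone_power(dirty$data[c, ], 1000, 50), 0))
  out <- preprocess_chain(dirty, seed = 34)
  post50 <- mean(vapply(seq_len(19), function(c)
    mibci:::tone_power(out$raw$data[c, ], 1000, 50), 0))
  expect_lt(post50, 0.05 * pre50)
  # sub-8 Hz residue is a sliver of the total power
  wp <- mibci:::welch_psd(t(out$raw$data), 1000, 2000)
  low <- sum(mibci:::band_power(wp, 0, 8))
  total <- sum(mibci:::band_power(wp, 0, 500))
  expect_lt(low / total, 0.05)
  expect_equal(dim(out$epochs$data)[1], 6)
})
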