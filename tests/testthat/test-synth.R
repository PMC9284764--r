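mont <- make_montage()

test_that("the montage has 19 mirror-symmetric motor-area channels", {
  expect_length(mont$labels, 19)
  expect_equal(anyDuplicated(mont$labels), 0)
  expect_equal(unname(mont$positions["Cz", ]), c(0, 0))
  left <- mont$positions[grepl("[135]$", mont$labels), ]
  right <- mont$positions[grepl("[246]$", mont$labels), ]
  # mirroring left across x = 0 reproduces the right-side positions
  mirrored <- left
  mirrored[, 1] <- -mirrored[, 1]
  rownames(mirrored) <- NULL
  rownames(right) <- NULL
  expect_equal(mirrored, right)
})

test_that("simulated recordings cover the schedule and are seed-reproducible", {
  sched <- build_assessment_schedule(1, 4, seed = 1)
  raw <- simulate_session(sched, seed = 2)
  expect_equal(ncol(raw$data), 40 * 1000)
  expect_equal(nrow(raw$data), 19)
  expect_equal(raw$sample_rate_hz, 1000)
  raw2 <- simulate_session(sched, seed = 2)
  expect_identical(raw$data, raw2$data)
  # empty schedule -> minimal recording, no error
  none <- simulate_session(build_assessment_schedule(1, 0, seed = 1),
                           seed = 3)
  expect_equal(ncol(none$data), 1000)
})

mu_power_at <- function(epochs, channel, trials) {
  idx <- which(mont$labels == channel)
  mean(vapply(trials, function(t) {
    wp <- mibci:::welch_psd(epochs$data[t, idx, ], 1000, 1000)
    mibci:::band_power(wp, 8, 13)
  }, 0))
}

test_that("contralateral mu suppression follows the amplitude model", {
  # deterministic ERD (full engagement), no channel noise: right-hand MI
  # suppresses the left (C3) source to half amplitude -> quarter power
  sched <- build_assessment_schedule(2, 30, seed = 5)
  sub <- subject_params(mu_amp = 2, beta_amp = 0, pink_noise_sd = 0,
                        erd_depth = 0.5, engagement_range = c(1, 1))
  raw <- simulate_session(sched, sub, scene_condition("vr", gain = 1),
                          seed = 6)
  ep <- extract_epochs(raw)
  lab <- as.character(ep$labels)
  ratio <- mu_power_at(ep, "C3", which(lab == "right")) /
           mu_power_at(ep, "C3", which(lab == "left"))
  expect_lt(abs(ratio - 0.25), 0.025)
})

test_that("no class effect is injected when the ERD depth is zero", {
  sched <- build_assessment_schedule(2, 30, seed = 7)
  sub <- subject_params(erd_depth = 0, pink_noise_sd = 0)
  raw <- simulate_session(sched, sub, scene_condition("vr", gain = 1),
                          seed = 8)
  ep <- extract_epochs(raw)
  lab <- as.character(ep$labels)
  ratio <- mu_power_at(ep, "C3", which(lab == "right")) /
           mu_power_at(ep, "C3", which(lab == "left"))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("lateralization sign and monotonicity in the effective ERD hold", {
  sched <- build_assessment_schedule(1, 20, seed = 9)
  contrast <- vapply(c(0, 0.3, 0.6, 0.9), function(g) {
    sub <- subject_params(engagement_range = c(1, 1))
    raw <- simulate_session(sched, sub, scene_condition("vr", gain = g),
                            seed = 10)
    ep <- extract_epochs(raw)
    lab <- as.character(ep$labels)
    mu_power_at(ep, "C4", which(lab == "right")) -
      mu_power_at(ep, "C3", which(lab == "right"))
  }, 0)
  # during right-hand MI, C4 power exceeds C3 once ERD is present
  expect_true(all(contrast[-1] > 0))
  # and the contrast grows with the effective ERD depth
  expect_true(all(diff(contrast) > 0))
})

test_that("artifact injection adds exactly the requested components", {
  sched <- build_assessment_schedule(1, 2, seed = 11)
  raw <- simulate_session(sched, seed = 12)
  same <- inject_artifacts(raw, 0, 0, 0, seed = 13)
  expect_identical(same$data, raw$data)
  expect_error(inject_artifacts(raw, drift_sd = -1), "non-negative")

  # pure 50 Hz on a silent recording: power a^2 / 2 per channel
  silent <- raw_from_matrix(matrix(0, 3, 20000))
  a <- 7
  lined <- inject_artifacts(silent, line_amp = a, seed = 14)
  p <- mean(lined$data[2, ]^2)
  expect_lt(abs(p - a^2 / 2) / (a^2 / 2), 0.05)

  # blink counts follow the Poisson rate (99% interval, with slack for
  # pulses merged by overlap)
  silent60 <- raw_from_matrix(matrix(0, 19, 60000),
                              labels = make_montage()$labels)
  blinked <- inject_artifacts(silent60, blink_rate_hz = 2, seed = 15)
  ref <- blinked$aux_blink_ref
  upcross <- sum(diff(ref > 0.5) == 1)
  expect_gt(upcross, 88)
  expect_lt(upcross, 152)
  # anterior row carries the strongest blink weight
  fc1 <- which(make_montage()$labels == "FC1")
  cp5 <- which(make_montage()$labels == "CP5")
  expect_gt(max(abs(blinked$data[fc1, ])), max(abs(blinked$data[cp5, ])))
})
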