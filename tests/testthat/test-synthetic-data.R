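test_that("sim_config validates its schedule", {
  expect_error(sim_config(1, 100, state_schedule = data.frame(
    start = c(0, 40), end = c(50, 80), state = "torpor")), "overlap")
  expect_error(sim_config(1, 100, state_schedule = data.frame(
    start = 50, end = 150, state = "torpor")), "within")
  expect_error(sim_config(1, 100, state_schedule = data.frame(
    start = 50, end = 40, state = "torpor")), "end > start")
  expect_silent(sim_config(1, 100, state_schedule = data.frame(
    start = c(0, 50), end = c(50, 100), state = c("a", "b"))))
})

test_that("every generator is bitwise deterministic under its seed", {
  cfg <- sim_config(9, duration = 720, state_schedule = data.frame(
    start = 200, end = 350, state = "torpor"))
  expect_identical(gen_core_temperature(cfg), gen_core_temperature(cfg))

  cfgp <- sim_config(9, duration = 5, noise_sd = 0.3)
  expect_identical(gen_photometry(cfgp), gen_photometry(cfgp))

  cfgf <- sim_config(9, duration = 20)
  expect_identical(gen_firing_assay(cfgf, 20, q10_dist = function(n) runif(n, 0.5, 4)),
                   gen_firing_assay(cfgf, 20, q10_dist = function(n) runif(n, 0.5, 4)))

  cfge <- sim_config(9, duration = 2, noise_sd = 0.1)
  expect_identical(gen_eeg(cfge, list(baseline = c(delta = 1, theta = 2))),
                   gen_eeg(cfge, list(baseline = c(delta = 1, theta = 2))))

  cfgb <- sim_config(9, duration = 2)
  expect_identical(gen_beats(cfgb, 600, 0.05), gen_beats(cfgb, 600, 0.05))
})

test_that("degenerate configurations collapse to constants", {
  cfg <- sim_config(1, duration = 720, noise_sd = 0)
  sim <- gen_core_temperature(cfg, circadian_mean = 37,
                              circadian_amplitude = 0)
  expect_equal(sim$trace$temp, rep(37, nrow(sim$trace)))
  expect_equal(nrow(sim$truth$true_bouts), 0L)

  cfgp <- sim_config(1, duration = 2, noise_sd = 0)
  sim <- gen_photometry(cfgp, event_rate_by_state = c(baseline = 0),
                        artifact_amplitude = 0, bleach_tau = Inf)
  d <- demux_channels(sim$recording)
  expect_equal(length(unique(d$signal$value)), 1L)
  expect_equal(length(unique(d$reference$value)), 1L)

  sim <- gen_beats(sim_config(1, duration = 1), rate_bpm = 600,
                   pause_prob = 0, jitter = 0)
  expect_equal(unique(round(diff(sim$beats), 10)), 0.1)
})

test_that("generator noise obeys configured moments", {
  cfg <- sim_config(77, duration = 7200, noise_sd = 0.2)
  sim <- gen_core_temperature(cfg, circadian_mean = 37,
                              circadian_amplitude = 0)
  resid <- sim$trace$temp - sim$truth$noiseless
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * 0.2 / sqrt(n))
  expect_lt(abs(sd(resid) - 0.2), 3 * 0.2 / sqrt(2 * (n - 1)))
})

test_that("generator precondition violations are rejected", {
  cfg <- sim_config(1, 720, state_schedule = data.frame(start = 100, end = 300,
                                                        state = "torpor"))
  expect_error(gen_core_temperature(cfg, bout_depth = -1), "positive")
  expect_error(gen_core_temperature(cfg, entry_rate = 0), "positive")
  expect_error(gen_photometry(sim_config(1, 1), amplitude_dist = c(-0.1, 0.01)),
               "positive")
  expect_error(gen_photometry(sim_config(1, 1), decay_tau = 0), "positive")
  expect_error(gen_firing_assay(sim_config(1, 1), 5, base_rate = 0), "positive")
  expect_error(gen_beats(sim_config(1, 1), rate_bpm = 0), "positive")
  expect_error(gen_beats(sim_config(1, 1), pause_prob = 0.6), "0.5")
})

test_that("scheduled bouts are recovered by the bout detector", {
  cfg <- sim_config(5, duration = 2880, noise_sd = 0.1,
                    state_schedule = data.frame(start = c(600, 1800),
                                                end = c(900, 2100),
                                                state = "torpor"))
  sim <- gen_core_temperature(cfg, bout_depth = 8)
  b <- detect_bouts(sim$trace, threshold = 31)
  expect_equal(nrow(b), 2L)
  expect_equal(nrow(sim$truth$true_bouts), 2L)
  # detected boundaries within one sample of the noiseless ground truth
  expect_true(all(abs(b$start - sim$truth$true_bouts$start) <= 5))
  expect_true(all(abs(b$end - sim$truth$true_bouts$end) <= 5))
})

test_that("firing assay ground truth drives the configured rate change", {
  sim <- gen_firing_assay(sim_config(13, 20), n_neurons = 50, q10_dist = 1,
                          base_rate = 50, n_bins = 20)
  res <- score_thermoresponse(sim$assays)
  expect_lt(abs(mean(res$mean_rate_t2 - res$mean_rate_t1)), 0.05)
  expect_equal(unname(sim$truth$true_q10), rep(1, 50))

  sim4 <- gen_firing_assay(sim_config(13, 20), n_neurons = 10, q10_dist = 4,
                           base_rate = 5, n_bins = 5)
  res4 <- score_thermoresponse(sim4$assays)
  # expected rate doubles when q10 = 4 over a 5 degC step
  expect_equal(mean(res4$mean_rate_t2 / res4$mean_rate_t1), 2, tolerance = 0.1)
})
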