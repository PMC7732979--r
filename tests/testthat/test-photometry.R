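test_that("demux splits channels by alternation and detects violations", {
  rec <- photometry_recording(c(1, 2, 3, 4), c("405", "470", "405", "470"))
  d <- demux_channels(rec)
  expect_equal(d$reference$value, c(1, 3))
  expect_equal(d$signal$value, c(2, 4))
  expect_equal(d$fs, 10)
  expect_equal(d$signal$time, c(0.05, 0.15))

  e <- demux_channels(photometry_recording(numeric(0), character(0)))
  expect_equal(nrow(e$signal), 0L)

  # index-parity oracle on a random tagged stream
  set.seed(8)
  v <- rnorm(200)
  rec <- photometry_recording(v, rep(c("470", "405"), 100))
  d <- demux_channels(rec)
  expect_equal(d$signal$value, v[seq(1, 199, 2)])
  expect_equal(d$reference$value, v[seq(2, 200, 2)])

  tags <- rep(c("405", "470"), 10); tags[8] <- "405"
  expect_error(demux_channels(photometry_recording(rnorm(20), tags)),
               "sample 8")
  expect_error(demux_channels(photometry_recording(rnorm(3),
                                                   c("405", "470", "405"))),
               "odd")
})

test_that("reference fit removes shared artifacts exactly when linear", {
  set.seed(10)
  ref <- 100 + cumsum(rnorm(600, 0, 0.1))
  d <- correct_reference(ref, ref)
  expect_lt(max(abs(d$dff)), 1e-10)

  d <- correct_reference(2 * ref + 3, ref)
  expect_lt(max(abs(d$dff)), 1e-10)
  expect_equal(unname(attr(d, "fit")["scale"]), 2)

  # invariant to rescaling both channels by a common positive constant
  sig <- ref + c(rep(0, 300), 5 * exp(-(1:300) / 20))
  d1 <- correct_reference(sig, ref)
  d2 <- correct_reference(sig * 3.7, ref * 3.7)
  expect_equal(d1$dff, d2$dff)

  expect_warning(correct_reference(sig, rep(50, 600)), "offset-only")
  expect_error(correct_reference(sig[1:10], ref[1:10]), "at least")
})

test_that("rolling baseline equals the brute-force windowed percentile", {
  const <- rolling_baseline(rep(0.3, 100), window = 2, fs = 10)
  expect_equal(const$baseline, rep(0.3, 100))

  set.seed(12)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    x <- rnorm(n)
    half <- 11 %/% 2
    got <- rolling_baseline(x, window = 1.1, fs = 10)  # 11-sample window
    expect_identical(got$baseline, oracle_roll_pctl(x, half, 0.10))
    expect_equal(got$local_sd, oracle_roll_sd(x, half))
    # order-statistic property: baseline never above the window median
    expect_true(all(got$baseline <= oracle_roll_pctl(x, half, 0.5) + 1e-12))
  }

  expect_warning(g <- rolling_baseline(rnorm(20), window = 60, fs = 10),
                 "global")
  expect_equal(length(unique(g$baseline)), 1L)
  expect_error(rolling_baseline(rnorm(100), window = 0.5, fs = 10),
               "at least 10")
})

test_that("transient detection recovers constructed geometry", {
  fs <- 10
  tm <- seq(0, 19.9, by = 1 / fs)
  flat <- dff_trace(tm, rep(0, length(tm)), baseline = 0, local_sd = 0.05)
  expect_equal(nrow(detect_transients(flat)), 0L)

  pulse <- pmax(0, 1 - abs(tm - 10) / 2)  # triangle: up 2 s, down 2 s
  d <- dff_trace(tm, pulse, baseline = 0, local_sd = 0.05)
  pk <- detect_transients(d, k = 2)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$amplitude, 1.0)
  expect_equal(pk$peak_time, 10)
  expect_equal(pk$base_width, 4.0, tolerance = 0.1)
})

test_that("generated transients are recovered with few false positives", {
  cfg <- sim_config(42, duration = 15, noise_sd = 0.3)
  sim <- gen_photometry(cfg, event_rate_by_state = c(baseline = 1.2),
                        amplitude_dist = c(0.1, 0.01), min_separation = 35)
  truth <- sim$truth$true_transients
  d <- demux_channels(sim$recording)
  dff <- rolling_baseline(correct_reference(d$signal, d$reference))
  pk <- detect_transients(dff, k = 5)
  m <- match_transients(pk$onset, truth$time, tol = 0.5)
  recall <- mean(!is.na(m))
  expect_gte(recall, 0.9)
  expect_lte(nrow(pk) - sum(!is.na(m)), 1L)       # false positives
  rel_err <- abs(pk$amplitude[m[!is.na(m)]] - truth$amplitude[!is.na(m)]) /
    truth$amplitude[!is.na(m)]
  expect_lte(mean(rel_err), 0.10)
})

test_that("epoch metrics match an independent recomputation", {
  fs <- 10
  tm <- seq(0, 59.9, by = 1 / fs)
  flat <- dff_trace(tm, rep(0, length(tm)), baseline = 0, local_sd = 0.01)
  m <- epoch_metrics(flat, pm_epoch(0, 60))
  expect_equal(m$auc, 0)
  expect_equal(m$variance, 0)
  expect_equal(m$n_peaks, 0L)
  expect_true(is.na(m$mean_peak_amplitude))
  expect_equal(m$total_peak_area, 0)

  # two disjoint identical triangles: total peak area doubles
  tri <- function(center) pmax(0, 1 - abs(tm - center) / 2)
  one <- dff_trace(tm, tri(15), baseline = 0, local_sd = 0.02)
  two <- dff_trace(tm, tri(15) + tri(40), baseline = 0, local_sd = 0.02)
  m1 <- epoch_metrics(one, pm_epoch(0, 60))
  m2 <- epoch_metrics(two, pm_epoch(0, 60))
  expect_equal(m2$n_peaks, 2L)
  expect_equal(m2$total_peak_area, 2 * m1$total_peak_area, tolerance = 0.02)
  expect_equal(m2$mean_peak_amplitude, m1$mean_peak_amplitude)

  # oracle recomputation of every metric on a synthetic epoch
  set.seed(14)
  x <- tri(20) * 0.8 + rnorm(length(tm), 0, 0.002)
  d <- rolling_baseline(dff_trace(tm, x), window = 6)
  m <- epoch_metrics(d, pm_epoch(0, 60), k = 5)
  dt <- 1 / fs
  auc_oracle <- sum(diff(tm) * ((x - min(x))[-1] + (x - min(x))[-length(x)]) / 2)
  expect_equal(m$auc, auc_oracle)
  expect_equal(m$variance, var(x))
  expect_equal(m$sd, sd(x))
  expect_equal(m$baseline_mean, mean(d$baseline))
  pk <- detect_transients(d, k = 5)
  expect_equal(m$n_peaks, nrow(pk))
  expect_equal(m$mean_peak_amplitude, mean(pk$amplitude))
  expect_equal(m$mean_peak_width, mean(pk$base_width))
  # total peak area bounded by the AUC above baseline
  above <- pmax(x - d$baseline, 0)
  expect_lte(m$total_peak_area,
             sum(diff(tm) * (above[-1] + above[-length(above)]) / 2) + 1e-12)
})

test_that("epoch temperature labels follow the strict 33 degC rule", {
  expect_equal(label_epoch_by_temperature(rep(31, 10)), "hypothermia")
  expect_equal(label_epoch_by_temperature(rep(36.5, 10)), "normothermia")
  expect_equal(label_epoch_by_temperature(rep(33, 10)), "normothermia")
  expect_true(is.na(label_epoch_by_temperature(NULL)))
  expect_equal(label_epoch_by_temperature(rep(34, 5), normo_threshold = 36),
               "intermediate")
})

test_that("hypothermia-style epochs show larger transients than normothermia", {
  wins <- 0L
  n_runs <- 10L
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(7000 + s, duration = 20, noise_sd = 0.3,
                      state_schedule = data.frame(start = 10, end = 20,
                                                  state = "hypothermia"))
    sim <- gen_photometry(cfg,
      event_rate_by_state = c(baseline = 2, hypothermia = 2),
      amplitude_dist = list(baseline = c(0.03, 0.005),
                            hypothermia = c(0.12, 0.02)))
    d <- demux_channels(sim$recording)
    dff <- rolling_baseline(correct_reference(d$signal, d$reference))
    normo <- epoch_metrics(dff, pm_epoch(0, 600, label = "normothermia"), k = 5)
    hypo <- epoch_metrics(dff, pm_epoch(600, 600, label = "hypothermia"), k = 5)
    ok <- isTRUE(hypo$variance > normo$variance) &&
      isTRUE(hypo$mean_peak_amplitude > normo$mean_peak_amplitude)
    wins <- wins + ok
  }
  expect_gte(wins, n_runs - 1L)
})
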