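test_that("detect_bouts handles forced cases", {
  flat <- temperature_trace(seq(0, 115, 5), rep(37, 24))
  expect_equal(nrow(detect_bouts(flat)), 0L)

  cold <- temperature_trace(seq(0, 55, 5), rep(30, 12))
  b <- detect_bouts(cold)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 60)
  expect_equal(b$min_temp, 30)

  mix <- temperature_trace(seq(0, 25, 5), c(37, 30, 30, 37, 29, 37))
  b <- detect_bouts(mix, threshold = 31, merge_gap = 0)
  expect_equal(b$duration, c(10, 5))
  expect_equal(b$start, c(5, 20))
  expect_equal(b$min_temp, c(30, 29))
})

test_that("threshold is inclusive and missing samples break bouts", {
  tr <- temperature_trace(seq(0, 25, 5), c(37, 31, 31, NA, 31, 37))
  b <- detect_bouts(tr, threshold = 31)
  expect_equal(nrow(b), 2L)   # 31 degC counts; NA splits the run
  expect_equal(b$duration, c(10, 5))
})

test_that("merge_gap and min_duration post-process runs as documented", {
  tr <- temperature_trace(seq(0, 40, 5), c(30, 30, 37, 30, 37, 37, 30, 37, 37))
  expect_equal(nrow(detect_bouts(tr)), 3L)
  b <- detect_bouts(tr, merge_gap = 5)
  expect_equal(nrow(b), 2L)               # first gap (5 min) bridged
  expect_equal(b$duration[1L], 20)
  expect_equal(b$min_temp[1L], 30)
  b2 <- detect_bouts(tr, min_duration = 10)
  expect_equal(nrow(b2), 1L)              # single-sample bouts dropped
  expect_equal(nrow(detect_bouts(tr, merge_gap = 5, min_duration = 15)), 1L)
})

test_that("detect_bouts equals the brute-force scan on random traces", {
  set.seed(101)
  for (i in 1:300) {
    tr <- random_trace(n = sample(5:80, 1))
    got <- detect_bouts(tr, threshold = 31)
    want <- oracle_bouts(tr$time, tr$temp, attr(tr, "interval"), 31)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$min_temp, want$min_temp)
  }
})

test_that("bout durations conserve sub-threshold time and respond monotonically", {
  set.seed(7)
  for (i in 1:50) {
    tr <- random_trace(n = 60)
    b <- detect_bouts(tr, threshold = 31)
    n_below <- sum(!is.na(tr$temp) & tr$temp <= 31)
    expect_equal(sum(b$duration), n_below * attr(tr, "interval"))
    # raising the threshold never decreases time below
    b35 <- detect_bouts(tr, threshold = 35)
    expect_gte(sum(b35$duration), sum(b$duration))
    # increasing min_duration never increases the bout count
    expect_lte(nrow(detect_bouts(tr, 31, min_duration = 15)), nrow(b))
  }
})

test_that("detect_bouts rejects bad input", {
  tr <- temperature_trace(c(0, 5, 10), c(37, 36, 35))
  expect_error(detect_bouts(tr, threshold = 50), "plausible range")
  expect_error(temperature_trace(c(0, 5, 12), c(37, 36, 35)), "non-uniform")
  expect_error(temperature_trace(c(0, 5, 5), c(37, 36, 35)),
               "strictly increasing")
})

test_that("summarize_torpor fields match a brute-force scan on generated data", {
  cfg <- sim_config(11, duration = 2880, state_schedule = data.frame(
    start = c(600, 1400, 2200), end = c(800, 1700, 2500), state = "torpor"))
  sim <- gen_core_temperature(cfg)
  base <- temperature_trace(seq(0, 595, 5), rep(37, 120))
  s <- summarize_torpor(sim$trace, base)

  want <- oracle_bouts(sim$trace$time, sim$trace$temp, 5, 31)
  expect_equal(s$n_bouts, nrow(want))
  expect_equal(s$time_below, sum(want$duration))
  expect_equal(s$longest_bout, max(want$duration))
  expect_equal(s$lowest_tcore, min(sim$trace$temp, na.rm = TRUE))
  expect_equal(s$delta_tcore, min(sim$trace$temp, na.rm = TRUE) - 37)
  expect_equal(s$tcore_variance, var(sim$trace$temp, na.rm = TRUE))

  warm <- temperature_trace(seq(0, 115, 5), rep(36, 24))
  s0 <- summarize_torpor(warm, base)
  expect_equal(s0$n_bouts, 0L)
  expect_equal(s0$time_below, 0)
  expect_equal(s0$longest_bout, 0)
  expect_error(summarize_torpor(warm, temperature_trace(0, NA)), "empty")
})

test_that("period_means assigns samples by clock time", {
  # trace starting at lights-on, 36 degC in light, 37 in dark, exactly 24 h
  time <- seq(0, 1435, 5)
  temp <- c(rep(36, 144), rep(37, 144))
  tr <- temperature_trace(time, temp, clock_offset = "7:00")
  m <- period_means(tr)
  expect_equal(m$light_mean, 36)
  expect_equal(m$dark_mean, 37)
  expect_equal(m$total_mean, 36.5)

  flat <- temperature_trace(time, rep(36, 288), clock_offset = "0:00")
  m <- period_means(flat)
  expect_equal(unname(unlist(m)), rep(36, 3))

  # oracle: brute-force clock assignment on a randomized trace
  set.seed(3)
  temp <- runif(288, 30, 40)
  tr <- temperature_trace(time, temp, clock_offset = "13:30")
  m <- period_means(tr)
  clock <- (parse_clock_test("13:30") + time) %% 1440
  light <- clock >= 420 & clock < 1140
  expect_equal(m$light_mean, mean(temp[light]))
  expect_equal(m$dark_mean, mean(temp[!light]))

  short <- temperature_trace(seq(0, 55, 5), rep(36, 12))
  expect_warning(period_means(short), "24 h")
})

test_that("injection_window_means uses half-open windows around injection", {
  time <- seq(0, 1435, 5)
  tr <- temperature_trace(time, rep(36.5, 288))
  m <- injection_window_means(tr, injection_time = 400)
  expect_equal(m$pre_mean, m$post_mean)

  temp <- ifelse(time < 400, 37, 30)
  tr <- temperature_trace(time, temp)
  m <- injection_window_means(tr, 400)
  expect_equal(m$pre_mean, 37)
  expect_equal(m$post_mean, 30)

  set.seed(5)
  temp <- runif(288, 30, 40)
  tr <- temperature_trace(time, temp, allow_implausible = TRUE)
  m <- injection_window_means(tr, 400)
  expect_equal(m$pre_mean, mean(temp[time >= 280 & time < 400]))
  expect_equal(m$post_mean, mean(temp[time >= 520 & time < 580]))

  expect_error(injection_window_means(tr, 60), "not covered")
})

test_that("movement summaries use the same windowing semantics", {
  time <- seq(0, 595, 5)
  zero <- movement_trace(time, rep(0, 120))
  s <- movement_summary(zero, list(c(0, 300), c(300, 600)))
  expect_equal(s$sum, c(0, 0))

  const <- movement_trace(time, rep(10, 120))
  s <- movement_summary(const, c(0, 60))
  expect_equal(s$sum, 120)  # 12 bins of 10 counts

  set.seed(9)
  counts <- rpois(120, 8)
  mv <- movement_trace(time, counts)
  s <- movement_summary(mv, c(100, 400))
  expect_equal(s$sum, sum(counts[time >= 100 & time < 400]))
  expect_equal(s$mean, mean(counts[time >= 100 & time < 400]))

  other <- temperature_trace(seq(0, 299, 2.5), rep(37, 120))
  expect_error(movement_summary(mv, c(0, 60), temperature = other),
               "different time grids")
})
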