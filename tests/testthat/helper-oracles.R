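# Independent brute-force oracles used to cross-check the package's
# implementations. Deliberately written as plain one-pass loops, not via the
# code paths they verify.

# one-pass run-length scan for sub-threshold bouts (no merging, no floor)
oracle_bouts <- function(time, temp, interval, threshold) {
  starts <- ends <- mins <- numeric(0)
  cur_start <- NA_real_; cur_min <- Inf
  for (i in seq_along(time)) {
    below <- !is.na(temp[i]) && temp[i] <= threshold
    if (below) {
      if (is.na(cur_start)) { cur_start <- time[i]; cur_min <- temp[i] }
      else cur_min <- min(cur_min, temp[i])
      cur_end <- time[i] + interval
    } else if (!is.na(cur_start)) {
      starts <- c(starts, cur_start); ends <- c(ends, cur_end)
      mins <- c(mins, cur_min)
      cur_start <- NA_real_; cur_min <- Inf
    }
  }
  if (!is.na(cur_start)) {
    starts <- c(starts, cur_start); ends <- c(ends, cur_end)
    mins <- c(mins, cur_min)
  }
  data.frame(start = starts, end = ends, duration = ends - starts,
             min_temp = mins)
}

# O(n*w) windowed percentile, centered window truncated at the edges,
# linear interpolation between order statistics
oracle_roll_pctl <- function(x, half, p) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - half):min(n, i + half)]
    unname(stats::quantile(w, p, type = 7))
  }, numeric(1))
}

oracle_roll_sd <- function(x, half) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    stats::sd(x[max(1L, i - half):min(n, i + half)]), numeric(1))
}

# random short telemetry trace that dips below threshold often
random_trace <- function(n = 50, interval = 5, p_na = 0.05) {
  temp <- runif(n, 25, 40)
  temp[runif(n) < p_na] <- NA
  temperature_trace(seq(0, by = interval, length.out = n), temp,
                    allow_implausible = TRUE)
}

parse_clock_test <- function(x) {
  p <- as.numeric(strsplit(x, ":")[[1]])
  p[1] * 60 + p[2]
}

# match detected transient onsets to ground-truth event times
match_transients <- function(detected_onsets, true_times, tol = 0.5) {
  used <- rep(FALSE, length(detected_onsets))
  match_idx <- rep(NA_integer_, length(true_times))
  for (j in seq_along(true_times)) {
    d <- abs(detected_onsets - true_times[j])
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      match_idx[j] <- which.min(d)
      used[which.min(d)] <- TRUE
    }
  }
  match_idx
}
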