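#' Core/skin/ambient temperature trace
#'
#' Container for a uniformly sampled temperature telemetry series. Missing
#' samples are explicit `NA`s and are never interpolated.
#'
#' @param time minutes from recording start, strictly increasing on a uniform
#'   grid (default step 5 min).
#' @param temp temperature in deg C. Values outside the plausible range
#'   `[15, 45]` trigger a warning unless `allow_implausible = TRUE`.
#' @param subject_id subject label.
#' @param lights_on,lights_off clock times of the light period, `"HH:MM"`
#'   strings or minutes after midnight (defaults 7:00 and 19:00).
#' @param clock_offset clock time of the first sample (`"HH:MM"` or minutes
#'   after midnight).
#' @param interval expected sampling interval in minutes; inferred from
#'   `time` when `NULL`.
#' @param tolerance relative tolerance on grid uniformity.
#' @param allow_implausible suppress the plausibility warning.
#'
#' @return A `data.frame` of class `temperature_trace` with columns `time`
#'   and `temp`, carrying subject and lighting metadata as attributes.
#' @export
temperature_trace <- function(time, temp, subject_id = "subject",
                              lights_on = "7:00", lights_off = "19:00",
                              clock_offset = 0, interval = NULL,
                              tolerance = 1e-6, allow_implausible = FALSE) {
  stopifnot(length(time) == length(temp), length(time) >= 1L)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  dt <- diff(time)
  if (is.null(interval)) interval <- if (length(dt)) stats::median(dt) else 5
  if (length(dt) && any(abs(dt - interval) > tolerance * interval)) {
    bad <- which(abs(dt - interval) > tolerance * interval)[1L]
    stop(sprintf(
      "non-uniform sampling grid: gap of %g min between t = %g and t = %g (expected %g)",
      dt[bad], time[bad], time[bad + 1L], interval))
  }
  finite <- temp[is.finite(temp)]
  if (!allow_implausible && length(finite) &&
      (any(finite < 15) || any(finite > 45)))
    warning("temperatures outside plausible range [15, 45] degC; ",
            "set allow_implausible = TRUE to silence")
  structure(data.frame(time = as.numeric(time), temp = as.numeric(temp)),
            subject_id = subject_id,
            lights_on = parse_clock(lights_on),
            lights_off = parse_clock(lights_off),
            clock_offset = parse_clock(clock_offset),
            interval = interval,
            class = c("temperature_trace", "data.frame"))
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> subject %s: %d samples every %g min (%.1f h), %d missing\n",
              attr(x, "subject_id"), nrow(x), attr(x, "interval"),
              diff(range(x$time)) / 60, sum(is.na(x$temp))))
  rng <- range(x$temp, na.rm = TRUE)
  cat(sprintf("  temp %.2f to %.2f degC\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.temperature_trace <- function(x, threshold = NULL, ...) {
  plot(x$time / 60, x$temp, type = "l", xlab = "time (h)",
       ylab = "core temperature (degC)", ...)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Detect torpor bouts from a core-temperature trace
#'
#' A bout is a maximal run of consecutive samples with temperature at or
#' below `threshold` (the study criterion is core temperature equal to or
#' below 31 degC). Each run spans `[first sample time, last sample time +
#' interval)`, so a single sub-threshold sample is a bout of one sampling
#' interval. Missing samples break runs; they never extend a bout. Runs
#' separated by at most `merge_gap` minutes are merged, then merged runs
#' shorter than `min_duration` are discarded.
#'
#' @param trace a [temperature_trace()].
#' @param threshold detection threshold in deg C, inclusive (default 31).
#' @param min_duration minimum bout duration in minutes after merging
#'   (default 0: no floor).
#' @param merge_gap maximum supra-threshold gap (minutes) bridged between
#'   runs (default 0: never merge).
#' @return A `data.frame` of class `torpor_bouts` with columns `start`,
#'   `end`, `duration` (minutes) and `min_temp` (deg C), disjoint and ordered.
#' @examples
#' tr <- temperature_trace(seq(0, 25, by = 5), c(37, 30, 30, 37, 29, 37))
#' detect_bouts(tr)  # two bouts: 10 min and 5 min
#' @export
detect_bouts <- function(trace, threshold = 31, min_duration = 0,
                         merge_gap = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (nrow(trace) == 0L) stop("empty trace")
  if (threshold < 15 || threshold > 45)
    stop("threshold outside the trace's plausible range [15, 45] degC")
  interval <- attr(trace, "interval")
  below <- !is.na(trace$temp) & trace$temp <= threshold

  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), min_temp = numeric(0))
  runs <- rle_runs(below)
  if (nrow(runs) == 0L)
    return(structure(empty, threshold = threshold,
                     class = c("torpor_bouts", "data.frame")))

  start <- trace$time[runs$first]
  end <- trace$time[runs$last] + interval
  # merge runs separated by <= merge_gap
  if (nrow(runs) > 1L && merge_gap > 0) {
    keep_start <- c(TRUE, (start[-1L] - end[-length(end)]) > merge_gap)
    grp <- cumsum(keep_start)
    start <- tapply(start, grp, min)
    end <- tapply(end, grp, max)
  }
  min_temp <- vapply(seq_along(start), function(i) {
    sel <- trace$time >= start[i] & trace$time < end[i]
    min(trace$temp[sel], na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    duration = as.numeric(end - start),
                    min_temp = min_temp, row.names = NULL)
  out <- out[out$duration >= min_duration, , drop = FALSE]
  row.names(out) <- NULL
  structure(out, threshold = threshold,
            class = c("torpor_bouts", "data.frame"))
}

# internal: first/last indices of TRUE runs
rle_runs <- function(flag) {
  r <- rle(flag)
  last <- cumsum(r$lengths)
  first <- last - r$lengths + 1L
  keep <- r$values
  data.frame(first = first[keep], last = last[keep])
}

#' @export
print.torpor_bouts <- function(x, ...) {
  cat(sprintf("<torpor_bouts> %d bout(s) at threshold %g degC\n",
              nrow(x), attr(x, "threshold")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Per-animal torpor summary statistics
#'
#' The six summary statistics used to quantify the torpor response:
#' `delta_tcore` (lowest core temperature minus the pre-fast baseline mean),
#' sample variance of core temperature, total time at or below the bout
#' threshold, number of bouts, longest bout, and the lowest core temperature
#' reached. All statistics use non-missing samples only.
#'
#' @param trace fasting-period [temperature_trace()].
#' @param baseline pre-fast [temperature_trace()] of the same subject.
#' @inheritParams detect_bouts
#' @return An object of class `torpor_summary` (a list with fields
#'   `delta_tcore`, `tcore_variance`, `time_below`, `n_bouts`,
#'   `longest_bout`, `lowest_tcore`, plus the detected `bouts`).
#' @export
summarize_torpor <- function(trace, baseline, threshold = 31,
                             min_duration = 0, merge_gap = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (!inherits(baseline, "temperature_trace") || nrow(baseline) == 0L ||
      all(is.na(baseline$temp)))
    stop("baseline trace is empty")
  bouts <- detect_bouts(trace, threshold, min_duration, merge_gap)
  lowest <- min(trace$temp, na.rm = TRUE)
  structure(list(
    delta_tcore = lowest - mean(baseline$temp, na.rm = TRUE),
    tcore_variance = stats::var(trace$temp, na.rm = TRUE),
    time_below = sum(bouts$duration),
    n_bouts = nrow(bouts),
    longest_bout = if (nrow(bouts)) max(bouts$duration) else 0,
    lowest_tcore = lowest,
    bouts = bouts,
    threshold = threshold,
    subject_id = attr(trace, "subject_id")
  ), class = "torpor_summary")
}

#' @export
print.torpor_summary <- function(x, ...) {
  cat(sprintf("<torpor_summary> subject %s (threshold %g degC)\n",
              x$subject_id, x$threshold))
  cat(sprintf("  delta Tcore   %8.2f degC\n", x$delta_tcore))
  cat(sprintf("  Tcore var     %8.3f degC^2\n", x$tcore_variance))
  cat(sprintf("  time <= thr   %8.0f min\n", x$time_below))
  cat(sprintf("  bouts         %8d\n", x$n_bouts))
  cat(sprintf("  longest bout  %8.0f min\n", x$longest_bout))
  cat(sprintf("  lowest Tcore  %8.2f degC\n", x$lowest_tcore))
  invisible(x)
}

#' @export
as.data.frame.torpor_summary <- function(x, ...) {
  data.frame(subject = x$subject_id, delta_tcore = x$delta_tcore,
             tcore_variance = x$tcore_variance, time_below = x$time_below,
             n_bouts = x$n_bouts, longest_bout = x$longest_bout,
             lowest_tcore = x$lowest_tcore)
}

#' Light/dark/total period means
#'
#' Assigns each sample to the light or dark period by its clock time
#' (half-open `[lights_on, lights_off)` is light) and averages within each
#' period and over the whole trace. Defaults follow a 7:00-19:00 light cycle.
#'
#' @param trace a [temperature_trace()] with a known `clock_offset`.
#' @return Named list with `light_mean`, `dark_mean`, `total_mean` (deg C).
#' @export
period_means <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  on_ <- attr(trace, "lights_on"); off_ <- attr(trace, "lights_off")
  clock <- (attr(trace, "clock_offset") + trace$time) %% 1440
  light <- clock >= on_ & clock < off_
  span <- diff(range(trace$time)) + attr(trace, "interval")
  if (span < 1440)
    warning("trace shorter than one full 24 h period; means use available samples")
  list(light_mean = mean(trace$temp[light], na.rm = TRUE),
       dark_mean = mean(trace$temp[!light], na.rm = TRUE),
       total_mean = mean(trace$temp, na.rm = TRUE))
}

#' Pre/post injection window means
#'
#' Means over half-open windows relative to an injection time, by default
#' the study's before (-120 to 0 min) and after (120 to 180 min) windows.
#'
#' @param trace a [temperature_trace()].
#' @param injection_time injection time, minutes from recording start.
#' @param pre_window,post_window numeric length-2 offsets (minutes) relative
#'   to the injection; samples with time in `[injection + lo, injection + hi)`
#'   are included.
#' @return Named list with `pre_mean` and `post_mean` (deg C).
#' @export
injection_window_means <- function(trace, injection_time,
                                   pre_window = c(-120, 0),
                                   post_window = c(120, 180)) {
  stopifnot(inherits(trace, "temperature_trace"))
  win_mean <- function(w) {
    lo <- injection_time + w[1]; hi <- injection_time + w[2]
    covered_lo <- trace$time[1L]
    covered_hi <- trace$time[nrow(trace)] + attr(trace, "interval")
    if (lo < covered_lo || hi > covered_hi)
      stop(sprintf("window [%g, %g) min not covered by trace [%g, %g)",
                   lo, hi, covered_lo, covered_hi))
    sel <- trace$time >= lo & trace$time < hi
    mean(trace$temp[sel], na.rm = TRUE)
  }
  list(pre_mean = win_mean(pre_window), post_mean = win_mean(post_window))
}

#' Windowed movement summaries
#'
#' Sums and means of gross-movement counts over half-open windows
#' `[start, end)`, with the same windowing semantics as the temperature
#' operations. When a paired temperature trace is supplied its time grid
#' must match exactly.
#'
#' @param movement a [temperature_trace()]-style trace whose `temp` column
#'   holds movement counts per bin (build with [movement_trace()]).
#' @param windows list of numeric length-2 windows in minutes.
#' @param temperature optional paired [temperature_trace()]; a grid mismatch
#'   is an error.
#' @return `data.frame` with columns `start`, `end`, `n`, `sum`, `mean`.
#' @export
movement_summary <- function(movement, windows, temperature = NULL) {
  stopifnot(inherits(movement, "temperature_trace"))
  if (!is.null(temperature)) {
    stopifnot(inherits(temperature, "temperature_trace"))
    if (nrow(temperature) != nrow(movement) ||
        any(temperature$time != movement$time))
      stop("movement and temperature traces are on different time grids")
  }
  if (is.numeric(windows)) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    sel <- movement$time >= w[1] & movement$time < w[2]
    v <- movement$temp[sel]
    data.frame(start = w[1], end = w[2], n = sum(!is.na(v)),
               sum = sum(v, na.rm = TRUE), mean = mean(v, na.rm = TRUE))
  })
  do.call(rbind, rows)
}

#' Movement-count trace on the telemetry grid
#'
#' @param time minutes from start (uniform grid).
#' @param counts gross movement counts per bin (nonnegative).
#' @param ... metadata passed to [temperature_trace()].
#' @return A trace usable with [movement_summary()].
#' @export
movement_trace <- function(time, counts, ...) {
  if (any(counts[is.finite(counts)] < 0)) stop("movement counts must be >= 0")
  temperature_trace(time, counts, allow_implausible = TRUE, ...)
}
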