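#' Interleaved two-channel fiber-photometry recording
#'
#' Raw photometry stream acquired at 20 samples/s with the excitation LED
#' alternating between the 405 nm isosbestic reference and the 470 nm
#' calcium-dependent signal, so each channel is effectively sampled at
#' 10 samples/s.
#'
#' @param values fluorescence samples (a.u.) in acquisition order.
#' @param channel per-sample channel tag, `"405"` or `"470"`.
#' @param fs interleaved acquisition rate, samples/s (default 20).
#' @param start time of the first sample, seconds.
#' @return Object of class `photometry_recording`.
#' @export
photometry_recording <- function(values, channel, fs = 20, start = 0) {
  stopifnot(length(values) == length(channel), fs > 0)
  channel <- as.character(channel)
  if (length(channel) && !all(channel %in% c("405", "470")))
    stop("channel tags must be '405' or '470'")
  structure(list(values = as.numeric(values), channel = channel,
                 fs = fs, start = start),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %d interleaved samples at %g/s (%.1f min)\n",
              length(x$values), x$fs, length(x$values) / x$fs / 60))
  invisible(x)
}

#' Split an interleaved recording into its two channels
#'
#' Checks strict channel alternation (and an even total sample count), then
#' returns the 470 nm signal and 405 nm reference streams, each at half the
#' interleaved rate with timestamps at its own sample instants.
#'
#' @param rec a [photometry_recording()].
#' @return List with `signal` and `reference`, each a `data.frame(time, value)`,
#'   plus `fs` (per-channel rate).
#' @export
demux_channels <- function(rec) {
  stopifnot(inherits(rec, "photometry_recording"))
  n <- length(rec$values)
  if (n == 0L) {
    e <- data.frame(time = numeric(0), value = numeric(0))
    return(list(signal = e, reference = e, fs = rec$fs / 2))
  }
  expected <- rep(c(rec$channel[1L], setdiff(c("405", "470"), rec$channel[1L])),
                  length.out = n)
  bad <- which(rec$channel != expected)
  if (length(bad))
    stop(sprintf("channel alternation broken at sample %d (got '%s', expected '%s')",
                 bad[1L], rec$channel[bad[1L]], expected[bad[1L]]))
  if (n %% 2L != 0L)
    stop("interleaved recording has an odd number of samples")
  t_all <- rec$start + (seq_len(n) - 1L) / rec$fs
  sig <- rec$channel == "470"
  list(signal = data.frame(time = t_all[sig], value = rec$values[sig]),
       reference = data.frame(time = t_all[!sig], value = rec$values[!sig]),
       fs = rec$fs / 2)
}

#' Reference-channel artifact correction to \eqn{\Delta F/F}
#'
#' Uses the isosbestic 405 nm reference, which carries photobleaching and
#' movement artifacts but no calcium-dependent fluorescence, to estimate the
#' artifactual component of the 470 nm signal. The reference is least-squares
#' fitted to the signal (scale + offset) over the whole epoch; the fitted
#' reference is the baseline-fluorescence estimate F0 and
#' \eqn{\Delta F/F = (signal - F0)/F0} elementwise.
#'
#' @param signal 470 nm stream: `data.frame(time, value)` from
#'   [demux_channels()], or a numeric vector (then `fs` supplies the rate).
#' @param reference 405 nm stream, same length.
#' @param fs per-channel sampling rate, samples/s, when vectors are given
#'   (default 10).
#' @param min_length minimum number of samples required for a stable fit.
#' @return A `dff_trace`: `data.frame(time, dff, baseline, local_sd)` with
#'   the fit coefficients in `attr(, "fit")`. `baseline`/`local_sd` are `NA`
#'   until [rolling_baseline()] is applied.
#' @export
correct_reference <- function(signal, reference, fs = 10, min_length = 20) {
  if (is.data.frame(signal)) { time <- signal$time; sig <- signal$value }
  else { sig <- as.numeric(signal); time <- (seq_along(sig) - 1) / fs }
  ref <- if (is.data.frame(reference)) reference$value else as.numeric(reference)
  if (length(sig) != length(ref)) stop("signal and reference lengths differ")
  if (length(sig) < min_length)
    stop(sprintf("need at least %d samples for the reference fit", min_length))
  if (is.data.frame(signal) && length(time) > 1)
    fs <- 1 / stats::median(diff(time))

  if (stats::sd(ref) < 1e-12) {
    if (stats::sd(sig) >= 1e-12)
      warning("constant reference with nonconstant signal; offset-only fit")
    f0 <- rep(mean(sig), length(sig))
    fit <- c(scale = 0, offset = mean(sig))
  } else {
    m <- stats::lm(sig ~ ref)
    f0 <- as.numeric(stats::fitted(m))
    fit <- c(scale = unname(coef(m)[2]), offset = unname(coef(m)[1]))
  }
  if (any(abs(f0) < 1e-9))
    warning("fitted baseline fluorescence crosses zero; dF/F unstable")
  structure(data.frame(time = time, dff = (sig - f0) / f0,
                       baseline = NA_real_, local_sd = NA_real_),
            fs = fs, fit = fit,
            class = c("dff_trace", "data.frame"))
}

#' Construct a \eqn{\Delta F/F} trace directly
#'
#' For pre-computed \eqn{\Delta F/F} series (e.g. loaded from disk) that
#' bypass [correct_reference()].
#'
#' @param time sample times, seconds.
#' @param dff \eqn{\Delta F/F} values.
#' @param baseline,local_sd optional precomputed rolling statistics.
#' @param fs sampling rate, samples/s.
#' @return A `dff_trace`.
#' @export
dff_trace <- function(time, dff, baseline = NA_real_, local_sd = NA_real_,
                      fs = 10) {
  stopifnot(length(time) == length(dff))
  structure(data.frame(time = as.numeric(time), dff = as.numeric(dff),
                       baseline = baseline, local_sd = local_sd),
            fs = fs, class = c("dff_trace", "data.frame"))
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d samples at %g/s (%.1f min); baseline %s\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs") / 60,
              if (all(is.na(x$baseline))) "not yet computed" else "computed"))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, ...) {
  plot(x$time, x$dff, type = "l", xlab = "time (s)",
       ylab = expression(Delta * F / F), ...)
  if (!all(is.na(x$baseline)))
    graphics::lines(x$time, x$baseline, col = "red")
  invisible(x)
}

#' Sliding-percentile baseline and local standard deviation
#'
#' For each sample, the 10th percentile (by default) and standard deviation
#' of \eqn{\Delta F/F} in a centered 1-min sliding window. Percentiles use
#' linear interpolation between order statistics (the default convention of
#' [stats::quantile()]); edge windows are truncated, not padded.
#'
#' @param dff a `dff_trace` from [correct_reference()], or a numeric vector.
#' @param window window length in seconds (default 60).
#' @param percentile baseline percentile (default 10).
#' @param fs sampling rate when `dff` is a plain vector (default 10).
#' @return The `dff_trace` with `baseline` and `local_sd` columns filled
#'   (or, for vector input, a list with `baseline` and `local_sd`).
#' @export
rolling_baseline <- function(dff, window = 60, percentile = 10, fs = 10) {
  vec_in <- !inherits(dff, "dff_trace")
  x <- if (vec_in) as.numeric(dff) else dff$dff
  if (!vec_in) fs <- attr(dff, "fs")
  n <- length(x)
  w <- round(window * fs)
  if (w < 10) stop("window must span at least 10 samples")
  p <- percentile / 100
  if (w > n) {
    warning("window longer than trace; using a single global percentile")
    base <- rep(unname(stats::quantile(x, p, type = 7)), n)
    lsd <- rep(stats::sd(x), n)
  } else {
    half <- w %/% 2L
    base <- roll_quantile_cpp(x, half, p)
    lsd <- roll_sd_cpp(x, half)
  }
  if (vec_in) return(list(baseline = base, local_sd = lsd))
  dff$baseline <- base
  dff$local_sd <- lsd
  attr(dff, "baseline_window") <- window
  attr(dff, "baseline_percentile") <- percentile
  dff
}

#' Detect calcium transients above the local baseline
#'
#' A transient is a maximal excursion where \eqn{\Delta F/F} exceeds
#' `baseline + k * local_sd`. Its amplitude is the maximum of
#' \eqn{\Delta F/F - baseline} within the excursion, and its base width the
#' time between the surrounding crossings of the baseline. When consecutive
#' excursions are not separated by a return to baseline, the base edge is
#' placed at the local minimum between them.
#'
#' @param dff a `dff_trace` with `baseline` and `local_sd` computed by
#'   [rolling_baseline()].
#' @param k detection threshold in multiples of the local standard deviation
#'   (default 2).
#' @param min_gap hysteresis, in seconds: consecutive excursions separated by
#'   a below-threshold gap shorter than `min_gap` with no intermediate return
#'   to baseline are counted as one transient (default 1). This keeps noise
#'   re-crossings during a transient's slow decay from registering as new
#'   events.
#' @return `data.frame` with one row per transient: `onset`, `peak_time`,
#'   `amplitude`, `base_width`, `base_start`, `base_end`. Zero rows when no
#'   excursion crosses threshold.
#' @export
detect_transients <- function(dff, k = 2, min_gap = 1) {
  stopifnot(inherits(dff, "dff_trace"))
  if (all(is.na(dff$baseline)))
    stop("baseline not computed; run rolling_baseline() first")
  x <- dff$dff; b <- dff$baseline; s <- dff$local_sd; tm <- dff$time
  n <- length(x)
  empty <- data.frame(onset = numeric(0), peak_time = numeric(0),
                      amplitude = numeric(0), base_width = numeric(0),
                      base_start = numeric(0), base_end = numeric(0))
  above <- x > b + k * s
  runs <- rle_runs(above)
  if (nrow(runs) == 0L) return(empty)
  at_base <- x <= b

  # debounce: absorb re-crossings during a decay into the ongoing event
  if (nrow(runs) > 1L && min_gap > 0) {
    dt_gap <- tm[runs$first[-1L]] - tm[runs$last[-nrow(runs)]]
    returns <- vapply(seq_len(nrow(runs) - 1L), function(i)
      any(at_base[(runs$last[i] + 1L):(runs$first[i + 1L] - 1L)]),
      logical(1))
    new_event <- c(TRUE, dt_gap >= min_gap | returns)
    grp <- cumsum(new_event)
    runs <- data.frame(first = tapply(runs$first, grp, min),
                       last = tapply(runs$last, grp, max))
  }
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs$first[i]; i1 <- runs$last[i]
    rel <- x[i0:i1] - b[i0:i1]
    pk <- i0 + which.max(rel) - 1L
    # left base edge: nearest sample at/below baseline before the excursion,
    # clipped at the local minimum toward a preceding excursion
    lo <- i0
    floor_idx <- if (i > 1L) runs$last[i - 1L] + 1L else 1L
    while (lo > floor_idx && !at_base[lo - 1L]) lo <- lo - 1L
    if (lo > 1L && at_base[lo - 1L]) lo <- lo - 1L
    else if (i > 1L && lo == floor_idx) {
      seg <- floor_idx:i0
      lo <- seg[which.min(x[seg] - b[seg])]
    }
    hi <- i1
    ceil_idx <- if (i < nrow(runs)) runs$first[i + 1L] - 1L else n
    while (hi < ceil_idx && !at_base[hi + 1L]) hi <- hi + 1L
    if (hi < n && at_base[hi + 1L]) hi <- hi + 1L
    else if (i < nrow(runs) && hi == ceil_idx) {
      seg <- i1:ceil_idx
      hi <- seg[which.min(x[seg] - b[seg])]
    }
    data.frame(onset = tm[i0], peak_time = tm[pk],
               amplitude = x[pk] - b[pk],
               base_width = tm[hi] - tm[lo],
               base_start = tm[lo], base_end = tm[hi])
  })
  do.call(rbind, out)
}

#' Recording epoch with concurrent core temperature
#'
#' The study analysed fluorescence in 10-min recording blocks, each labelled
#' hypothermia or normothermia by the concurrent core temperature.
#'
#' @param start epoch start, seconds.
#' @param duration epoch duration, seconds (default 600).
#' @param temperature concurrent core-temperature samples (deg C), optional.
#' @param hypo_threshold hypothermia threshold, deg C (default 33; the epoch
#'   is hypothermia when its mean temperature is strictly below this).
#' @param label explicit label overriding the temperature rule.
#' @return Object of class `pm_epoch`.
#' @export
pm_epoch <- function(start, duration = 600, temperature = NULL,
                     hypo_threshold = 33, label = NULL) {
  if (is.null(label))
    label <- label_epoch_by_temperature(temperature, hypo_threshold)
  structure(list(start = start, duration = duration,
                 temperature = temperature, label = label),
            class = "pm_epoch")
}

#' Label an epoch by its concurrent core temperature
#'
#' Hypothermia when the epoch-mean core temperature is strictly below
#' `hypo_threshold` (study rule: below 33 degC), normothermia otherwise.
#' An epoch with no concurrent telemetry is left unlabeled (`NA`). The
#' stricter definition used in parts of the study (normothermia only above
#' 36 degC) is available via `normo_threshold`.
#'
#' @param temperature concurrent core-temperature samples, deg C.
#' @param hypo_threshold hypothermia cutoff, deg C (strict `<`; default 33).
#' @param normo_threshold optional normothermia cutoff, deg C; when given,
#'   epochs with mean temperature in `[hypo_threshold, normo_threshold)` are
#'   labelled `"intermediate"`.
#' @return `"hypothermia"`, `"normothermia"`, `"intermediate"` or `NA`.
#' @export
label_epoch_by_temperature <- function(temperature, hypo_threshold = 33,
                                       normo_threshold = NULL) {
  if (is.null(temperature) || !sum(is.finite(temperature)))
    return(NA_character_)
  m <- mean(temperature, na.rm = TRUE)
  if (m < hypo_threshold) return("hypothermia")
  if (!is.null(normo_threshold) && m < normo_threshold) return("intermediate")
  "normothermia"
}

# internal: trapezoidal integral
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

#' Epoch transient metrics
#'
#' The six per-epoch metrics used to quantify calcium activity: area under
#' the curve (trapezoidal integral of \eqn{\Delta F/F} above the epoch
#' minimum), variance (and SD) of \eqn{\Delta F/F}, mean of the rolling
#' baseline, mean base width and mean amplitude of detected transients, and
#' total peak area (integral above baseline between each peak's base
#' crossings).
#'
#' @param dff a `dff_trace` with the rolling baseline computed.
#' @param epoch a [pm_epoch()] (or a numeric `c(start, duration)` in s).
#' @param k transient-detection threshold passed to [detect_transients()].
#' @return One-row `data.frame` of class `transient_metrics`: `auc`,
#'   `variance`, `sd`, `baseline_mean`, `mean_peak_width`,
#'   `mean_peak_amplitude`, `total_peak_area`, `n_peaks`, `epoch_label`.
#'   Peak width/amplitude are `NA` and total area 0 when no peak is found.
#' @export
epoch_metrics <- function(dff, epoch, k = 2) {
  stopifnot(inherits(dff, "dff_trace"))
  if (is.numeric(epoch)) epoch <- pm_epoch(epoch[1], epoch[2])
  stopifnot(inherits(epoch, "pm_epoch"))
  if (all(is.na(dff$baseline)))
    stop("baseline not computed; run rolling_baseline() first")
  lo <- epoch$start; hi <- epoch$start + epoch$duration
  sel <- dff$time >= lo & dff$time < hi
  if (!any(sel)) stop("epoch lies outside the trace")
  win <- attr(dff, "baseline_window")
  if (!is.null(win) && epoch$duration < win)
    warning("epoch shorter than the baseline window")
  sub <- dff[sel, , drop = FALSE]
  class(sub) <- class(dff)
  attr(sub, "fs") <- attr(dff, "fs")

  peaks <- detect_transients(sub, k = k)
  total_area <- 0
  if (nrow(peaks)) {
    total_area <- sum(vapply(seq_len(nrow(peaks)), function(i) {
      ps <- sub$time >= peaks$base_start[i] & sub$time <= peaks$base_end[i]
      trapz(sub$time[ps], pmax(sub$dff[ps] - sub$baseline[ps], 0))
    }, numeric(1)))
  }
  structure(data.frame(
    auc = trapz(sub$time, sub$dff - min(sub$dff)),
    variance = stats::var(sub$dff),
    sd = stats::sd(sub$dff),
    baseline_mean = mean(sub$baseline),
    mean_peak_width = if (nrow(peaks)) mean(peaks$base_width) else NA_real_,
    mean_peak_amplitude = if (nrow(peaks)) mean(peaks$amplitude) else NA_real_,
    total_peak_area = total_area,
    n_peaks = nrow(peaks),
    epoch_label = if (is.null(epoch$label)) NA_character_ else epoch$label,
    stringsAsFactors = FALSE
  ), class = c("transient_metrics", "data.frame"))
}
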