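# EEG relative band power and beat-interval heart-rate summaries.

#' EEG recording container
#'
#' @param samples voltage samples (uV).
#' @param fs sampling rate, samples/s (default 200).
#' @param channel channel label.
#' @param filtered whether the acquisition band-pass (high-pass 0.5 Hz,
#'   low-pass 30 Hz) has already been applied.
#' @param filter_desc free-text description of the applied filter.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs = 200, channel = "EEG",
                          filtered = FALSE, filter_desc = NULL) {
  stopifnot(fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 filtered = filtered, filter_desc = filter_desc),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d samples at %g/s (%.1f min), %s\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs / 60,
              if (x$filtered) paste0("filtered (", x$filter_desc %||% "band-pass", ")")
              else "unfiltered"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default EEG frequency bands
#'
#' Theta is 6-10 Hz per the study; delta (0.5-4 Hz) and alpha (8-13 Hz) are
#' conventional defaults, not study values, and are configurable everywhere
#' they are used.
#'
#' @return Named list of `c(lo, hi)` intervals in Hz.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(6, 10), alpha = c(8, 13))
}

#' Zero-phase band-pass preconditioning
#'
#' Applies the acquisition chain's high-pass (0.5 Hz) and low-pass (30 Hz)
#' filtering as a zero-phase 4th-order Butterworth band-pass
#' (forward-backward, so the effective magnitude response is squared).
#'
#' @param rec an [eeg_recording()] with `filtered = FALSE`.
#' @param hp,lp high-/low-pass cutoffs, Hz.
#' @param order Butterworth order (default 4).
#' @return The filtered [eeg_recording()] with metadata updated.
#' @export
bandpass_precondition <- function(rec, hp = 0.5, lp = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$filtered) warning("recording is already marked filtered")
  if (lp >= rec$fs / 2 || hp >= rec$fs / 2)
    stop("filter cutoff at or above the Nyquist frequency")
  if (hp >= lp) stop("high-pass cutoff must be below low-pass cutoff")
  bf <- signal::butter(order, c(hp, lp) * 2 / rec$fs, type = "pass")
  # remove the DC offset first: the high-pass kills it anyway, and a large
  # offset only feeds the filter's edge transients
  filtered <- as.numeric(signal::filtfilt(bf, rec$samples - mean(rec$samples)))
  eeg_recording(filtered, fs = rec$fs, channel = rec$channel,
                filtered = TRUE,
                filter_desc = sprintf(
                  "zero-phase Butterworth order %d band-pass %g-%g Hz",
                  order, hp, lp))
}

# internal: Welch averaged periodogram. Hann-tapered segments with 50%
# overlap; returns density over [0, fs/2].
welch_psd <- function(x, fs, seg_seconds = 4, overlap = 0.5) {
  nseg <- round(seg_seconds * fs)
  n <- length(x)
  if (nseg > n) nseg <- n
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  scale <- fs * sum(w^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    X <- stats::fft((seg - mean(seg)) * w)
    pxx <- Mod(X[seq_len(nf)])^2 / scale
    if (nseg %% 2L == 0L) pxx[2:(nf - 1L)] <- 2 * pxx[2:(nf - 1L)]
    else pxx[2:nf] <- 2 * pxx[2:nf]
    acc <- acc + pxx
  }
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = acc / length(starts))
}

#' Relative EEG band power in time bins
#'
#' For each bin (5 min by default), the spectral density is estimated by an
#' averaged periodogram (Hann-tapered 4-s segments, 50% overlap), the power
#' in each named band is integrated over `[lo, hi)`, and relative power is
#' the band power divided by the total power over the full estimated range —
#' the study's normalization. Over an exhaustive disjoint band partition the
#' relative powers in a bin sum to 1.
#'
#' @param rec a filtered [eeg_recording()].
#' @param bands named list of `c(lo, hi)` intervals, Hz (default
#'   [eeg_bands()]).
#' @param bin_minutes bin length, minutes (default 5).
#' @param seg_seconds,overlap Welch estimator parameters.
#' @param exclude optional logical mask (length of the recording) of samples
#'   to exclude; bins with more than half their samples excluded are flagged
#'   (`flagged = TRUE`, powers `NA`).
#' @return `data.frame`: `bin_start` (s), `band`, `power`, `rel_power`,
#'   `flagged`.
#' @export
relative_band_power <- function(rec, bands = eeg_bands(), bin_minutes = 5,
                                seg_seconds = 4, overlap = 0.5,
                                exclude = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!rec$filtered)
    warning("recording not marked filtered; apply bandpass_precondition() first")
  for (b in bands) if (b[2] > rec$fs / 2) stop("band edge above Nyquist")
  nbin <- round(bin_minutes * 60 * rec$fs)
  n <- length(rec$samples)
  n_bins <- max(1L, floor(n / nbin))
  out <- vector("list", n_bins)
  for (i in seq_len(n_bins)) {
    idx <- ((i - 1L) * nbin + 1L):min(i * nbin, n)
    flag <- !is.null(exclude) && mean(exclude[idx]) > 0.5
    if (flag) {
      out[[i]] <- data.frame(bin_start = (idx[1L] - 1L) / rec$fs,
                             band = names(bands), power = NA_real_,
                             rel_power = NA_real_, flagged = TRUE)
      next
    }
    x <- rec$samples[idx]
    if (!is.null(exclude)) x <- x[!exclude[idx]]
    sp <- welch_psd(x, rec$fs, seg_seconds, overlap)
    df <- sp$freq[2L] - sp$freq[1L]
    total <- sum(sp$psd) * df
    bp <- vapply(bands, function(b) {
      inb <- sp$freq >= b[1] & sp$freq < b[2]
      if (b[2] >= rec$fs / 2) inb <- inb | sp$freq == b[2]  # include Nyquist
      sum(sp$psd[inb]) * df
    }, numeric(1))
    out[[i]] <- data.frame(bin_start = (idx[1L] - 1L) / rec$fs,
                           band = names(bands), power = unname(bp),
                           rel_power = unname(bp / total), flagged = FALSE)
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Beat series container
#'
#' @param beat_times strictly increasing beat times, seconds.
#' @return Object of class `beat_series` with derived RR intervals (ms).
#' @export
beat_series <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1L && any(diff(beat_times) <= 0))
    stop("beat times must be strictly increasing")
  structure(list(times = beat_times, rr_ms = diff(beat_times) * 1000),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats over %.1f s (mean RR %.1f ms)\n",
              length(x$times), diff(range(x$times)),
              mean(x$rr_ms)))
  invisible(x)
}

#' Binned heart rate from beat times
#'
#' Per bin, 60 divided by the mean inter-beat (RR) interval in seconds,
#' using the intervals between consecutive beats falling inside the bin.
#' Bins with fewer than two beats are undefined (`NA`).
#'
#' @param series a [beat_series()] or numeric beat times (s).
#' @param bin bin length, seconds (default 60).
#' @return `data.frame`: `bin_start` (s), `n_beats`, `bpm`.
#' @export
heart_rate <- function(series, bin = 60) {
  if (!inherits(series, "beat_series")) series <- beat_series(series)
  tt <- series$times
  if (!length(tt)) return(data.frame(bin_start = numeric(0),
                                     n_beats = integer(0), bpm = numeric(0)))
  edges <- seq(0, max(tt) + bin, by = bin)
  out <- lapply(seq_len(length(edges) - 1L), function(i) {
    b <- tt[tt >= edges[i] & tt < edges[i + 1L]]
    data.frame(bin_start = edges[i], n_beats = length(b),
               bpm = if (length(b) >= 2L) 60 / mean(diff(b)) else NA_real_)
  })
  do.call(rbind, out)
}

#' Detect pauses (skipped beats) in a beat series
#'
#' Flags RR intervals exceeding `factor` times the rolling median RR
#' (centered window of 11 intervals, truncated at the edges). The default
#' factor 1.8 sits below the 2.0 of a fully skipped beat to tolerate
#' interval jitter.
#'
#' @param series a [beat_series()] or numeric beat times (s).
#' @param factor multiple of the local median RR that defines a pause.
#' @param window rolling-median window, in intervals (default 11).
#' @return `data.frame` with one row per pause: `interval_index` (index of
#'   the flagged RR interval), `onset` (time of the beat before the pause,
#'   s), `rr_ms`, `local_median_ms`.
#' @export
detect_pauses <- function(series, factor = 1.8, window = 11) {
  if (!inherits(series, "beat_series")) series <- beat_series(series)
  if (length(series$times) < 10L)
    stop("need at least 10 beats for a stable local median")
  rr <- series$rr_ms
  n <- length(rr)
  half <- window %/% 2L
  med <- vapply(seq_len(n), function(i)
    stats::median(rr[max(1L, i - half):min(n, i + half)]), numeric(1))
  hit <- which(rr > factor * med)
  data.frame(interval_index = hit, onset = series$times[hit],
             rr_ms = rr[hit], local_median_ms = med[hit])
}
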