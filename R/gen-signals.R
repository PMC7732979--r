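# Synthetic generators for photometry, slice-ephys, EEG and beat series.

# internal: keep only Fourier components with lo <= |f| < hi (Hz);
# symmetric mask so the inverse transform is real
fft_bandlimit <- function(x, fs, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                # fold to [0, fs/2]
  keep <- f >= lo & f < hi
  X <- stats::fft(x)
  X[!keep] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate an interleaved two-channel photometry recording
#'
#' Emulates 20 samples/s acquisition alternating between the 405 nm
#' isosbestic reference and the 470 nm calcium signal. Both channels share a
#' multiplicative exponential photobleaching decay and an additive
#' low-frequency (< 0.5 Hz) motion artifact; only the signal channel carries
#' calcium transients (instantaneous rise, exponential decay). Transient
#' onset times follow a Poisson process whose rate depends on the scheduled
#' state; amplitudes (in \eqn{\Delta F/F} units) are drawn from a normal
#' distribution folded at zero.
#'
#' @param config a [sim_config()]; `noise_sd` is the per-channel white-noise
#'   SD in a.u.
#' @param event_rate_by_state named numeric vector of transient rates
#'   (events/min) per state label (default `c(baseline = 2)`); states absent
#'   from the vector get rate 0.
#' @param amplitude_dist `c(mean, sd)` of transient amplitudes in
#'   \eqn{\Delta F/F} (mean must be positive), or a named list of such pairs
#'   per state label to emulate state-dependent transient size (e.g. larger
#'   transients during hypothermia).
#' @param decay_tau transient decay time constant, s (> 0).
#' @param min_separation minimum spacing between transient onsets, s
#'   (default 0: pure Poisson timing). Events closer than this to their
#'   predecessor are thinned, giving temporally distinct transients for
#'   parameter-recovery experiments.
#' @param bleach_tau photobleaching time constant, s (`Inf` for none).
#' @param artifact_amplitude SD of the shared motion artifact, a.u.
#' @param f0_signal,f0_reference baseline fluorescence of each channel, a.u.
#' @param fs interleaved acquisition rate, samples/s (default 20).
#' @return List with `recording` (a [photometry_recording()]) and `truth`
#'   (list with `true_transients`: data.frame of `time`, `amplitude`, `tau`).
#' @export
gen_photometry <- function(config, event_rate_by_state = c(baseline = 2),
                           amplitude_dist = c(0.05, 0.01), decay_tau = 2,
                           min_separation = 0, bleach_tau = 1800,
                           artifact_amplitude = 1, f0_signal = 100,
                           f0_reference = 100, fs = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (decay_tau <= 0) stop("decay_tau must be positive")
  if (any(event_rate_by_state < 0)) stop("event rates must be >= 0")
  amp_for <- function(state) {
    a <- if (is.list(amplitude_dist)) {
      amplitude_dist[[state]] %||% amplitude_dist[["baseline"]]
    } else amplitude_dist
    if (is.null(a)) stop("no amplitude distribution for state ", state)
    a
  }
  amp_means <- if (is.list(amplitude_dist))
    vapply(amplitude_dist, `[`, numeric(1), 1L) else amplitude_dist[1]
  if (any(amp_means <= 0)) stop("transient amplitude mean must be positive")

  dur_s <- config$duration * 60
  n <- 2L * floor(dur_s * fs / 2)       # even interleaved count
  t_all <- (seq_len(n) - 1) / fs
  channel <- rep(c("405", "470"), length.out = n)
  bleach <- if (is.finite(bleach_tau)) exp(-t_all / bleach_tau) else rep(1, n)

  # shared low-frequency motion artifact, identical additive term
  set.seed(sub_seed(config$seed, 11L))
  if (artifact_amplitude > 0) {
    art <- fft_bandlimit(stats::rnorm(n), fs, 0.01, 0.5)
    art <- art / stats::sd(art) * artifact_amplitude
  } else art <- numeric(n)

  # state-dependent Poisson transient times + folded-normal amplitudes
  set.seed(sub_seed(config$seed, 12L))
  segs <- config$state_schedule
  # cover full duration with explicit baseline segments
  edges <- sort(unique(c(0, segs$start, segs$end, config$duration)))
  ev_time <- numeric(0); ev_amp <- numeric(0)
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    st <- state_at(config, (lo + hi) / 2)
    rate <- if (st %in% names(event_rate_by_state))
      event_rate_by_state[[st]] else 0
    k <- stats::rpois(1L, rate * (hi - lo))
    if (k > 0) {
      ad <- amp_for(st)
      ev_time <- c(ev_time, sort(stats::runif(k, lo * 60, hi * 60)))
      ev_amp <- c(ev_amp, abs(stats::rnorm(k, ad[1], ad[2])))
    }
  }

  if (min_separation > 0 && length(ev_time) > 1L) {
    keep <- rep(TRUE, length(ev_time))
    last <- ev_time[1L]
    for (j in seq_along(ev_time)[-1L]) {
      if (ev_time[j] - last < min_separation) keep[j] <- FALSE
      else last <- ev_time[j]
    }
    ev_time <- ev_time[keep]; ev_amp <- ev_amp[keep]
  }

  transient_dff <- numeric(n)
  for (j in seq_along(ev_time)) {
    idx <- t_all >= ev_time[j]
    transient_dff[idx] <- transient_dff[idx] +
      ev_amp[j] * exp(-(t_all[idx] - ev_time[j]) / decay_tau)
  }

  f0 <- ifelse(channel == "470", f0_signal, f0_reference)
  values <- f0 * bleach + art +
    ifelse(channel == "470", f0_signal * bleach * transient_dff, 0)
  set.seed(sub_seed(config$seed, 13L))
  values <- values + stats::rnorm(n, 0, config$noise_sd)

  list(recording = photometry_recording(values, channel, fs = fs),
       truth = list(true_transients = data.frame(
         time = ev_time, amplitude = ev_amp,
         tau = rep(decay_tau, length(ev_time)))))
}

#' Simulate a two-temperature firing-rate assay
#'
#' Per neuron, Poisson spike counts in 2-min bins at a 25 degC bath
#' temperature with mean `base_rate`, and at 30 degC with mean
#' `base_rate * q10^((30-25)/10)`, emulating the slice current-clamp
#' protocol used to classify temperature-responsive neurons.
#'
#' @param config a [sim_config()] (only the seed is used).
#' @param n_neurons number of neurons.
#' @param q10_dist per-neuron true Q10: a single value, a vector of length
#'   `n_neurons`, or a function of `n` returning one draw per neuron.
#' @param base_rate firing rate at the lower temperature, spikes/s (> 0).
#' @param bin_minutes bin length, minutes (default 2).
#' @param n_bins bins per temperature (default 5).
#' @param t1,t2 bath temperatures, deg C (defaults 25 and 30).
#' @param region region label attached to every neuron (default "MPN").
#' @return List with `assays` (data.frame: `neuron_id`, `region`,
#'   `temperature`, `bin`, `count`, `rate`) and `truth` (`true_q10` per
#'   neuron).
#' @export
gen_firing_assay <- function(config, n_neurons, q10_dist = 1, base_rate = 5,
                             bin_minutes = 2, n_bins = 5, t1 = 25, t2 = 30,
                             region = "MPN") {
  stopifnot(inherits(config, "sim_config"))
  if (base_rate <= 0) stop("base_rate must be positive")
  set.seed(sub_seed(config$seed, 21L))
  q10 <- if (is.function(q10_dist)) q10_dist(n_neurons)
         else rep_len(q10_dist, n_neurons)
  if (any(q10 <= 0)) stop("true q10 values must be positive")
  bin_s <- bin_minutes * 60
  rate2 <- base_rate * q10^((t2 - t1) / 10)
  rows <- lapply(seq_len(n_neurons), function(i) {
    c1 <- stats::rpois(n_bins, base_rate * bin_s)
    c2 <- stats::rpois(n_bins, rate2[i] * bin_s)
    data.frame(neuron_id = sprintf("n%03d", i), region = region,
               temperature = rep(c(t1, t2), each = n_bins),
               bin = rep(seq_len(n_bins), 2L),
               count = c(c1, c2), rate = c(c1, c2) / bin_s)
  })
  list(assays = do.call(rbind, rows),
       truth = list(true_q10 = stats::setNames(q10,
                      sprintf("n%03d", seq_len(n_neurons)))))
}

#' Simulate a band-structured EEG voltage trace
#'
#' Sum of band-limited Gaussian noise components, each scaled so its
#' variance (power) matches the per-state target, concatenated segment by
#' segment along the state schedule. Sampled at 200 samples/s as in the
#' polysomnography acquisition.
#'
#' @param config a [sim_config()]; `noise_sd` adds broadband measurement
#'   noise on top of the band components (0 for none).
#' @param band_power_by_state named list: per state label, a named numeric
#'   vector of target powers (uV^2) per band. States absent from the list
#'   fall back to `"baseline"`.
#' @param bands named list of `c(lo, hi)` frequency intervals in Hz
#'   (defaults delta 0.5-4, theta 6-10, alpha 8-13 are available via
#'   [eeg_bands()]).
#' @param fs sampling rate, samples/s (default 200).
#' @return List with `recording` (an [eeg_recording()]) and `truth`
#'   (`true_band_powers`: per-state target vectors).
#' @export
gen_eeg <- function(config, band_power_by_state, bands = eeg_bands(),
                    fs = 200) {
  stopifnot(inherits(config, "sim_config"), is.list(band_power_by_state))
  for (b in bands) {
    if (b[2] > fs / 2)
      stop("band edge above the Nyquist frequency")
    if (any(unlist(band_power_by_state) < 0))
      stop("band power targets must be nonnegative")
  }
  segs <- config$state_schedule
  edges <- sort(unique(c(0, segs$start, segs$end, config$duration)))
  samples <- numeric(0)
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    st <- state_at(config, (lo + hi) / 2)
    targets <- band_power_by_state[[st]]
    if (is.null(targets)) targets <- band_power_by_state[["baseline"]]
    if (is.null(targets)) stop("no band-power targets for state ", st)
    n <- round((hi - lo) * 60 * fs)
    seg <- numeric(n)
    set.seed(sub_seed(config$seed, 30L + i))
    for (bn in names(targets)) {
      if (targets[[bn]] <= 0) next
      if (is.null(bands[[bn]])) stop("unknown band ", bn)
      comp <- fft_bandlimit(stats::rnorm(n), fs, bands[[bn]][1], bands[[bn]][2])
      seg <- seg + comp / stats::sd(comp) * sqrt(targets[[bn]])
    }
    if (config$noise_sd > 0)
      seg <- seg + stats::rnorm(n, 0, config$noise_sd)
    samples <- c(samples, seg)
  }
  list(recording = eeg_recording(samples, fs = fs, filtered = TRUE),
       truth = list(true_band_powers = band_power_by_state, bands = bands))
}

#' Simulate a beat-time series with occasional skipped beats
#'
#' Inter-beat intervals are jittered around `60/rate_bpm`; each internal
#' beat is then deleted with probability `pause_prob`, doubling the local
#' interval — the signature of a skipped heartbeat under enhanced vagal
#' tone.
#'
#' @param config a [sim_config()] (duration in minutes, seed).
#' @param rate_bpm mean heart rate, beats/min (> 0; study baselines were
#'   about 776 bpm in normothermia and 401 bpm in torpor).
#' @param pause_prob per-beat deletion probability in `[0, 0.5)`.
#' @param jitter fractional SD of inter-beat intervals (default 0.03).
#' @return List with `beats` (vector of beat times, s) and `truth`
#'   (`true_pauses`: times of deleted beats, and `pause_after`: index into
#'   the returned beat vector of the beat preceding each deletion).
#' @export
gen_beats <- function(config, rate_bpm = 600, pause_prob = 0,
                      jitter = 0.03) {
  stopifnot(inherits(config, "sim_config"))
  if (rate_bpm <= 0) stop("rate_bpm must be positive")
  if (pause_prob < 0 || pause_prob >= 0.5)
    stop("pause_prob must be in [0, 0.5)")
  dur_s <- config$duration * 60
  rr <- 60 / rate_bpm
  n <- ceiling(dur_s / rr) + 10L
  set.seed(sub_seed(config$seed, 41L))
  ibi <- rr * pmax(1 + stats::rnorm(n, 0, jitter), 0.1)
  beats <- cumsum(ibi)
  beats <- beats[beats <= dur_s]
  set.seed(sub_seed(config$seed, 42L))
  m <- length(beats)
  del <- which(stats::runif(m) < pause_prob)
  del <- del[del > 1L & del < m]          # keep first and last beats
  if (length(del) > 1L)                   # no back-to-back deletions
    del <- del[!c(FALSE, diff(del) == 1L)]
  kept <- if (length(del)) beats[-del] else beats
  pause_after <- if (length(del)) match(beats[del - 1L], kept) else integer(0)
  list(beats = kept,
       truth = list(true_pauses = beats[del], pause_after = pause_after))
}
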