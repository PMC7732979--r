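#' Simulate a core-temperature telemetry trace with torpor bouts
#'
#' Generates a circadian core-temperature rhythm sampled every
#' `config$sampling_interval` minutes (default 5, as for implanted probes)
#' with fasting-induced hypothermic bouts during intervals of the state
#' schedule labelled `"torpor"`. The noiseless temperature relaxes with
#' first-order kinetics toward (circadian baseline - `bout_depth`) during a
#' bout and back to baseline afterwards; with the default rate constants an
#' 8 degC bout crosses 31 degC well within an hour of onset. Gaussian noise
#' (`config$noise_sd`) is added on an independent sub-stream, so the ground
#' truth (intervals where the noiseless trace is at or below `threshold`)
#' does not depend on the noise draw.
#'
#' @param config a [sim_config()]; bout intervals come from its schedule.
#' @param circadian_mean mean core temperature, deg C (default 37).
#' @param circadian_amplitude half peak-to-trough circadian amplitude, deg C
#'   (default 1; trough mid-light for a nocturnal animal).
#' @param bout_depth bout depth below the circadian baseline, deg C (> 0
#'   whenever bouts are scheduled).
#' @param entry_rate,exit_rate first-order relaxation rate constants
#'   (1/min) for bout entry and recovery (defaults 0.1).
#' @param threshold bout threshold (deg C) used to record ground truth
#'   (default 31).
#' @param clock_offset clock time of the first sample (default "10:00",
#'   when food was removed in the fasting protocol).
#' @param subject_id label for the generated trace.
#' @return List with `trace` (a [temperature_trace()]) and `truth` (list with
#'   `true_bouts`, a data.frame of half-open bout intervals on the noiseless
#'   trace, and `noiseless`, the underlying temperature).
#' @examples
#' cfg <- sim_config(1, duration = 2880, state_schedule =
#'   data.frame(start = c(600, 1800), end = c(900, 2100), state = "torpor"))
#' sim <- gen_core_temperature(cfg)
#' nrow(sim$truth$true_bouts)
#' @export
gen_core_temperature <- function(config, circadian_mean = 37,
                                 circadian_amplitude = 1, bout_depth = 8,
                                 entry_rate = 0.1, exit_rate = 0.1,
                                 threshold = 31, clock_offset = "10:00",
                                 subject_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (entry_rate <= 0 || exit_rate <= 0)
    stop("entry_rate and exit_rate must be positive")
  sched <- config$state_schedule
  in_torpor_sched <- nrow(sched) && any(sched$state == "torpor")
  if (in_torpor_sched && bout_depth <= 0)
    stop("bout_depth must be positive when torpor bouts are scheduled")

  dt <- config$sampling_interval
  time <- seq(0, config$duration - dt, by = dt)
  # circadian baseline: trough 6 h after lights-on for a nocturnal animal
  clock <- (parse_clock(clock_offset) + time) %% 1440
  baseline <- circadian_mean -
    circadian_amplitude * cos(2 * pi * (clock - 780) / 1440)

  torpor <- state_at(config, time) == "torpor"
  target <- baseline - ifelse(torpor, bout_depth, 0)
  temp0 <- numeric(length(time))
  temp0[1] <- baseline[1]
  for (i in seq_along(time)[-1]) {
    k <- if (torpor[i]) entry_rate else exit_rate
    temp0[i] <- target[i] + (temp0[i - 1] - target[i]) * exp(-k * dt)
  }

  set.seed(sub_seed(config$seed, 1L))
  temp <- temp0 + stats::rnorm(length(time), 0, config$noise_sd)

  below <- temp0 <= threshold
  runs <- rle_runs(below)
  true_bouts <- data.frame(start = time[runs$first],
                           end = time[runs$last] + dt)
  true_bouts$duration <- true_bouts$end - true_bouts$start

  trace <- temperature_trace(time, temp, subject_id = subject_id,
                             clock_offset = clock_offset, interval = dt,
                             allow_implausible = TRUE)
  list(trace = trace,
       truth = list(true_bouts = true_bouts, noiseless = temp0,
                    threshold = threshold))
}
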