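#' Simulation configuration
#'
#' Shared configuration object for the synthetic-data generators. A given
#' `sim_config` (including its seed) always yields bitwise-identical output
#' from every generator.
#'
#' @param seed integer seed for the generator's pseudo-random streams. Each
#'   generator splits this seed deterministically per signal component, so
#'   adding one component does not perturb the others.
#' @param duration total duration in minutes.
#' @param sampling_interval sampling interval in minutes for telemetry-style
#'   series (default 5, matching implanted-probe exports). Signal generators
#'   (photometry, EEG) carry their own samples-per-second rates and ignore
#'   this field.
#' @param state_schedule `data.frame` with columns `start`, `end` (minutes)
#'   and `state` (label). Intervals must be non-overlapping and lie within
#'   `[0, duration]`. Time outside any interval is in the implicit
#'   `"baseline"` state.
#' @param noise_sd additive Gaussian noise standard deviation, in the native
#'   units of the generated signal.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, duration = 4320,
#'                   state_schedule = data.frame(start = 600, end = 900,
#'                                               state = "torpor"))
#' @export
sim_config <- function(seed, duration, sampling_interval = 5,
                       state_schedule = NULL, noise_sd = 0.1) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(duration), duration > 0,
            is.numeric(sampling_interval), sampling_interval > 0,
            is.numeric(noise_sd), noise_sd >= 0)
  if (is.null(state_schedule)) {
    state_schedule <- data.frame(start = numeric(0), end = numeric(0),
                                 state = character(0))
  }
  if (!all(c("start", "end", "state") %in% names(state_schedule)))
    stop("state_schedule needs columns start, end, state")
  sched <- state_schedule[order(state_schedule$start), , drop = FALSE]
  if (nrow(sched)) {
    if (any(sched$start < 0) || any(sched$end > duration))
      stop("state_schedule intervals must lie within [0, duration]")
    if (any(sched$end <= sched$start))
      stop("state_schedule intervals must have end > start")
    if (nrow(sched) > 1L &&
        any(sched$start[-1L] < sched$end[-nrow(sched)]))
      stop("state_schedule intervals overlap")
  }
  structure(list(seed = as.integer(seed), duration = duration,
                 sampling_interval = sampling_interval,
                 state_schedule = sched, noise_sd = noise_sd),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "| duration", x$duration, "min |",
      nrow(x$state_schedule), "scheduled state interval(s)\n")
  invisible(x)
}

# internal: state label at given times (minutes)
state_at <- function(config, time) {
  st <- rep("baseline", length(time))
  sched <- config$state_schedule
  if (nrow(sched)) {
    for (i in seq_len(nrow(sched))) {
      st[time >= sched$start[i] & time < sched$end[i]] <- sched$state[i]
    }
  }
  st
}
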