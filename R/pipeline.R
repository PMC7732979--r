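# Declarative multi-stage runner: simulate -> analyze -> summarize.

#' Run a declarative analysis pipeline
#'
#' Executes the stages of a run configuration in order, writing tidy CSV
#' result tables, a machine-readable JSON manifest (package version,
#' parameters, seeds, output files) and a plain-text log to the output
#' directory. Reruns with the same configuration produce byte-identical
#' result tables. Unknown configuration keys are rejected by name; a stage
#' whose input is neither an earlier stage nor an existing file fails fast.
#'
#' Supported stage `op`s:
#' \describe{
#'   \item{`simulate_core_temperature`}{params: `duration` (min, required),
#'     `sampling_interval`, `noise_sd`, `bouts` (list of `c(start, end)`
#'     minutes), plus any [gen_core_temperature()] argument. Writes
#'     `<name>_trace.csv` and `<name>_truth.json`.}
#'   \item{`score_torpor`}{`input`: name of an earlier simulate stage or a
#'     CSV path; params: `threshold`, `min_duration`, `merge_gap`, and
#'     optional `baseline_minutes` (length of the leading segment used as
#'     the pre-fast baseline for [summarize_torpor()]). Writes
#'     `<name>_bouts.csv` (and `<name>_summary.csv` when a baseline is
#'     given).}
#' }
#'
#' @param config a named list, or the path of a YAML file with top-level
#'   keys `seed`, `out_dir`, `stages` and optional `log_level`.
#' @return Invisibly, a list with `results` (per-stage R objects), `files`
#'   (written paths) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "log_level", "stages")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  if (is.null(config$stages) || !length(config$stages))
    stop("config must list at least one stage")
  seed <- config$seed %||% 1L
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  files <- character(0)
  log <- c(sprintf("thermotrace pipeline (package %s)",
                   as.character(utils::packageVersion("thermotrace"))),
           sprintf("seed: %d | stages: %d", seed, length(config$stages)))

  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    bad <- setdiff(names(st), c("name", "op", "params", "input"))
    if (length(bad))
      stop("unknown stage key(s): ", paste(bad, collapse = ", "))
    if (is.null(st$op)) stop("stage ", i, " has no op")
    name <- st$name %||% paste0("stage", i)
    params <- st$params %||% list()
    log <- c(log, sprintf("[%s] op=%s params={%s}", name, st$op,
                          paste(names(params), unlist(params),
                                sep = "=", collapse = ", ")))

    if (st$op == "simulate_core_temperature") {
      allowed <- c("duration", "sampling_interval", "noise_sd", "bouts",
                   "circadian_mean", "circadian_amplitude", "bout_depth",
                   "entry_rate", "exit_rate", "threshold", "clock_offset",
                   "subject_id")
      bad <- setdiff(names(params), allowed)
      if (length(bad)) stop("unknown param(s): ", paste(bad, collapse = ", "))
      if (is.null(params$duration)) stop("simulate stage needs a duration")
      sched <- NULL
      if (!is.null(params$bouts)) {
        m <- do.call(rbind, lapply(params$bouts, as.numeric))
        sched <- data.frame(start = m[, 1], end = m[, 2], state = "torpor")
      }
      cfg <- sim_config(seed, params$duration,
                        sampling_interval = params$sampling_interval %||% 5,
                        state_schedule = sched,
                        noise_sd = params$noise_sd %||% 0.1)
      gen_args <- params[intersect(names(params),
                                   names(formals(gen_core_temperature)))]
      sim <- do.call(gen_core_temperature, c(list(config = cfg), gen_args))
      f1 <- file.path(config$out_dir, paste0(name, "_trace.csv"))
      f2 <- file.path(config$out_dir, paste0(name, "_truth.json"))
      write_timeseries_csv(sim$trace, f1)
      write_ground_truth(sim$truth["true_bouts"], f2)
      files <- c(files, f1, f2)
      results[[name]] <- sim

    } else if (st$op == "score_torpor") {
      allowed <- c("threshold", "min_duration", "merge_gap", "baseline_minutes")
      bad <- setdiff(names(params), allowed)
      if (length(bad)) stop("unknown param(s): ", paste(bad, collapse = ", "))
      if (is.null(st$input)) stop("score_torpor stage needs an input")
      trace <- if (st$input %in% names(results)) {
        results[[st$input]]$trace
      } else if (file.exists(st$input)) {
        read_timeseries_csv(st$input)
      } else stop("unmet dependency for stage '", name, "': ", st$input)
      thr <- params$threshold %||% 31
      bouts <- detect_bouts(trace, threshold = thr,
                            min_duration = params$min_duration %||% 0,
                            merge_gap = params$merge_gap %||% 0)
      f1 <- file.path(config$out_dir, paste0(name, "_bouts.csv"))
      write_bouts_csv(bouts, f1, subject = attr(trace, "subject_id"))
      files <- c(files, f1)
      results[[name]] <- list(bouts = bouts)
      if (!is.null(params$baseline_minutes)) {
        sel <- trace$time < params$baseline_minutes
        base <- temperature_trace(trace$time[sel], trace$temp[sel],
                                  interval = attr(trace, "interval"),
                                  allow_implausible = TRUE)
        rest <- temperature_trace(trace$time[!sel], trace$temp[!sel],
                                  interval = attr(trace, "interval"),
                                  allow_implausible = TRUE)
        summ <- summarize_torpor(rest, base, threshold = thr)
        f2 <- file.path(config$out_dir, paste0(name, "_summary.csv"))
        write_torpor_summary_csv(summ, f2)
        files <- c(files, f2)
        results[[name]]$summary <- summ
      }

    } else stop("unknown stage op: ", st$op)
  }

  manifest <- list(package = "thermotrace",
                   version = as.character(utils::packageVersion("thermotrace")),
                   seed = seed, config = config, files = basename(files))
  fm <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(list(results = results, files = c(files, fm), out_dir = config$out_dir))
}
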