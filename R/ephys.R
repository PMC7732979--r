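# Q10 thermosensitivity classification of neurons from firing rates at two
# bath temperatures.

#' Mean firing rate from binned spike times
#'
#' Spike times within a recording segment are counted in consecutive bins
#' (2 min by default, matching the slice protocol) and the per-bin rates are
#' averaged. A trailing partial bin is discarded; a segment shorter than one
#' bin yields a single partial-bin rate with a warning.
#'
#' @param spike_times spike times in seconds.
#' @param segment `c(start, end)` of the constant-temperature segment, s.
#' @param bin_minutes bin length in minutes (default 2).
#' @return List with `mean_rate` (spikes/s), `bin_rates`, and `n_bins`.
#' @export
binned_rates <- function(spike_times, segment, bin_minutes = 2) {
  stopifnot(length(segment) == 2L, segment[2] > segment[1])
  bin_s <- bin_minutes * 60
  len <- segment[2] - segment[1]
  if (len < bin_s) {
    warning("segment shorter than one bin; returning a single partial-bin rate")
    k <- sum(spike_times >= segment[1] & spike_times < segment[2])
    return(list(mean_rate = k / len, bin_rates = k / len, n_bins = 1L))
  }
  n_bins <- floor(len / bin_s)
  edges <- segment[1] + (0:n_bins) * bin_s
  counts <- vapply(seq_len(n_bins), function(i)
    sum(spike_times >= edges[i] & spike_times < edges[i + 1L]), numeric(1))
  rates <- counts / bin_s
  list(mean_rate = mean(rates), bin_rates = rates, n_bins = n_bins)
}

#' Temperature coefficient Q10
#'
#' `q10 = (rate2/rate1)^(10/(t2 - t1))`: the factor by which the firing rate
#' would change over a 10 degC increase. For the study's 25 to 30 degC step
#' this is the squared rate ratio. A silent neuron that starts firing
#' (`rate1 = 0`, `rate2 > 0`) has infinite Q10 (returned as `Inf`); two
#' silent measurements are undefined (`NA`).
#'
#' @param rate1,rate2 mean firing rates at `t1` and `t2`, spikes/s.
#' @param t1,t2 bath temperatures, deg C (defaults 25 and 30).
#' @return Dimensionless Q10 (vectorized).
#' @examples
#' q10(2, 4)  # doubling over 5 degC -> 4
#' @export
q10 <- function(rate1, rate2, t1 = 25, t2 = 30) {
  if (t2 == t1) stop("t1 and t2 must differ")
  out <- (rate2 / rate1)^(10 / (t2 - t1))
  out[rate1 == 0 & rate2 > 0] <- Inf
  out[rate1 == 0 & rate2 == 0] <- NA_real_
  out
}

#' Percent increase equivalent to a Q10 cutoff
#'
#' The percent change in firing rate over a temperature step `dt` that
#' corresponds to a given Q10: `100 * (q10^(dt/10) - 1)`. For Q10 = 2 and a
#' 5 degC step this is 41.4% — the study's cutoff for temperature
#' responsiveness.
#'
#' @param q10 temperature coefficient (default 2).
#' @param dt temperature step, deg C (default 5).
#' @return Percent change.
#' @examples
#' q10_cutoff_percent()  # 41.42136
#' @export
q10_cutoff_percent <- function(q10 = 2, dt = 5) 100 * (q10^(dt / 10) - 1)

#' Classify a neuron as temperature-responsive (TR) or not (NR)
#'
#' TR when the percent increase in firing rate from `t1` to `t2` strictly
#' exceeds the cutoff. The default cutoff is exactly
#' `100 * (2^(5/10) - 1)` = 41.42% — the percent change corresponding to
#' Q10 = 2 over a 5 degC step — so the percent rule and `q10 > 2` agree.
#' (The alternative "more than 50%" cutoff can be requested explicitly.)
#' A silent neuron that starts firing is TR by convention (any increase from
#' zero exceeds any percent cutoff); a neuron silent at both temperatures is
#' `"undefined"`.
#'
#' @param rate1,rate2 mean firing rates at the two temperatures, spikes/s.
#' @param cutoff_percent classification cutoff, percent (default
#'   `q10_cutoff_percent(2, t2 - t1)`).
#' @param t1,t2 bath temperatures, deg C.
#' @return Character vector: `"TR"`, `"NR"` or `"undefined"`.
#' @export
classify_response <- function(rate1, rate2, cutoff_percent = NULL,
                              t1 = 25, t2 = 30) {
  if (is.null(cutoff_percent)) cutoff_percent <- q10_cutoff_percent(2, t2 - t1)
  pc <- 100 * (rate2 - rate1) / rate1
  lab <- ifelse(pc > cutoff_percent, "TR", "NR")
  lab[rate1 == 0 & rate2 > 0] <- "TR"
  lab[rate1 == 0 & rate2 == 0] <- "undefined"
  lab
}

#' Score a two-temperature firing assay
#'
#' Computes per-neuron mean rates, percent change, Q10 and TR/NR label from
#' a long-format assay table (as produced by [gen_firing_assay()] or read
#' from CSV with columns `neuron_id`, `region`, `temperature`, and `rate` or
#' `count` per bin).
#'
#' @param assays assay `data.frame`.
#' @param bin_minutes bin length in minutes when only `count` is present.
#' @param cutoff_percent passed to [classify_response()].
#' @return `data.frame` with one row per neuron: `neuron_id`, `region`,
#'   `mean_rate_t1`, `mean_rate_t2`, `percent_change`, `q10`, `label`.
#' @export
score_thermoresponse <- function(assays, bin_minutes = 2,
                                 cutoff_percent = NULL) {
  stopifnot(all(c("neuron_id", "temperature") %in% names(assays)))
  if (!"rate" %in% names(assays)) {
    if (!"count" %in% names(assays)) stop("need a 'rate' or 'count' column")
    assays$rate <- assays$count / (bin_minutes * 60)
  }
  if (!"region" %in% names(assays)) assays$region <- "unspecified"
  temps <- sort(unique(assays$temperature))
  if (length(temps) != 2L) stop("assay table must contain exactly two temperatures")
  out <- lapply(split(assays, assays$neuron_id), function(d) {
    r1 <- mean(d$rate[d$temperature == temps[1]])
    r2 <- mean(d$rate[d$temperature == temps[2]])
    data.frame(neuron_id = d$neuron_id[1L], region = d$region[1L],
               mean_rate_t1 = r1, mean_rate_t2 = r2,
               percent_change = 100 * (r2 - r1) / r1,
               q10 = q10(r1, r2, temps[1], temps[2]),
               label = classify_response(r1, r2, cutoff_percent,
                                         temps[1], temps[2]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Region-level TR percentages and pooled summary
#'
#' Per-region counts and TR percentages, plus a pooled percentage over a
#' region set computed from summed counts (never by averaging percentages).
#' Neurons labelled `"undefined"` are excluded from the denominators.
#'
#' @param results `data.frame` from [score_thermoresponse()] (needs columns
#'   `region` and `label`).
#' @param pool regions to pool over (default: all regions present).
#' @return List with `per_region` (`data.frame`: `region`, `n`, `n_tr`,
#'   `percent_tr`) and `pooled` (`n`, `n_tr`, `percent_tr`). Percentages are
#'   exact; round to 1 decimal for display.
#' @examples
#' res <- data.frame(region = rep(c("MPN", "rostral MPA"), c(73, 35)),
#'                   label = c(rep(c("TR", "NR"), c(41, 32)),
#'                             rep(c("TR", "NR"), c(20, 15))))
#' region_summary(res)$pooled$percent_tr  # 56.48... -> prints as 56.5
#' @export
region_summary <- function(results, pool = NULL) {
  stopifnot(all(c("region", "label") %in% names(results)))
  res <- results[results$label != "undefined", , drop = FALSE]
  if (!nrow(res)) stop("no classified neurons")
  per <- do.call(rbind, lapply(split(res, res$region), function(d)
    data.frame(region = d$region[1L], n = nrow(d),
               n_tr = sum(d$label == "TR"),
               percent_tr = 100 * sum(d$label == "TR") / nrow(d),
               stringsAsFactors = FALSE)))
  row.names(per) <- NULL
  if (is.null(pool)) pool <- per$region
  sel <- per$region %in% pool
  if (!any(sel)) stop("empty region set")
  n <- sum(per$n[sel]); n_tr <- sum(per$n_tr[sel])
  list(per_region = per,
       pooled = list(regions = per$region[sel], n = n, n_tr = n_tr,
                     percent_tr = 100 * n_tr / n))
}
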