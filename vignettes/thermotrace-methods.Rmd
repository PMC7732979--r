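---
title: "Methods and design notes for thermotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for thermotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`thermotrace` packages the computations used to quantify fasting-induced
torpor and the activity of thermoregulatory preoptic neurons: torpor-bout
scoring from core-temperature telemetry, heat-loss and calorimetry
derivations, a fiber-photometry ΔF/F pipeline, Q10-based thermosensitivity
classification, EEG relative band power and beat-interval heart-rate
summaries. This vignette records the models behind each stage, the
parameters that matter, the numerical conventions, and what the synthetic
generators do and do not emulate.

## Torpor scoring from telemetry

A `temperature_trace` is a uniformly sampled series (default 5-min interval)
of core temperature in °C. Missing samples are explicit `NA`s and are never
interpolated: inventing sub-threshold temperatures would invent hypothermia,
so missing data *break* bouts — a conservative choice.

`detect_bouts()` defines a bout as a maximal run of samples with temperature
at or below the threshold (default 31 °C, inclusive, since the defining
criterion is "equal to or below"). Each run is reported as the half-open,
sample-aligned interval `[first sample, last sample + interval)`, so duration
is always `n_samples × interval` and a single sub-threshold sample is a 5-min
bout. Two post-processing knobs default to off because the scoring rule
itself states no values for them:

* `merge_gap` (min, default 0) — bridge brief supra-threshold excursions
  between runs. With 0, the raw runs are reported.
* `min_duration` (min, default 0) — discard merged runs shorter than this.

With both at 0 the invariant `Σ durations = (samples ≤ threshold) × interval`
holds exactly, and the implementation is tested for equality against a
one-pass brute-force scan on thousands of random traces.

`summarize_torpor()` reports the six per-animal statistics: Δ*T*core (lowest
core temperature minus the mean of a caller-supplied pre-fast baseline
segment), the *sample* variance of *T*core (n−1 denominator; the convention
is unstated upstream, so the unbiased estimator is used), total time at or
below threshold, bout count, longest bout, and lowest *T*core. Light/dark
means assign samples by clock time with the half-open light period
`[lights_on, lights_off)`, default 7:00–19:00. Injection-window means use
half-open windows relative to the injection time, default (−120, 0) and
(120, 180) min.

## Heat loss index and calorimetry

`heat_loss_index()` computes
`HLI = (Tskin − Tambient) / (Tcore − Tambient)`, ~0 under full
vasoconstriction and ~1 when the skin reaches core temperature. The index is
returned as `NA` (an undefined marker, not an error) when
`|Tcore − Tambient| < epsilon`; `epsilon` defaults to 0.1 °C, roughly the
resolution of the loggers such studies use. Values above 1 (skin warmer than
core, possible under rapid core cooling) are *not* clamped — clamping is a
modelling assumption the formula does not contain — but they do raise a
warning.

Thermal-image ROIs (circle over interscapular brown adipose tissue, line
segment along the tail) average the pixels whose *centers* fall inside the
ROI. Pixel-center membership is the simplest reproducible rule for a
procedure originally performed interactively in vendor software; ROI
coordinates are user input because the anatomical landmarks cannot be
inferred from a temperature matrix. RER is VCO₂/VO₂; lean-mass normalization
is elementwise division. Heat (kcal/h) is accepted as an input column — the
acquisition software computes it internally — and `lusk_heat()` offers the
classical Lusk calorific equivalent `(3.815 + 1.232·RER)·VO2` only as a
clearly labelled convenience, not as a reproduction of any vendor formula.

## Fiber photometry

Acquisition interleaves a 405 nm isosbestic reference and the 470 nm calcium
signal at 20 samples/s, giving two 10 samples/s channels.
`demux_channels()` enforces strict tag alternation (any violation is an
error naming the first offending sample) because silent resynchronisation
would corrupt every downstream quantity.

**Reference correction.** The reference carries bleaching and motion
artifacts but no calcium-dependent fluorescence. `correct_reference()` fits
the reference to the signal by ordinary least squares (scale + offset) over
the whole epoch, takes the fitted series as the baseline fluorescence F₀ and
forms `ΔF/F = (signal − F0)/F0` elementwise. A single time-invariant fit is
the simplest model consistent with "use the reference to remove shared
artifacts", is exactly invariant to rescaling both channels by a common
constant, and is testable: when the signal is an affine function of the
reference, ΔF/F is zero to machine precision. A constant reference with a
nonconstant signal degrades to an offset-only fit with a warning. Because
the fit minimises the whole-epoch residual, ΔF/F is centred near zero;
transient amplitudes are therefore always measured relative to the rolling
baseline, never to zero.

**Rolling baseline.** `rolling_baseline()` computes, for every sample, the
10th percentile and the standard deviation of ΔF/F in a centred 1-min
window. Percentiles interpolate linearly between order statistics (the
default type-7 convention of `stats::quantile`); edge windows are truncated,
not padded, so the baseline is defined at every sample. The kernel is
implemented in C++ and reproduces the type-7 arithmetic expression for
expression, so tests can require bit-identical agreement with a brute-force
R oracle. A window longer than the trace degrades to a single global
percentile with a warning; a window under 10 samples is an error.

**Transient detection.** A transient is a maximal excursion of ΔF/F above
`baseline + k·local_sd`; its amplitude is the maximum of ΔF/F − baseline in
the excursion and its base width the time between the surrounding baseline
crossings (when two excursions are not separated by a return to baseline,
the edge sits at the local minimum between them). Two numerical choices
matter in practice:

* `min_gap` (s, default 1): during a slow decay the trace hovers at the
  threshold and noise re-crosses it several times; excursions separated by a
  below-threshold gap shorter than `min_gap` with no intermediate return to
  baseline are counted as one transient. Without this hysteresis every large
  event spawns a handful of spurious "detections" in its tail.
* `k` (default 2): because the baseline is a 10th percentile (≈1.28 SD below
  the mean for Gaussian noise), `baseline + 2·SD` sits only ~0.7 SD above
  the mean, which is permissive. The default mirrors the two local
  statistics the pipeline already computes; for sparse-event recovery with
  near-zero false positives the package's own tests use `k = 5`, where a
  Gaussian-noise crossing is a ~10⁻⁴-per-sample event.

Worth knowing: the local SD includes the transients themselves. One event of
amplitude *a* and decay τ in a window *W* inflates the SD by roughly
`a·sqrt(τ/(2W))` (≈0.13·*a* for τ = 2 s, W = 60 s), so a cluster of three
large events inside one window can push the k = 5 threshold above any
amplitude — temporally clustered events are fundamentally harder for this
family of detectors, which is why the generator offers a `min_separation`
option for well-posed recovery experiments.

**Epoch metrics.** `epoch_metrics()` evaluates a 10-min epoch (the study's
recording block) and returns: AUC (trapezoidal integral of ΔF/F above the
epoch minimum — this reference makes AUC nonnegative and shift-invariant,
since no AUC baseline is defined upstream), variance *and* SD of ΔF/F (the
upstream wording conflates the two, so both are reported), the mean rolling
baseline, mean base width and mean amplitude of detected peaks (`NA` when
there are none), and total peak area (per-peak integral above baseline
between base crossings; 0 when there are none). Epochs are labelled
hypothermia when their mean concurrent core temperature is strictly below
33 °C; because a stricter normothermia definition (>36 °C) also appears in
this literature, `label_epoch_by_temperature()` accepts an optional
`normo_threshold` that labels the band between the two cutoffs
"intermediate" rather than guessing which rule produced a given figure.

## Q10 classification

`q10()` is `(rate2/rate1)^(10/(t2 − t1))`; for the 25→30 °C protocol this is
the squared rate ratio. A silent neuron that starts firing has infinite Q10
(returned as `Inf` and classified TR — any increase from zero exceeds any
percent cutoff); a neuron silent at both temperatures is undefined. The TR
cutoff is *strictly greater than* `100·(2^(1/2) − 1)` ≈ 41.42% — the percent
change exactly equivalent to Q10 = 2 over 5 °C — stored at full precision so
the percent-change rule and `q10 > 2` agree everywhere, including within a
hair of the boundary. (A hand-rounded 41.4 would disagree with Q10 > 2 for
rate ratios between 1.4140 and 1.41421.) The alternative "more than 50%"
convention that also circulates for this protocol is available as
`cutoff_percent = 50`; 41.4% is the default because it is the mathematically
consistent Q10 = 2 boundary. Region summaries pool TR percentages from
summed counts, never by averaging per-region percentages, so the pooled
value always lies between the per-region extremes.

## EEG band power and beat series

EEG preconditioning applies the acquisition chain's 0.5 Hz high-pass and
30 Hz low-pass as one zero-phase 4th-order Butterworth band-pass
(forward–backward, so the magnitude response is squared; ≥20 dB at 50 Hz).
The mean is subtracted first — the high-pass removes it anyway, and the
plain forward–backward filter otherwise turns a DC offset into large edge
transients.

`relative_band_power()` estimates each 5-min bin's spectrum by an averaged
periodogram with Hann-tapered 4-s segments at 50% overlap (0.25 Hz
resolution, enough to separate the 4 Hz and 6 Hz band edges; the upstream
description says only that an FFT was used, so these are package defaults,
exposed as arguments). Band power integrates the density over `[lo, hi)`;
a band ending at the Nyquist frequency includes the Nyquist bin so that a
disjoint exhaustive partition sums exactly to the total, and relative powers
over such a partition sum to 1 ± 10⁻⁶ in every bin. Only theta (6–10 Hz) is
fixed by the study; delta 0.5–4 Hz and alpha 8–13 Hz are conventional
defaults and configurable. Artifact exclusion was a human judgement upstream,
so exclusion masks are caller-supplied; a bin with more than half its samples
excluded is flagged rather than reported.

Heart rate per bin is `60 / mean RR` over the intervals inside the bin, with
fewer than two beats yielding `NA` rather than a fabricated rate.
`detect_pauses()` flags RR intervals exceeding 1.8× a rolling 11-interval
median: a fully skipped beat doubles the interval, and 1.8 leaves headroom
for physiological jitter while staying far above its ~3% SD.

## The synthetic generators

Every generator takes a `sim_config` (seed, duration, state schedule, noise
SD) and returns the data plus the ground truth needed by the matching
analysis stage. Determinism is bitwise: each signal component draws from its
own deterministically derived sub-seed, so adding one component never
perturbs another, and identical configs give identical output.

* **Core temperature** — sinusoidal circadian baseline (default mean 37 °C,
  amplitude 1 °C, trough mid-light) with first-order relaxation toward
  `baseline − bout_depth` during scheduled bouts. Entry/exit rate constants
  default to 0.1 min⁻¹ (time constant 10 min), so a default 8 °C bout
  crosses 31 °C within ~15 min of onset — consistent with animals reaching
  deep hypothermia well within an hour. Ground truth records where the
  *noiseless* trace is at or below threshold, so it is independent of the
  noise draw. Default noise SD 0.1 °C matches implanted-probe resolution.
* **Photometry** — both channels share a multiplicative exponential bleach
  (default τ 1800 s) and an *additive identical* low-frequency (<0.5 Hz)
  motion artifact; only the signal channel carries transients
  (instantaneous rise, exponential decay, default τ 2 s — the slow kinetics
  of GCaMP6s). The default baseline brightness is equal for the two channels
  (100 a.u.), under which the identical additive artifact is removed exactly
  by the scale+offset fit; unequal brightnesses leave a proportional
  residual, which is realistic but makes recovery tests noisier. Event times
  are Poisson per state; `min_separation` thins them to a minimum spacing
  for recovery experiments. Amplitudes are folded-normal in ΔF/F units and
  may be given per state (the hypothermia-vs-normothermia contrast is
  generated as larger-amplitude transients during hypothermia).
* **Firing assay** — Poisson counts in 2-min bins, base rate at 25 °C and
  `base_rate · q10^((30−25)/10)` at 30 °C, ground truth per-neuron Q10.
* **EEG** — sums of band-limited Gaussian noise scaled to target powers.
  Band limitation is done by FFT masking, which confines power exactly to
  the band; a high-order Butterworth at a normalized frequency of 0.005
  would be numerically fragile and leak.
* **Beats** — jittered inter-beat intervals (default fractional SD 0.03)
  around `60/rate_bpm`; each internal beat is deleted with probability
  `pause_prob` (back-to-back deletions are suppressed so every pause is a
  clean interval doubling). Typical rates for this literature are ~776 bpm
  in normothermia and ~401 bpm in torpor; those are sensible generator
  settings, not test oracles.

What the generators deliberately do **not** emulate: biophysical
thermoregulation (bout kinetics are phenomenological), ECG waveform
morphology (only beat times), realistic EEG nonstationarity within a state,
photometry sensor nonlinearity or wavelength-dependent artifact coupling,
and bursty/clustered calcium event statistics. Passing recovery tests
therefore demonstrates correctness of the *computations* under the stated
statistical structure, not robustness to every pathology of real recordings.

## Test and acceptance problem sizes

The packaged checks use sizes chosen to make sampling error negligible while
keeping a full run around a minute: 1000 random 3-day traces for the
bout-detector/oracle equality; 100 random traces for bit-exact rolling-
baseline agreement; one 15-min recording with ~10 well-separated transients
at ~30× the ΔF/F noise SD for recall and amplitude accuracy (at 5× noise the
10th-percentile baseline convention alone biases measured amplitudes by
~26%, so small-amplitude accuracy is not a meaningful target for this
pipeline); 100 two-state 20-min simulations for the hypothermia direction
check; and 200 neurons per true Q10 ∈ {0.5, 1, 4} at 5 bins × 5 Hz for
classifier accuracy, where the binomial noise floor is far below the 41.4%
cutoff.

## Known limitations

* The reference fit is epoch-global; slow drifts that differ *between*
  channels (e.g. wavelength-dependent bleaching) leave a residual that the
  rolling baseline, not the fit, must absorb.
* Bout scoring assumes a uniform grid; telemetry with irregular timestamps
  must be regularised upstream (gaps become explicit `NA`s).
* The pause detector's rolling median assumes pauses are sparse (<~20% of
  intervals); sustained bradycardia shifts the median itself.
* `run_pipeline()` covers the simulate → score-torpor chain declaratively;
  the other stages are composed as ordinary R functions.
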