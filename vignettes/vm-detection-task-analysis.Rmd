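---
title: "Membrane-potential analysis of a whisker detection task: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-potential analysis of a whisker detection task: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmdetect)
```

## The scientific problem

Head-fixed, water-restricted mice can learn to report a brief (1 ms)
deflection of a single whisker by licking a water spout within a 1 s
reward window. Whole-cell recordings from layer 2/3 projection neurons
in the primary somatosensory barrel cortex during this go/no-go task
reveal how subthreshold membrane potential (Vm) dynamics relate to
sensory processing, learning, and movement initiation. `vmdetect`
implements the complete analysis chain for such recordings — behavioral
parsing and performance gating, spike removal, stimulus-locked and
lick-locked quantification, and group statistics — together with a
simulator that generates full synthetic sessions with known ground
truth, so that every stage can be validated by parameter recovery
rather than by eye.

## Behavioral parsing and performance gating

Trials are either *test* trials (real whisker deflection) or *catch*
trials (a logged virtual stimulus time with no deflection), scheduled
at random inter-trial intervals of 2–10 s with 40–50% catch
probability; a trial is aborted if the mouse licked during the 2 s
preceding its planned time. Outcomes follow the standard signal
detection contingency: a lick inside the half-open reward window
`[stim, stim + 1 s)` makes a test trial a *hit* and a catch trial a
*false alarm*; otherwise *miss* / *correct rejection*. We chose the
half-open convention for every analysis window in the package because
it makes window arithmetic unambiguous and partitions exact: each
spike, lick, or sample belongs to exactly one window.

Discriminability is

$$d' = \Phi^{-1}(\mathrm{HR}) - \Phi^{-1}(\mathrm{FAR}),$$

with a rate measured as exactly 0 or 1 replaced by $1/(2N)$ or
$1 - 1/(2N)$ before applying the quantile, $N$ being the trial count of
the rate being corrected (the per-rate convention; the correction is
applied *only* at the exact extremes). Recordings are gated by
performance: $d' > 1.1$ qualifies a recording as coming from a trained
"good performer", $d' < 0.9$ as "naive"; values between the gates are
indeterminate and excluded. Lick contacts are extracted from the sensor
trace as onsets of supra-threshold excursions with a 50 ms debounce.
The generic default threshold is the midpoint of the 5th and 95th
percentiles of the trace, which suits sensors with a substantial
contact duty cycle; for low-duty-cycle sensors such as the simulated
0/1 contact signal this midpoint sits in the noise, so the pipeline
configuration uses an explicit threshold (0.5 sensor units) instead.

## Subthreshold decomposition

Action potentials are detected as peaks of excursions above an absolute
threshold (session median Vm + 25 mV by default) whose rising slope
exceeds 10 mV/ms, with a 2 ms refractory rule; the slope is evaluated
over a 0.25 ms lag so single-sample noise at 20 kHz does not dominate
the derivative. Two genuine spikes inside one refractory period
collapse into one detection — a documented limitation that matters
little at the sparse firing rates of layer 2/3.

The subthreshold trace is obtained by median filtering with an 8 ms
centered window (161 samples at 20 kHz). The window must comfortably
exceed the 1–2 ms spike width; 8 ms removes the waveform while leaving
slower synaptic envelopes intact. Edges are handled by reflect padding,
which keeps the filter unbiased near the trace boundaries. One
consequence worth knowing: a running median slightly attenuates sharp
peaks, so the measured PSP amplitude of a fast kernel is ~5–7% below
the amplitude of the unfiltered kernel. This smoothing is part of the
estimand — the analysis measures the peak of the *filtered* average —
and the simulator's ground truth is therefore defined on the
median-filtered noise-free signal.

## Evoked quantification

All stimulus-locked metrics are computed on the trial-averaged,
AP-removed trace of one cell and one outcome class:

* **baseline Vm** — mean over `[-5 ms, 0)` before the stimulus;
* **PSP amplitude** — peak in the early window `(0, 50 ms]` minus
  baseline. Restricting the peak search to the early response prevents
  the slower depolarization from contaminating the sensory amplitude;
  the bound is configurable.
* **ΔVm late / lick** — mean over `[0.05, 0.25)` s / `[0.25, 1.0)` s
  minus baseline, with the alternative `[0.05, 0.35)` / `[0.35, 1.0)`
  split also reported;
* **evoked AP rates** — spike rate in the early/late/lick windows
  across trials minus the spontaneous rate, reported as-is even when
  negative;
* **spontaneous AP rate** — spikes in the 2 s preceding each trial's
  (real or virtual) stimulus, excluding windows containing any lick,
  flagged low-confidence below 16 s of qualifying time;
* **PSTH** — 50 ms (or 10 ms) bins, averaged over trials, with a
  baseline-subtracted display variant.

Aggregation is cell-by-cell by default; the mouse level first averages
cells within each mouse so every animal receives equal weight. Paired
hit/miss comparisons report the percent change of the means
(guarded when the miss mean is zero) together with the signed-rank
test.

## Spontaneous licking

Licks are segmented into bouts by a 1 s silent gap — the same time
scale as the selection rule, which keeps bout cessation and bout
separation consistent. A bout counts as spontaneous and unrewarded if
its onset is ≥3 s after the most recent preceding real stimulus (catch
trials do not disqualify; future stimuli do not disqualify) and ≥1 s
after the previous bout's offset. Lick-aligned modulation is the mean
subthreshold Vm at `[-0.1, +0.1)` s around bout onset minus the
baseline at `[-1.0, -0.6)` s, with spike rates treated analogously.

The pre-lick depolarization onset scans the cell's mean aligned trace
forward from −0.6 s and reports the first crossing of baseline mean +
3×SD(baseline) that persists for at least 50 ms. The persistence rule
is our noise-robustness addition: without it, single-sample noise
crossings produce spuriously early onsets. The SD is computed from the
per-cell mean aligned trace (not across bouts), which matches the
threshold to the noise actually present in the trace being scanned. A
degenerate SD of exactly 0 (possible only for synthetic input) falls
back to an absolute 0.5 mV floor and is flagged. Cells whose trace
never crosses are reported as lacking pre-lick depolarization rather
than assigned a latency.

## Statistics

Group comparisons use the two-tailed Wilcoxon rank-sum test (unpaired)
and signed-rank test (paired), computed through `stats::wilcox.test`:
exact null distributions when `n1*n2 ≤ 400` (unpaired) or `n ≤ 25`
(paired) and the data are tie-free, otherwise the normal approximation
with tie and continuity corrections. Degenerate inputs (identical
samples, all-zero differences) return p = 1 with a flag instead of
failing. Box summaries use type-7 quantiles and Tukey whiskers (most
extreme points within 1.5 IQR of the quartiles). Raw p-values are
reported without multiple-testing correction, consistent with how such
focused comparison sets are conventionally reported.

## The simulator and what it does (not) emulate

`simulate_session()` generates a complete session:

* **Scheduler** — ITIs uniform on [2, 10] s, catch probability 0.45,
  the 2 s abort rule evaluated against the accumulating lick stream.
  Because reward consumption licking itself aborts subsequent trial
  candidates, scheduling and response generation run as one sequential
  closed loop.
* **Behavior** — response probability 0.77/0.17 (test/catch) for
  trained mice, 0.31/0.28 for naive mice; reaction times follow a
  shifted gamma (mean 317 ms trained / 369 ms naive, SD 100 ms, floor
  50 ms) truncated to the reward window; spontaneous bouts arrive at
  9/min (Poisson, thinned so bouts never overlap each other, a
  response bout, or a reward window — a mouse has one tongue), with
  ~6 licks/s and exponential durations around 1 s.
* **Vm** — resting −62 mV; Ornstein–Uhlenbeck background (τ = 100 ms,
  σ = 2 mV) for slow network-driven fluctuations plus 0.3 mV white
  measurement noise; a difference-of-exponentials PSP kernel
  (τ rise 2 ms, decay 30 ms, peak-normalised, per-trial amplitude
  Normal with SD 2 mV floored at 0) at every test stimulus; an
  alpha-like late kernel peaking at 261 ms (FWHM ≈ 0.3 s) on hit
  trials and scaled by 0.35 on miss trials; a linear pre-lick ramp
  rising over the 260 ms before every bout onset, holding through the
  bout and decaying with τ = 300 ms; and spikes from an inhomogeneous
  Poisson rate $r = r_0 e^{g\,\Delta V_m}$ (0.3 Hz at rest, 0.4/mV,
  capped at 15 Hz, 3 ms minimum interval) rendered as 1 ms triangular
  45 mV waveforms.
* **Amplitude presets** mirror the published effect structure:
  S2-projecting cells of trained mice carry the large late/lick
  depolarization (late kernel 6 mV, ramp 2.5 mV), M1-projecting cells
  much less; in naive mice M1-projecting cells show the larger PSP
  (12.2 vs 8.4 mV) and lick-related depolarization.

Ground truth for each cell is the noise-free signal processed by the
same AP-removal filter, evaluated with the same window definitions, so
recovery error isolates the effect of noise, spiking, and finite trial
counts.

The simulator is phenomenological. It does **not** model
conductance-based spike generation, whisker kinematics, orofacial
movement, electrode drift, or trial-to-trial correlations beyond the
OU process. Passing recovery tests therefore demonstrates that the
analysis code measures what it claims to measure under the assumed
statistical structure — not that real cortical data satisfy that
structure.

## Numerical choices and problem sizes

Times are seconds from recording start, Vm is mV, and sessions live on
a fixed 20 kHz grid (the lick sensor may use its own rate; the
simulator uses 5 kHz). Events map to samples by rounding, so aligned
windows are exact to half a sample. Validation suites use: oracle
equivalence on 100 random instances per primitive; a recovery cohort
of 20 cells × 700 s sessions (~30 hit trials and ~50 selected bouts
per cell); a behavioral closed loop of ~2000 trials; and 10,000-replicate
null calibrations of both rank tests at the cohort's sample sizes
(31 vs 22 unpaired, 19 paired). These sizes give sampling error
comfortably below the asserted tolerances (e.g. ±0.5 mV for group-mean
recovery) while keeping the default test run fast.

## Known limitations

* The original analysis environment's median-filter window and spike
  thresholds are unpublished; defaults here are physiologically
  motivated and configurable, and validation is against simulator
  ground truth rather than waveform-exact figure reproduction.
* Bout-level inference treats the first supra-threshold sensor sample
  as tongue contact; piezo ringing or slow capacitive sensors may need
  a different threshold/debounce configuration.
* The d' gate uses all trials of a recording; no sliding-window
  performance tracking is attempted.
* Mouse-level aggregation assumes cell assignments are exchangeable
  within mouse; no hierarchical shrinkage is applied.
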