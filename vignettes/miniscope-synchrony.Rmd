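---
title: "Synchronous patterns, behavior and stimulus responses from dual-region miniscope sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronous patterns, behavior and stimulus responses from dual-region miniscope sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minisync)
```

`minisync` implements the downstream analyses of dual-region miniature
microscope experiments: two head-mounted scopes image calcium activity in
two brain areas (for example cerebellar Purkinje cell dendrites and motor
cortex) while an on-board IMU records head acceleration at 104 Hz, and
optionally an LED driver delivers optogenetic stimuli. The package consumes
the outputs of standard upstream tools (motion correction and CNMF-E-style
source extraction, exported as CSV tables) and provides the event-level,
population-level and behavioral analyses, together with a synthetic session
generator that supplies ground truth for every stage.

## The analysis model

### Event onsets

Calcium-event onsets are extracted per cell by a matched filter: the trace
is cross-correlated with a unit-energy double-exponential transient
template, local maxima of the filter output above `threshold` (default 3)
times the noise SD become events, and a parabola through the three samples
around each maximum gives sub-frame timing. The noise SD is estimated from
the median absolute deviation of the first difference divided by
$\sqrt{2}$, which is robust to the transients themselves; because the
template has unit energy, white noise passes through the filter with
unchanged SD, so the same estimate calibrates the filtered signal. Two
details matter in practice:

* the transient tail keeps the filter output high after an onset, so noise
  ripples there form spurious local maxima; a candidate is only accepted if
  the output rose by at least one threshold above the trough since the
  previous accepted event (a prominence gate);
* events closer than `refractory_s` (default 0.2 s) to an accepted event
  are discarded, keeping the earlier one. Ground-truth events violating the
  refractory spacing are by construction outside the detector's contract.

The detector's output is invariant to positive rescaling of the trace.

### Synchronous patterns

Onset times of all cells are convolved with a unit-peak Epanechnikov kernel
$k(t) = 1 - (t/h)^2$ on $|t| \le h$ and summed into the population kernel
sum $S(t)$, evaluated on a 10 ms grid. We read the kernel's "steepness" as
its half-width and default to $h = 0.1$ s, which spans about three frames
at 30 Hz; the parameter is exposed because the original choice is not fully
specified. Maximal grid runs with $S$ above $\mu + 2\sigma$ (moments over
the whole grid; a median/MAD option exists but is off by default) become
global synchronous events, as half-open intervals. Cells with at least one
onset inside the same event co-fire once, regardless of how many onsets
they contribute; pairs that co-fire at least `min_co = 5` times are
synchronous pairs (SPs), labeled `within_<region>` or `across` by their
endpoints. Adjacent supra-threshold runs separated by any sub-threshold
grid point are distinct events; no merging rule is applied.

A property worth knowing: chance co-firing between two independent Poisson
cells grows linearly with session length, while the $\mu + 2\sigma$
threshold scales with the population. At the population sizes of real
sessions (one to three hundred cells) chance events spread over tens of
thousands of pairs and the $\ge 5$ rule is selective; with a dozen cells
and sessions of many minutes, chance pairs cross five co-firings easily.
The planted-ensemble benchmark therefore uses compact one-minute sessions
(24 cells, a 6-member cross-region ensemble firing 10 times, 25 ms onset
jitter), where recovery is complete (all 15 member pairs flagged in every
seed tested) with a pooled false-pair rate of about 2%.

### SP-triggered behavioral acceleration

The compound acceleration $a_{xyz} = \sqrt{x^2 + y^2 + z^2}$ is cut into
$\pm 2$ s snippets around each SP. The threshold is $\mu + 2\sigma$ of the
snippet's outer baseline — the earliest quarter of the pre-window, farthest
from the SP, so the movement itself cannot contaminate the baseline. A side
"rises above threshold" when the mean of its samples does
(`criterion = "window_mean"`): under the alternative pointwise reading
(available as `criterion = "pointwise"`), the maximum over a two-second
window exceeds its own $2\sigma$ threshold on essentially any stochastic
baseline and the `no_change` category becomes unreachable. Categories are
`post`/`pre` (the crossing side with the larger mean, the central
$\pm 150$ ms band excluded), `around` (only the central band crosses) and
`no_change`; they partition the classified SPs exactly, and SPs whose
window does not fit in the recording are dropped and counted. The signal is
low-pass filtered at 10 Hz before thresholding — chosen so the filter's
impulse spread stays well inside the $\pm 150$ ms band.

The random-trigger control draws uniform trigger times and compares, via a
two-sample proportion test without continuity correction, the fraction of
snippets whose post-window crosses threshold between random and SP
triggers. The indicator here is pointwise (any sample crossing), which
keeps both fractions away from the degenerate 0/1 corners and the test
calibrated; degenerate tables return $p = 1$.

### Rearing, turning, triggered averages

Rearing is segmented from the low-passed (2 Hz) y channel by hysteresis
(`theta_on` 0.15 g, `theta_off` 0.08 g) with epoch bounds extended outward
to a low edge threshold (`theta_off / 2`), so durations approximate the
full excursion rather than its supra-hysteresis core; epochs must last
0.5–10 s. Turns are signed threshold crossings of the low-passed x channel
(up = left under the default convention; flipping the convention swaps all
labels) with a refractory between epochs. These thresholds are in g and
were fixed against the synthetic templates; real rearing was scored
semi-manually from video in the source experiments, so fully automatic
segmentation of real data is an extension and should be validated
per-animal. Peri-event triggered averages resample snippets onto a uniform
relative grid and report the pointwise mean, SEM ($0$ by convention for a
single trigger) and the latency of the mean's peak after the trigger.

### Optogenetic stimulus responses

Trials are cut around stimulus onsets (or offsets); trials overlapping the
recording edges are dropped and counted. A cell is a responder when the
maximum of its trial-averaged trace between stimulus offset and offset +
1.5 s exceeds $\mu + 2\sigma$ of the baseline. The baseline statistics pool
the raw per-trial pre-stimulus samples rather than the trial average: the
pooled $\sigma$ measures single-trial spontaneous variability (including
spontaneous transients), so a response must exceed what ongoing activity
reaches — taking both statistics on the averaged trace caps specificity
near chance because a pointwise max almost always exceeds its own
$2\sigma$. Responder onsets come from a four-parameter logistic fitted to
the rise phase only (stimulus onset to the averaged peak); the onset is the
closed-form $\mu + \sigma$ crossing of the fit, with a flagged fall-back to
the first raw crossing if the fit fails or leaves the window.

Dorsal-striatum style modulation uses, per cell, a paired t-test across
trials of the pre-stimulus mean against the during-stimulation mean of raw
fluorescence (an event-rate option exists); $p < 0.05$ splits into
`decreased`/`increased` by sign, otherwise `unchanged`, with zero-variance
differences defined as $p = 1$ and no multiple-testing correction by
default (a Benjamini–Hochberg option exists), matching the per-cell
criterion of the source analyses. Movement-locked activity compares 1 s
window means before and after each movement onset, per turn direction.

## The synthetic session generator

`synth_config()` defaults encode the reported statistics of the real
recordings: per-cell Poisson baselines of 0.62 Hz (cerebellum) and 0.22 Hz
(cortex); transient half-decay times of 0.217 s and 0.488 s with a 20 ms
rise; 30 Hz frames and a 104 Hz IMU; movement following a synchronous
event with probability 0.31 at ~80 ms lognormal latency; rearing templates
of 2.2 s at 1.47 per minute when enabled. Planted synchronous events inject
one jittered onset (SD 25 ms) into each ensemble member; `sp_count` plants
an exact number of events when a controlled firing count is needed.
Stimulation trials assign each cell a response class — `increased` cells
receive a time-locked onset 0.22 s after stimulus offset (plus extra events
during long stimuli), `decreased` cells lose 80% of their baseline events
during stimulation, `unchanged` cells are untouched.

The decay rate of the transient kernel is calibrated so that the kernel's
peak-to-half interval equals the configured `t_half_s` — the statistic the
estimator measures — rather than fixing the decay constant at
$\ln 2 / t_{1/2}$, which would make emitted transients read ~5% slow. At
the 30 Hz imaging rate the sharp rise is undersampled and the half-decay
estimator retains a 2–4% negative discretization bias across onset phases;
recovery is exact at sampling rates that resolve the rise.

One global seed is split deterministically into per-component streams
(events, ensemble, jitter, trace noise, IMU noise, movement, rearing,
turning, stimulation), so each component is independently reproducible and
identical configurations give byte-identical sessions and pipeline
reports.

What the generator does *not* emulate: sensor drift and motion artifacts,
non-stationary behavioral states, bursty or correlated baseline firing,
source-extraction crosstalk, and the skewed amplitude distributions of real
transients. Passing recovery tests therefore demonstrate correctness of the
analysis chain under the stated statistical model, not performance on real
recordings.

## Numerical choices and degenerate inputs

* All times are in seconds from session start; intervals are half-open
  $[t_0, t_1)$, so an onset exactly at an interval's end is not a
  participant.
* Kernel-sum grid step 10 ms (at least 10 samples across the kernel);
  `kernel_sum()` refuses a grid coarser than $h/4$.
* Constant traces yield empty event trains, not errors; NaN in a trace is a
  hard error. Cells with zero baseline SD are flagged and Z-scored to zero.
* Zero-variance paired differences give $p = 1$; degenerate proportion
  tables give $p = 1$.
* Refractory and layout ties break deterministically (earlier event;
  lexicographic cell id).
* Half-decay events must be isolated by 1 s on both sides; events that
  never fall to half within the follow window are reported censored, and a
  crossing must be confirmed by the following sample so an isolated noise
  dip cannot end a decay early.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
sessions of 60–600 s with 2–50 cells per region, 20 seeds for the
ensemble-recovery and responder benchmarks and 200 replicates for the
type-I calibrations; these sizes were chosen so every benchmark
distribution is tight enough to assert against while a full run stays in
the minutes range on a single core.

## Known limitations

* The `min_co = 5` SP rule is calibrated for session lengths of a few
  minutes; much longer sessions need a recalibrated `min_co` or a
  jitter-based null, which is out of scope here.
* Rearing/turn thresholds are template-tuned defaults, not validated
  against scored video.
* The pipeline accepts either raw or deconvolved traces and records which
  was used, but does not itself deconvolve.
* Gyroscope channels are not parsed (the acquisition firmware reads only
  the accelerometer).
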