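# minisync

Analysis pipeline for **dual-region miniature-microscope (miniscope)
sessions**: calcium imaging from two brain areas at 30 frames/s, a
head-mounted IMU sampling acceleration at 104 Hz, and (optionally) an
optogenetic stimulation log. The package is written for experimenters who
already have motion-corrected, source-extracted traces (e.g. CNMF-E output
exported to CSV) and need the downstream event-level, population-level and
behavioral analyses.

What it computes:

* **Event inference** — sub-frame calcium-event onsets by matched
  filtering with a unit-energy transient template (threshold 3 noise-SD on
  the filter output, MAD-of-first-difference noise estimate, parabolic
  sub-frame interpolation, 0.2 s refractory), per-cell event rates, and
  half-decay times of isolated transients.
* **Synchronous patterns (SPs)** — all onsets are convolved with a
  unit-peak Epanechnikov kernel (half-width h = 0.1 s) and summed into a
  population kernel sum S(t); maximal stretches with
  S > mean + 2·σ are global synchronous events; cells with onsets in the
  same event co-fire once; pairs co-firing ≥ 5 times are SPs, labeled
  within- or across-region, with a degree-sorted arc-diagram layout and
  GraphML/CSV export.
* **Behavior from the IMU** — the compound acceleration
  a_xyz = √(x² + y² + z²); SP-triggered classification of acceleration
  into *no change / post / pre / around* (window means against
  mean + 2·σ of the far pre-window baseline, ±150 ms central band); a
  random-trigger control with a proportion test; rearing segmentation from
  the y channel (hysteresis + duration limits) and left/right turn
  detection from the x channel; peri-event triggered averages with SEM and
  peak latency.
* **Stimulus responses** — trial tensors around stimuli; responders by the
  mean + 2·σ rule (baseline σ pooled over raw per-trial pre-stimulus
  samples); response onsets from a sigmoid fit to the rise phase; and
  three-way *decreased / unchanged / increased* modulation by paired
  t-tests of pre vs during-stimulation means, with per-cluster event
  rates.
* **A synthetic session generator** whose defaults encode the reported
  statistics of such recordings (0.62 / 0.22 Hz event rates, 0.217 /
  0.488 s half-decays, 2.2 s rearings at 1.47/min, ~80 ms movement
  latency after a synchronous event) and emits full ground truth, so every
  stage has a recovery benchmark.

Everything is tibble-first: results are tibbles or small S3 objects with
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Simulate a two-region session with a planted synchronous ensemble whose
events are always followed by a movement bout, then run the SP and behavior
analyses:

```r
library(minisync)

cfg <- synth_config(duration_s = 120, sp_count = 8L,
                    p_move_given_sp = 1, seed = 42L)
session <- simulate_session(cfg)

events <- detect_events(session$traces,
                        onset_params(t_half_s = c(CBL = 0.217, CTX = 0.488)))
sp <- detect_sp(events, session$traces$cells, duration_s = 120)
sp$kernel_sum
#> <kernel_sum> 12001 grid points, dt = 0.01 s, h = 0.1 s
#>   mu = 1.52, sigma = 1.344, threshold = 4.208
sp$graph
#> <sp_graph> 30 cells, 207 co-firing pairs, 66 SPs (min_co = 5, 26 sync events)
```

The kernel sum averages 1.52 with SD 1.34, so the synchrony threshold is
4.21 — roughly four coincident onsets. 26 supra-threshold events yield 66
synchronous pairs; the planted 12-member ensemble (40% of each region)
accounts for C(12,2) = 66, so recovery is exact here:

```r
sp$scope$participation
#> # A tibble: 2 × 4
#>   region n_cells frac_within frac_across
#>   <chr>    <int>       <dbl>       <dbl>
#> 1 CBL         15         0.4         0.4
#> 2 CTX         15         0.4         0.4

a <- compound_accel(session$accel)
trig <- classify_sp_triggers(a, (sp$sync_events$t0 + sp$sync_events$t1) / 2)
trig$fractions
#> # A tibble: 4 × 3
#>   category      n fraction
#>   <chr>     <int>    <dbl>
#> 1 no_change    15    0.577
#> 2 post         11    0.423
#> 3 pre           0    0
#> 4 around        0    0
```

Eleven of the 26 detected synchronous events are followed by
supra-threshold acceleration — the 8 planted ensemble events (each coupled
to a bout) plus coincidence events overlapping them; background coincidence
events show no change. The population acceleration around the planted
events peaks ~0.28 s after the synchronous time (80 ms latency + half the
0.4 s bout):

```r
eta <- event_triggered_average(a$t, a$a, session$truth$sp_times, win_s = 2)
eta
#> <eta> 8 triggers (0 dropped), window +/- 2 s, peak latency 0.279 s
autoplot(eta)
```

`run_pipeline()` drives the whole chain (simulate/load → events → SPs →
behavior → stimulus response → graph export) from one config list or YAML
file, writes every artifact as CSV/GraphML plus a `report.json` with all
headline quantities and a full parameter echo, and is byte-for-byte
reproducible for a fixed config and seed.

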