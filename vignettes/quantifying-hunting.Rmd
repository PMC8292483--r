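---
title: "Quantifying appetitive locomotion in predatory hunting: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying appetitive locomotion in predatory hunting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locohunt)
```

## The problem

When a mouse hunts an insect it alternates bouts of *appetitive locomotion*
(closing on the prey) with contact phases (jaw attacks) and disengagement.
Quantifying this behavior, and relating it to neural signals — spiking of
midbrain projection neurons, striatal dopamine measured by fiber
photometry — requires a chain of small, well-specified procedures:
segmenting approach episodes from tracking data, summarizing attacks,
aligning neural signals to behavioral events, measuring speed tuning, and
a few satellite assays (runway gait, looming-evoked escape, synaptic
puncta density). `locohunt` implements this chain as composable functions,
together with seeded synthetic-data generators that plant known ground
truth for every modality, so each stage is testable end to end without any
recordings.

## Approach-episode segmentation

The substrate is a `trajectory`: uniformly sampled (50 frames/s) positions
of the predator centroid, a head point, and the prey. From it we derive
the `kinematic_series`: binned locomotion speed (200 ms bins), the signed
azimuth angle between the head direction (centroid-to-head vector) and the
centroid-to-prey bearing, and the predator–prey distance (PPD).

An approach episode must satisfy two criteria simultaneously: the PPD
decreases continuously until it falls below 3 cm, and the azimuth stays
within ±90°. Two points in this definition are under-determined and we had
to make them precise:

* **"Continuously decrease" under tracking jitter.** We use a
  running-minimum slack: within an episode the PPD may never exceed *any
  earlier within-episode value* by more than `rise_tolerance` (0.5 cm). A
  fixed slack relative to the running minimum absorbs frame-to-frame
  jitter but cannot be exploited by a slow sustained climb, which a
  windowed rule (e.g. "no rise within 3 frames") would permit. The rule is
  also monotone under interval extension, which guarantees that maximal
  episodes are well defined and lets an independent exhaustive scan verify
  the detector exactly.
* **Where an episode starts.** The episode's end is pinned by the first
  frame with PPD < 3 cm; the start is the furthest preceding frame from
  which both criteria hold, which by construction lands on the latest
  local PPD maximum before the final descent — the moment the animal
  commits to closing distance.

Episodes closer than `min_gap` (0.5 s) merge, but only when the azimuth
criterion also holds across the gap; otherwise they are genuinely separate
approaches and both are kept (an unconditional merge would put
azimuth-violating frames inside an episode). Episodes shorter than one
speed bin (0.2 s) are discarded since no peak speed can be attributed to
them. Frames with missing azimuth or PPD violate both criteria; metrics
that cannot be computed (no episodes, no attacks) are `NA`, never 0,
because 0 is a legitimate frequency.

From the episodes and the attack log come the five per-trial hunting
metrics: time to capture (prey introduction to last jaw attack), latency
to attack (first jaw attack), attack frequency (attacks / time to
capture), approach speed (mean of per-episode peak speeds) and approach
frequency (episodes / time to capture). `net_effect()` is the exact ON −
OFF subtraction used for within-subject manipulation effects, and
`average_per_mouse()` averages metrics across the standard three trials,
propagating undefined values with per-metric counts.

### Speed from positions

Binned speed defaults to within-bin path length divided by bin duration
(robust to within-bin turns); endpoint displacement is selectable. Two
consequences matter for interpretation. First, a brief speed peak is
attenuated by 200 ms binning: a sinusoidal ~0.7 s approach profile loses
roughly 5–10 % of its peak, so peak-speed comparisons against planted
values should either use finer bins or tolerate that attenuation. Second,
path-length speed of a *noisy, slow* point is biased upward (the noise
path accumulates); at approach speeds of 25–45 cm/s with 0.1 cm tracking
noise the bias is below 3 %, but near-stationary noisy tracking reads
several cm/s. The synthetic looming trials therefore plant their speed
variability in the profile itself rather than in position noise.

## Peri-event alignment and the 15 %-of-peak onset

`align_to_events()` turns a spike train into a trial-averaged, Z-scored
peri-event response (20 ms bins; Z against the mean and SD of the
trial-averaged rate over a [−2, −1] s baseline window — chosen to sit well
outside the ~100 ms leads under study). A zero baseline SD (an exactly
periodic train) flags the unit rather than producing infinities.
`event_triggered_average()` does the same for ΔF/F traces, sharing the
container.

The response onset is the time at which the (optionally Gaussian-smoothed,
50 ms SD for spike PSTHs) average first reaches 15 % of its peak amplitude
relative to baseline. Our estimator walks *back from the peak* to the
nearest preceding run of `hold` (3) sub-threshold bins and linearly
interpolates the crossing; walking forward from the window start instead
turned out to be fragile — a single distant noise bump that clears the
threshold for three bins captures the onset (we observed estimates more
than a second early on otherwise ordinary synthetic units). Interpolation
makes the estimator exact on piecewise-linear inputs (a 0.2 s ramp from
baseline yields −0.17 s analytically, which the tests assert to machine
precision) and equivariant under time translation. The offset is the
symmetric forward walk: the first post-peak run of `hold` bins back inside
the 15 % band. When the peak does not exceed the baseline by at least
2 baseline SDs the estimate is undefined.

Two systematic effects are worth knowing. Smoothing pulls the measured
crossing slightly *earlier* (the kernel mixes future signal into the foot
of the rise), while the 15 % threshold sits slightly *after* the true
start of a finite-rise ramp; for a ~100 ms rise with 50 ms smoothing the
two nearly cancel, leaving a net bias of about −10 ms. The photometry
transients (instant rise, exponential decay) show the same ~10 ms early
bias through the 40 Hz anti-aliasing filter. Both are well inside the
±30 ms recovery tolerance the tests use.

## Speed tuning

`speed_tuning()` partitions locomotion bouts (hysteresis thresholds: on at
3 cm/s, off at 1 cm/s, minimum 1 s — 3 cm/s being the lower edge of the
analyzed range) into consecutive 500 ms windows; each window contributes
its mean speed and the unit's firing rate. Rates are averaged within
3 cm/s speed bins, min–max normalized to [0, 1] per unit (so units average
onto a common scale), and the speed–rate association is the Spearman rank
correlation over bins whose centres lie in 3–30 cm/s.

The p-value uses the exact permutation distribution of the rank statistic
for ≤ 10 bins (asymptotic beyond), since the asymptotic approximation is
unreliable at such small n. One genuine subtlety emerged in calibration
testing: bins visited for only a handful of windows have high-variance
mean rates, and unequal variances break the exchangeability on which the
rank-permutation null rests — flat-rate units then show slightly too many
spurious "significant" correlations. We therefore require at least
`min_windows = 10` windows (5 s of locomotion) before a bin enters the
correlation; sparse bins remain in the curve but not in the test. With
this guard the flat-null rejection rate matches the nominal level in
simulation. Whether the population correlation should be computed over
bins of the averaged curve or over units × bins is ambiguous in the
field's practice; both work through `average_tuning_curves()` plus
`spearman_rank()`, with bin-level the default.

## Antidromic identification

A unit is accepted as a projection neuron when (a) the median first-spike
latency after terminal photostimulation (10 ms search window) is below
5 ms, (b) at least half the pulses are followed by a spike, and (c) the
Pearson correlation between the mean pulse-evoked waveform and the mean
locomotion waveform is at least 0.9. The 5 ms bound is the standard
criterion; the reliability (0.5) and similarity (0.9) cutoffs make the
qualitative "faithfully following / comparable waveform" requirements
operational and are exposed as parameters.

## Photometry

ΔF/F uses a running 10th-percentile baseline over a 30 s window (evaluated
on a 0.5 s grid and interpolated), which tracks slow bleaching while
ignoring transients; a fixed whole-trace percentile is selectable for
short recordings. The raw trace is low-pass filtered at 40 Hz (mirroring
the acquisition hardware's anti-aliasing) with reflect-padding before the
zero-phase filter — without padding the filter's edge transients reach
several percent of the signal at the trace ends. ΔF/F is exactly invariant
to any positive gain on the raw trace, which the tests assert to 1e-9.

Evoked amplitudes average the trace across pulses first and then take the
post-stimulus peak (1 s window) minus the pre-stimulus mean (1 s);
averaging before the peak keeps the max-of-noise bias of the peak operator
small. The input–output curve aggregates amplitudes per laser power with a
control channel alongside; the suppression ratio is the mean treated
amplitude over the mean control amplitude.

## Gait and looming escape

Stance onsets are transitions of the body-frame paw velocity from forward
(swing) to backward (stance), detected with a ±2 cm/s hysteresis pair on a
5-frame smoothed velocity and a 100 ms minimum inter-step interval. Step
frequency is (n − 1) steps over the first-to-last onset span; stride
length is the mean ground-frame displacement between consecutive stance
onsets. Escape metrics are window statistics of the 200 ms-binned speed:
peak during the three stimulus cycles (first onset to last onset + 2 s),
mean over the following 10 s, and mean over the 10 s before the first
onset; the window extents are declared defaults, not recovered constants.

## Puncta density

Micrographs are binarized with Otsu's between-class-variance threshold
(fixed thresholds selectable), and puncta are counted as 8-connected
foreground components intersecting the region mask, gated to
[max(2, 0.2πr²), 6πr²] pixels for an expected punctum radius r to reject
single-pixel noise and merged blobs; touching puncta count once, as in the
binarize-then-count procedure. Density is count per µm² of mask; the
normalized density divides a target region's density by a reference
region's, so pixel size cancels exactly. An area-fraction mode is provided
because count-versus-area is genuinely ambiguous in common practice.
EBImage supplies the Otsu threshold, but component labelling is our own
breadth-first implementation: the field's convention for this procedure is
8-connectivity, and the available labeller is 4-connected (verified on
diagonal-touching pixels). The tests check the labelling against an
independent label-propagation oracle on hundreds of random images.

## The synthetic generators

Every generator takes a single integer seed, fans it out to independent
sub-streams (geometry, event emission, noise), and records all planted
quantities in a `ground_truth` object that round-trips exactly through
type-preserving JSON. The defaults are the study conditions:

* **Hunting trials**: 10–20 approach episodes per trial (default 15), peak
  approach speeds 25–45 cm/s, 50 frames/s in a 25 × 25 cm arena, 0.1 cm
  Gaussian position noise per coordinate, jaw attacks as a 2 /s Poisson
  process while the noise-free PPD is under 3 cm. Between episodes the
  predator's head points away from the prey and the PPD increases, so
  outside planted episodes at least one criterion fails by construction;
  because predator and prey move linearly between episodes the PPD is
  convex there and cannot re-cross 3 cm downward. Prey motion between
  episodes is a relocation at fixed speed — the quantitative escape
  kinematics of the prey are free parameters of the generator, not
  estimates of real insect behavior.
* **Speed-tuned units**: inhomogeneous Poisson spikes with rate
  `baseline (5 Hz) + slope (1 Hz per cm/s) × speed(t + 0.1 s)` over a
  treadmill profile of 4–8 s bouts (targets 8–28 cm/s, 100 ms initiation
  ramp — rapid bout onsets are what make a ~100 ms lead recoverable
  through a 15 %-of-peak estimator), then a 50-pulse 1 Hz tagging block
  with antidromic spikes at 3 ms ± 0.2 ms. Waveforms are fixed biphasic
  templates plus white noise; a mismatched-unit mode swaps in a second
  template whose correlation with the first is ≈ −0.65.
* **Photometry**: transients are impulses convolved with a 0.5 s
  exponential kernel, amplitude 0.08 ΔF/F, planted 125 ms before each
  locomotion onset, on a baseline of 100 a.u. with optional slow bleach
  and 0.01 ΔF/F-equivalent noise; evoked mode plants amplitudes
  `0.3 P/(P + 10) × suppression` at scheduled pulse powers.
* **Gait**: body at 20 cm/s, 5 steps/s, duty cycle 0.6 in a trot pattern;
  stride = speed/frequency = 4 cm. The defaults are commensurate with the
  50 Hz frame grid, so noiseless recovery is exact rather than
  quantization-limited.
* **Looming**: 8 cm/s baseline wandering, a burst to 40 cm/s across three
  stimulus cycles (1 s apart, 12 s in), then freezing; positions are
  integrated along a slowly turning heading that steers away from walls so
  the planted per-step speeds are exactly what path-length binning
  recovers.
* **Puncta**: n non-overlapping bright disks (radius 3 px, intensity 0.8)
  fully inside the mask on a 0.1 background with 0.05 noise, at
  0.1 µm/pixel.

What the generators deliberately do **not** emulate: correlated or
heavy-tailed tracking error, prey biomechanics, electrode drift and
sorting failures, hemodynamic or motion artifacts in photometry, uneven
illumination in micrographs. Passing the recovery tests therefore
demonstrates that the procedures are correct and well calibrated on data
matching their assumptions — not that they are robust to every failure
mode of real recordings.

## Problem sizes in the test suite

The shipped tests run the episode detector against an exhaustive
criteria-scan oracle on 500 random series of up to 400 frames, recover
planted episodes on 100 noisy and 100 noiseless trials, check onset
recovery on 18 synthetic units, tuning-null calibration on 200 reseeded
flat units, antidromic classification on 100 planted units, suppression
recovery on 100 paired sessions, gait on 50 noisy runs, and component
counting on 200 random 64 × 64 images — sizes chosen so the whole suite
completes in a couple of minutes on one CPU while keeping the Monte Carlo
margins meaningful.

## Known limitations

* The episode detector's slack parameters (0.5 cm rise tolerance, 0.5 s
  merge gap, 0.2 s minimum duration) are behavioral conventions, exposed
  as arguments; different tracking quality may warrant different values.
* Peak-speed metrics inherit the 200 ms binning attenuation discussed
  above.
* The Spearman p-value is exact only for ≤ 10 occupied bins and after the
  occupancy guard; window-level correlation is available but its samples
  are serially dependent, so its asymptotic p should be read loosely.
* `compute_dff` assumes a positive, background-corrected baseline and
  errors otherwise rather than guessing a correction.
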