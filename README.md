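# locohunt

Quantification of appetitive locomotion during predatory hunting, and of
the neural signals that accompany it, in laboratory mice.

When a mouse hunts an insect, its behavior decomposes into intermittent
*approach episodes* — bouts of appetitive locomotion in which the
predator–prey distance (PPD) falls continuously below 3 cm while the prey
stays within ±90° of the head direction — separated by contact phases with
jaw attacks. `locohunt` implements the full measurement chain around this
definition:

* **Kinematics** — binned locomotion speed (200 ms bins at 50 frames/s),
  azimuth angle, and PPD from predator/prey tracking tables.
* **Hunting metrics** — approach-episode segmentation by the two criteria
  above, plus the five per-trial metrics: time to capture, latency to
  attack, attack frequency, approach speed (mean of per-episode peak
  speeds), approach frequency (episodes / time to capture), and exact
  ON − OFF net effects for optogenetic manipulations.
* **Neural tuning** — antidromic identification of projection units
  (median latency < 5 ms, reliable pulse-following, waveform similarity),
  trial-averaged Z-scored peri-event responses, 15 %-of-peak onset/offset
  estimation, and locomotion speed-tuning curves (firing rate per 500 ms
  window, 3 cm/s speed bins, Spearman rank correlation over 3–30 cm/s
  with exact small-sample permutation p).
* **Photometry** — ΔF/F with a running-percentile baseline,
  event-triggered averages, onset-lead estimation (shared 15 % rule),
  evoked-transient amplitudes, input–output curves, suppression ratios.
* **Locomotor assays** — runway gait (stance-onset detection from
  body-frame paw velocity; step frequency and stride length) and
  looming-evoked escape metrics (peak speed during stimuli, average
  speeds before/after).
* **Puncta quantification** — Otsu binarization, 8-connected component
  counting with a size gate, density per µm², and reference-region
  normalization.
* **Synthetic data** — seeded generators for every modality with planted
  ground truth (episode intervals, onset leads, tuning slopes, gait
  parameters, puncta counts), so the whole chain is testable without any
  recordings.

## Worked example

```r
library(locohunt)

sim <- simulate_hunting_trial(n_episodes = 12, seed = 7)
kin <- kinematics(sim$trajectory)
hunting_trial(kin, sim$attacks)
#> <hunting_trial_result>
#>   time to capture:    30.46 s
#>   latency to attack:  2.50 s
#>   attack frequency:   1.0506 /s
#>   approach speed:     32.73 cm/s
#>   approach frequency: 0.3940 /s
#>   episodes:           12
```

The detector recovered all 12 planted episodes. Time to capture is the
span from prey introduction to the last jaw attack; the attack frequency
(~1.05 attacks/s) counts 32 attacks over that span; the approach speed is
the mean of the 12 per-episode peak binned speeds (the planted peaks
average 35.9 cm/s — 200 ms binning attenuates brief peaks by a few
percent); the approach frequency is 12 episodes / 30.46 s.

On the neural side:

```r
unit <- simulate_speed_tuned_spikes(seed = 3)
identify_antidromic(unit$train, unit$pulses)
#> <antidromic_result> IDENTIFIED (median latency 3.02 ms, reliability 1.00,
#>                     waveform r = 1.000)
speed_tuning(unit$train, unit$speed, bouts = unit$bouts)
#> <speed_tuning_curve> 10 bins, 309 windows; Spearman rho = 1.0000 (p = 0.000397)
```

The unit was planted with a 3 ms antidromic latency and a positive rate
slope of 1 Hz per cm/s, so it is correctly identified and its normalized
tuning curve rises monotonically across the 3–30 cm/s bins.

See the vignette (`vignettes/quantifying-hunting.Rmd`) for the models,
parameter choices and caveats behind each stage.

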