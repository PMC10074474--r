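# msalpha

Analysis of how spontaneous microsaccades relate to transient
lateralisation of posterior EEG alpha (8–12 Hz) activity.

During attempted fixation the eyes still make tiny involuntary saccades
(microsaccades, < 1° of visual angle). `msalpha` implements the complete
analysis chain to ask whether the *direction* of such microsaccades is
accompanied by a lateralised, transient modulation of posterior alpha
power — and a synthetic-data generator with known ground truth so the whole
chain can be validated without laboratory recordings. It is aimed at
cognitive-neuroscience researchers working with concurrent eye-tracking and
EEG.

## What it computes

* **Microsaccade detection** from binocular gaze at 1000 Hz: binocular
  averaging (strict NaN policy), ±100 ms blink padding, smoothed absolute
  velocity (Gaussian 7-ms window), a trial-based threshold of 5× the median
  velocity, a 100-ms refractory period, pre/post-window magnitude and
  direction (pre: −50–0 ms, post: +50–100 ms), a `< 1°` magnitude ceiling
  and a 3.42-arcmin displacement floor, and start/return classification
  against a median fixation reference.
* **Saccade-locked epoching** of EEG (±1200 ms) with contra/ipsi channel
  roles for a posterior pair (default PO7/PO8; also O1/O2).
* **Time-frequency analysis**: Hanning-taper STFT, 1–50 Hz in 1-Hz steps,
  300-ms windows in 20-ms steps, and from it
  * the lateralisation contrast
    `L = 100·(P_contra − P_ipsi)/(P_contra + P_ipsi)` (percent),
  * baseline-corrected log power per role (baseline −500…−150 ms),
  * the topographic contrast `100·(P_left − P_right)/(P_left + P_right)`,
  * inter-trial phase coherence
    `ITPC = | mean_trials ( c / |c| ) |` ∈ [0, 1].
* **Cluster-based permutation inference** over participant × frequency ×
  time maps: per-cell paired t tests (two-sided α = 0.05), same-sign
  4-adjacency clusters scored by summed t, sign-flip permutations (default
  10,000) with the max-|t-sum| statistic, p = proportion of permutation
  maxima at or above the observed cluster's |t-sum| (C++ kernel, plus an
  exact enumeration variant for small n).
* **Synthetic data**: fixational drift + injected start/return
  microsaccades with known onsets, 1/f EEG noise, a saccade-locked evoked
  transient, and a 10-Hz ipsilateral burst with a configurable phase-locked
  fraction.

## Worked example

Simulate a small study with an injected ipsilateral alpha effect, run the
full pipeline, and inspect the report:

```r
library(msalpha)
cfg <- sim_config(n_participants = 8, n_trials_per_participant = 30, seed = 5)
report <- run_pipeline(cfg, n_permutations = 2000, verbose = FALSE)
print(report)
```

```
Microsaccade-locked alpha lateralisation report
  config 63b6f1e3, seed 5; 365 epochs; pair PO7/PO8
  detection: recall 0.994, precision 1.000, onset error 1.77 ms, direction agreement 1.000
  subset all   : n=8, mean 8-12 Hz lateralisation 0-250 ms = -25.98%, min cluster p = 0.0075
  subset start : n=8, mean 8-12 Hz lateralisation 0-250 ms = -25.59%, min cluster p = 0.0085
  subset return: n=8, mean 8-12 Hz lateralisation 0-250 ms = -25.46%, min cluster p = 0.0065
```

Reading this: the detector recovered 99.4% of the injected microsaccades
with no false alarms and ~2 ms onset error; in all three event subsets the
8–12 Hz contra-minus-ipsi contrast in the 250 ms after saccade onset is
strongly negative (alpha power is higher ipsilateral to the saccade, as
injected), and the cluster-based permutation test flags it:

```r
print(report$subsets$all$lateralisation$test)
```

```
Cluster-based sign-flip permutation test (n = 8, 2000 permutations)
  cluster-forming |t| >= 2.365 (two-sided alpha = 0.05)
  cluster 15: sign -1, 99 cells, t-sum -938.0, p 0.0075
  cluster 19: sign +1, 90 cells, t-sum 367.5, p 0.0075
  ...
```

The dominant negative cluster covers the alpha band just after saccade
onset. (The accompanying positive cluster reflects the paired *return*
saccade of opposite direction a few hundred ms later — its burst lands on
the opposite hemisphere.) `plot(report)` draws the group-mean
lateralisation map; `report$subsets$start$log_power` and `...$itpc` hold
the baselined log-power and phase-coherence analyses per channel role.

Individual stages are exported too — `simulate_gaze()`, `merge_eyes()`,
`pad_blinks()`, `compute_velocity()`, `detect_microsaccades()`,
`epoch_eeg()`, `stft_epochs()`, `participant_lateralisation()`, `itpc()`,
`cluster_test()` — see the methods vignette
(`vignettes/microsaccade-alpha-methods.Rmd`) for the model behind each.

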