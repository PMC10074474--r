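---
title: "Methods: microsaccade-locked lateralisation of EEG alpha activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsaccade-locked lateralisation of EEG alpha activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Even during attempted fixation the oculomotor system produces small
involuntary saccades — *microsaccades*, here defined as gaze shifts below
1 degree of visual angle. Posterior EEG alpha activity (8–12 Hz) lateralises
with spatial cognition, and spontaneous microsaccades are a candidate driver
of such lateralisation: a microsaccade in one direction is accompanied by a
transient change of alpha power that differs between the hemisphere
contralateral and ipsilateral to the movement. `msalpha` implements the full
analysis chain needed to quantify that association — microsaccade detection
from gaze velocity, saccade-locked EEG epoching, time-frequency
decomposition, contra/ipsi contrasts, inter-trial phase coherence (ITPC),
and cluster-based permutation inference — together with a synthetic-data
generator with known ground truth, so every stage can be validated end to
end without access to laboratory recordings.

## Pipeline model, stage by stage

### Gaze preprocessing

Binocular gaze at 1000 Hz is averaged into a single horizontal channel.
The merge is *strict*: a sample is missing whenever either eye is missing,
which prevents half-blink velocity spikes. Each maximal missing-data run is
then padded by 100 ms on each side (clipped at the trace bounds) to remove
residual blink artifacts. Padding operates on the missing runs present at
call time, so a second application would widen runs by a further margin; the
pipeline applies it exactly once, before any velocity is computed. The
vertical channel is carried through the data model but plays no role in
detection, which is deliberately horizontal-only: the lateralisation
question is about left/right shifts.

### Microsaccade detection

Velocity is the absolute forward first difference of position scaled to
deg/s, smoothed by a Gaussian-weighted moving average over a 7-ms window.
The kernel is a truncated Gaussian with `sigma = window/5`, normalised to
unit sum; missing samples propagate through the window, while at the trace
edges the kernel is renormalised over the in-range samples. The forward
difference is the simplest scheme consistent with a temporal derivative,
and the kernel is documented precisely so that an independent
direct-convolution oracle reproduces it in the tests.

Onsets are the first samples of runs exceeding a *trial-based* threshold of
5 times the median velocity; the median is taken over the trial's delay
period (encoding offset to cue onset) ignoring missing samples, so blinks do
not deflate it. A 100-ms refractory period discards onsets following an
accepted onset too closely. Saccade metrics come from two fixed windows:
pre-saccade position is mean gaze over [−50, 0) ms, post-saccade position
over [+50, +100] ms; magnitude is their absolute difference and direction
its sign (negative = left). Events are kept when magnitude < 1 degree
(microsaccades) and |displacement| ≥ 3.42 arcmin — 1% of the 5.7-degree
stimulus eccentricity. The floor is applied symmetrically in both
directions; a one-sided, toward-stimulus reading of the criterion is
conceivable but asymmetric, and we prefer the symmetric rule.

Start/return classification compares pre- and post-saccade distance to a
fixation reference, the median gaze over −1500…−500 ms before cue onset
(this window is specified in seconds; we treat the occasionally seen
"−1.5 to −0.5 ms" phrasing as a units typo). Distance increasing means a
*start* microsaccade, decreasing a *return*; exact ties are excluded from
the split but stay in the all-saccade pool, since only strict inequalities
define the classes. Analyses use only events at least 500 ms after encoding
offset and at least 500 ms before cue onset, where fixation is the sole task
demand and the microsaccades can be called spontaneous.

### Saccade-locked epoching

EEG at the same clock is cut from 1200 ms before to 1200 ms after each
surviving microsaccade onset (2401 samples at 1000 Hz). Events whose window
leaves the trial recording are dropped and counted. Epochs may overlap when
two microsaccades are less than 2400 ms apart; no de-overlapping is applied
beyond the detector's 100-ms refractory period, matching how such epochs
are treated in practice. Channel roles cross hemifields: for the PO7/PO8
pair, a leftward saccade makes PO8 (right hemisphere) contralateral and PO7
ipsilateral.

### Time-frequency decomposition

A short-time Fourier transform of Hanning-tapered data: 300-ms windows
advanced in 20-ms steps, frequencies 1–50 Hz in 1-Hz steps. A 300-ms window
has ~3.3-Hz native resolution; the 1-Hz grid is obtained by zero-padding
each tapered segment to 1 s, the common interpolative-sampling convention
for "1-Hz steps" in windowed analyses. Coefficients are scaled by
`2/sum(taper)` so a unit-amplitude sinusoid at a bin frequency has magnitude
~1; all derived quantities are ratio- or phase-based, so the scale cancels.
Time points whose window would leave the epoch (within ~150 ms of the
edges) are undefined, not zero-filled — zero-filling would attenuate edge
power and bias baselines.

### Derived quantities

* **Lateralisation contrast.** Per electrode, power is averaged over epochs
  separately for left and right saccades, and the normalised contrast
  `L = 100·(P_contra − P_ipsi)/(P_contra + P_ipsi)` formed; the two
  electrodes' contrasts are averaged. `L` is bounded in ±100% and
  antisymmetric under contra/ipsi exchange. Cells with zero denominator are
  undefined and excluded from averages.
* **Baselined log power.** Trial-averaged power per role is log-transformed
  and the mean log power over the −500…−150 ms pre-saccade baseline is
  subtracted per frequency. Averaging before the log follows the reading of
  condition-average "log-normalised power"; a per-trial-log variant would
  change absolute values but not the ipsi/contra asymmetry the test
  targets.
* **ITPC.** Fourier coefficients are normalised to unit length, averaged
  across epochs, and the modulus taken: 0 for random phases, 1 for perfect
  phase locking. Zero-magnitude coefficients carry no phase and are
  excluded; an all-zero cell is undefined. Under a uniform-phase null the
  expected ITPC of *n* epochs is ≈ √π/(2√n), which the tests verify against
  a Monte-Carlo oracle.
* **Topography.** Per channel, 8–12 Hz power 0–250 ms post-saccade averaged
  separately over left- and right-saccade epochs and contrasted as
  `100·(left − right)/(left + right)`.

### Cluster-based permutation inference

Participant-level difference maps (e.g. `L`, or Δlog-power ipsi − contra)
are tested against zero. Cells whose two-sided paired t test reaches
α = 0.05 (|t| at or above the critical value; ties inclusive) enter
clustering; maximal connected components of same-sign cells under
4-neighbour adjacency on the frequency × time lattice — the standard
lattice neighbourhood for 2-D data, diagonals excluded — are scored by their
summed t values. Each of the 10,000 permutations flips the sign of every
participant's whole map independently with probability ½, the
exchangeability operation of a paired design, and contributes its maximum
|t-sum| pooled over both signs; pooling controls the two-sided family-wise
error without an explicit α/2 split. A cluster's p value is the proportion
of permutation maxima at or above its |t-sum|. The observed data are *not*
added to the permutation distribution; when no permutation reaches the
observed statistic the p value is floored at `1/n_permutations` (a
`plus_one` flag switches to the `(b+1)/(m+1)` convention). For small
samples `cluster_test_exact()` enumerates all `2^n` sign patterns and the
Monte-Carlo p converges to that exact value. The permutation kernel is
implemented in C++ (Rcpp); the R test suite checks it against a naive
BFS/enumeration oracle written independently in R.

Numerical conventions worth stating: cells with zero variance across
participants get t = 0 when the mean is also zero, and a sign-preserving
sentinel (±1e12) otherwise, so constant-offset cells cluster sensibly
instead of producing NaN; undefined (edge) cells must be trimmed before
testing (`trim_defined()`), and the test refuses arrays containing NA.

## The synthetic-data generator

The generator emulates the study design the analysis assumes: trials with a
250-ms encoding display, a retention delay drawn uniformly from
2000–2500 ms, and a 1000-Hz recording; 2 sessions × 10 blocks × 60 trials
(1200 trials) per participant; 23 participants by default. Desk-scale
analyses pass smaller `n_participants`/`n_trials_per_participant`
explicitly.

Gaze is fixation plus slow drift plus step-like saccadic displacements plus
per-eye tracker noise:

* **Saccade waveform** — raised-cosine (sigmoidal) displacement over 20 ms.
  This reproduces a step with a realistic transition without modelling
  peak-velocity physics (no main-sequence model).
* **Drift** — a sum of four low-frequency (0.2–1.2 Hz) sinusoids with random
  amplitudes and phases, rescaled to a 0.05-degree SD. Quasi-periodic drift
  keeps drift velocity bounded, so the 5×-median threshold cleanly separates
  drift from saccades, while still exercising the fixation-reference logic.
* **Tracker noise** — independent Gaussian noise per eye and sample,
  SD 0.002 degrees. After binocular averaging and the 7-ms smoothing this
  yields a median velocity near 1.6 deg/s and a detection threshold near
  8 deg/s, below the peak velocity of even the smallest injected saccades
  (0.1 degree over 20 ms peaks near 8 deg/s) and far above the noise floor.
* **Event stream** — start microsaccades arrive at 1 event/s during the
  delay (magnitudes uniform on 0.1–0.9 degrees, directions fair-coin); each
  is followed with probability 0.5 by a return microsaccade of opposite
  direction 200–400 ms later that undoes 85–100% of the displacement.
  Sequential placement keeps all events ≥ 100 ms apart (≥ 150 ms between
  pairs); rates above 6/s are rejected because that spacing becomes
  infeasible. The published record does not report empirical rate or
  magnitude distributions, so these defaults are field-typical
  placeholders, exposed in the configuration.
* **Blinks** — with probability 0.1 per trial, one 100–300 ms missing run in
  both eyes, placed away from injected events (blinks and microsaccades
  rarely co-occur, and this keeps ground truth recoverable) to exercise the
  padding path.

EEG per channel is 1/f background noise (spectral shaping of white Gaussian
noise, exponent 1, RMS 10 µV), a saccade-locked broadband evoked transient
on all channels (Gaussian bump peaking 100 ms after onset, σ = 50 ms,
4 µV — its energy sits below ~5 Hz so it does not masquerade as an alpha
effect), and the effect of interest: a 10-Hz burst with a 250-ms Hanning
envelope starting at saccade onset, added **only** to the channels
ipsilateral to the saccade (left saccade → PO7/O1). Its peak amplitude is
`alpha_effect_amplitude` × noise RMS (default gain 1), split into a
phase-locked component (phase fixed relative to onset) and a random-phase
component according to `alpha_phase_locked_fraction` (default 0.5). Setting
the gain to 0 yields a null world for false-positive calibration; setting
the phase-locked fraction to 1 makes ipsilateral ITPC approach 1 in the
burst window as noise vanishes.

Reproducibility: each participant gets two RNG substreams (gaze and EEG)
derived from the master seed, so gaze regenerates identically whether or
not EEG is requested, and identical seed + configuration gives bit-identical
outputs.

What the generator does **not** emulate — and hence what passing tests do
not show about laboratory data: ocular spike potentials and EMG artifacts,
non-stationary or heavy-tailed tracker noise, saccade main-sequence
kinematics, vertical-saccade structure, pupil signals, volume-conducted
topographies beyond the four posterior channels, and any attention-driven
coupling between cognition and microsaccade statistics. Recovery results on
synthetic data validate the *implementation*, not the neuroscientific
claim.

## Problem sizes and runtimes used for validation

The validation suite chooses sizes where every targeted property is
measurable yet the whole suite runs in minutes: detector recovery uses
200 trials (about 400 injected events); the effect-recovery run uses
8 participants × 30 trials (≈ 365 epochs) with 2000 permutations; the
false-positive calibration runs 20 independent null worlds of
5 participants × 16 trials each; the permutation oracle enumerates all 32
sign patterns for 5 participants against 10,000 Monte-Carlo draws; ITPC
calibration uses 50 identical epochs and 200 × 50 uniform-phase draws
against a 10⁴-replicate Rayleigh oracle. The full-design defaults
(23 × 1200) remain available for larger simulations.

## Known limitations

* Detection is horizontal-only by design; oblique microsaccades with small
  horizontal components are treated by their horizontal projection.
* The 1-Hz frequency grid is interpolative (zero-padded), not additional
  spectral resolution; neighbouring frequency bins are correlated.
* Cluster inference is over time × frequency within a predefined electrode
  pair; no spatial (channel-neighbourhood) clustering and no TFCE.
* The baselined log-power analysis assumes a clean pre-saccade baseline;
  for return microsaccades the preceding start saccade contaminates it, so
  conclusions there rest on the lateralisation and ITPC contrasts instead.
* Epochs are stored as dense in-memory arrays; at the full design size
  (tens of thousands of epochs) the time-frequency step should be run per
  participant, as `run_pipeline()` does.
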