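---
title: "Predicting honeybee swarming from hive vibration spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting honeybee swarming from hive vibration spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The monitoring problem

Accelerometers embedded in the honeycomb of a hive log power spectra of
comb vibration, averaged every 3 minutes, at 3 Hz frequency resolution.
A colony preparing to issue a primary swarm changes its vibrational
behaviour days to weeks before the exit, but the change is subtle: night
spectra of a preparing colony can be nearly identical to those of a quiet
one.  `hivewatch` implements a supervised pipeline that extracts what
signal there is, plus detectors for the loud, unambiguous events: swarm
lift-off, failed (returned) swarms, and queen piping.

This vignette documents the model, its tunable parameters, the synthetic
data generator that stands in for field recordings, and the design
decisions taken where the method leaves room.

# The discriminant core

`swarm_dfa(x, labels)` fits the shared classification machinery:

1. **PCA.** Features (one spectrum or one flattened 3DFT per row) are
   centred and decomposed; components with numerically zero variance are
   dropped.  The leading `keep_fraction` (default 0.4) of the remaining
   components — *by count, not by cumulative variance*, matching how the
   optimised configuration is specified — enter the next stage.  Feature
   length far exceeds the training count, so this truncation is also the
   main guard against over-fitting: too few scores discard information,
   too many admit noise.
2. **DFA.** Fisher's criterion in score space: the within-class scatter
   `S_w` is regularised with a ridge of `1e-6 · trace/dim` (it is singular
   whenever scores outnumber items) and the whitened between-class scatter
   is eigendecomposed.  With two classes the between-class scatter has
   rank 1, so only DF1 carries class separation.  The method as published
   uses *three* DF axes; we define DF2/DF3 as the remaining eigenvectors
   of the whitened between-class scatter in eigenvalue-then-index order —
   successive orthogonal directions carrying the residual (zero)
   between-class variance.  This reproduces a three-dimensional DF space
   without inventing extra classes; it is an interpretation, and the
   classification burden rests on DF1.
3. **DF curves.** Each axis is back-projected through the selected
   components into feature space.  Scoring a new feature then needs no
   explicit PCA projection: the DF coordinate is the cross-correlation
   product (zero-lag inner product) of the centred feature with the curve,
   and the two routes agree to machine precision (tested at 1e-9).
4. **Criterion and threshold.** A point's criterion value is
   `d(·, c_PTS)/d(·, c_NS)` (distance ratio to the class centroids);
   a point on the NS centroid returns the `Inf` sentinel.  The alarm
   threshold is found by exhaustive scan over midpoints of consecutive
   sorted unique criterion values, minimising misclassifications; ties
   break toward the widest optimal gap, so the cut sits at the safest
   margin.  Values *below* threshold mean "swarming state".

Training-set reduction (`reduce_training_set()`) searches for the subset
of training items whose model minimises the error over the *full*
collection — removed items are still scored.  The subset search is
exhaustive up to `2^20` candidate subsets and falls back to greedy
backward elimination (with a warning) beyond that, since exploring every
combination is combinatorially infeasible in general.
`parametric_optimisation()` wraps the whole chain in a deterministic
full-factorial grid scan whose objective is the percentage error.

## Open choices, and what the package does

* **"Normalised with respect to their mean"** can mean divide or
  subtract; divide is the default (it makes features gain-invariant,
  which the tests rely on), subtract is available via `normalise =`.
* **Whether the 2DFT consumes linear or log amplitude** is not pinned
  down; linear is the default (`log_scale` in `strategy_config()` flips
  it), keeping the DC bin interpretable as the night-mean amplitude.
* **Pooling order for the instantaneous training items**: the 13
  pre-swarm nights are averaged on raw amplitudes first, then normalised
  and logged.
* **No taper window** is applied before either DFT; magnitudes are
  one-sided and scaled by 1/T so bin 0 is the window mean.  Rectangular
  framing keeps Parseval's identity exact (tested at 1e-9 relative).

# The two strategies

**Instantaneous (strategy 1).**  Features are hourly mean spectra from a
configurable night hour (default 3–4 AM), cropped to 18–800 Hz (wind
contaminates the band below 18 Hz), divided by their mean,
log10-transformed.  Training PTS items pool the `ramp_days` = 13 nights
before each training colony's swarm; NS items pool 13-night blocks of
non-swarming nights.  The training databases are capped at 24 PTS and 32
NS items — the optimised database sizes of the published configuration.

**Spectral evolution (strategy 2).**  Per day and per spectral bin, the
one-sided DFT magnitude of the bin's time course over the midnight–5 AM
window (100 frames at 180 s cadence, 51 modulation bins); per pixel, a
second one-sided DFT across `history_days` = 10 consecutive days (6
across-day bins, 0–0.5 cycles/day = up to 3.5 repetitions per week).
Crop is 25–800 Hz and is applied *before* the 2DFT.  Tensors are
flattened row-major and mean-normalised, with no log.  Training uses up
to 20 PTS windows (end dates within 6 days of a swarm) and 21 NS windows,
again the published optimum sizes.

Because magnitudes discard phase, both transforms are invariant to
circular shifts of their time axes: the features record *that* and *how
fast* the spectrum changed, not *when* — which prevents training to
absolute timings.

**Gap policy.** A day is usable when at least 90 % of its window frames
are present; isolated missing frames are linearly interpolated in time
per bin; an unusable day invalidates every 3DFT window containing it.
Missing data are represented explicitly (`quality = "missing"`) and are
never zero-filled — zero rows in an ingested container are converted to
missing, because a zero spectrum would otherwise masquerade as a strong
alarm (the criterion of a near-zero feature is small).

# Alarms and performance accounting

`hourly_alarm()` scores every hour (instantaneous: the hour's mean
spectrum; evolution: the day's 3DFT, shared by all of that day's hours).
`nightly_mean()` averages the non-missing hourly criteria over
midnight–5 AM; an all-missing night stays missing.  The published results
use the midnight–5 AM window for both strategies, while the discussion
suggests 8 PM–1 AM for the evolution strategy; both are supported via the
`window` argument and midnight–5 AM is the default for both.

A *sustained* trigger is at least two consecutive triggered nightly
means; single-night flukes do not count (the method's own narrative never
defines sustainment, so this is the package's choice, applied
symmetrically to swarming and non-swarming colonies).  `lead_time()`
reports the days from the start of the earliest sustained run that
persists to within two days of the swarm; a trigger on the swarm date
itself counts with lead 0.  `performance_summary()` mirrors the published
accounting: nightly-mean errors per class, raw hourly false positives
(any trigger while not intending to swarm — after the last queen pipe,
or any time for a non-swarming colony), raw hourly false negatives (no
trigger in the 14 days before the swarm), mean warning, and the
colony-level success rate.

# The synthetic generator

Field recordings are not distributable, so `simulate_series()` generates
seasons with the statistical structure the pipeline assumes, directly in
the frequency domain (pipe audio is the one waveform-level component).
Per colony: a smooth noise floor with a tilt and gain drawn once (so
colonies differ and classification is non-trivial), Gaussian buzz peaks
at 125/250 Hz, a foraging day (9:00–16:00) with amplified, broadened
peaks and a broadband bump, per-bin multiplicative log-normal noise of
0.2 decades, and random sub-18 Hz wind gusts.  Swarming scenarios add:

* a **signature ramp**: Gaussian peaks at `sig_freq` = 21 Hz and its
  harmonic(s), whose amplitude grows linearly from zero over the final
  `ramp_days` = 13 days to `sig_gain` = 3 night-noise standard
  deviations.  21 Hz is the band of the dorso-ventral abdominal
  vibration signal, where real pre-swarm discriminant spectra
  concentrate their weight.  `sig_gain = 0` is an exact null: the
  generator draws all randomness independently of the event schedule, so
  a swarming scenario and its quiet twin are byte-identical before the
  swarm;
* a **lift-off transient** (60 Hz peak on a broadband pedestal, ~6 min)
  at each exit, followed by a sustained 45 % drop of the buzz amplitude;
* **failed swarms**: the transient, then two hours of a ~150 Hz re-entry
  peak and a 30 % amplitude increase instead of a drop;
* **queen pipes** rendered as narrow drifting ridges (toots 350→480 Hz,
  quacks 280→350 Hz) following a natural chronology
  (`default_pipe_schedule()`): first toot 4–7 days after the primary
  swarm, quacking 6 h later, toot cessation at each afterswarm.

What the generator does *not* emulate: physical comb propagation, real
weather, brood-cycle drift, varroa or queenless states, inter-colony
acoustic leakage, and the full 5.5 kHz bandwidth (the default grid stops
at 897 Hz because both strategies crop at 800 Hz).  Green tests therefore
demonstrate the pipeline's correctness and its sensitivity under the
stated noise model — not field performance.

# The reference experiment

`swarm_benchmark()` (also run by `scripts/acceptance.R`) simulates 18
swarming and 14 non-swarming colonies over 60-day seasons (colony seeds
1–32 for master seed 1), trains on the first half of each class, and
reports held-out spectrum-level and 3DFT-level errors plus the two
colony-level success rates.  Ground-truth labels follow the training
definitions: PTS nights are the 13 ramp nights; PTS windows end within 6
days of the swarm; NS nights/windows precede the ramp entirely or follow
the last queen pipe; the transitional span between swarm and last pipe is
excluded from error accounting, as swarming-class membership there is
genuinely ambiguous.  Thresholds are optimised over all labelled items of
the training colonies — the full-collection clustering step of the
training phase — and held-out colonies contribute nothing to training.

Problem sizes were chosen to keep the experiment at desk scale: 32
colonies × 60 days × 480 frames × 300 bins simulate in about two minutes
on one CPU, and the evolution-strategy PCA operates on 41 training
vectors of length ~79,000.

# Numerical notes and limitations

* Timestamps are timezone-naive local clock times (encoded as UTC);
  night windows are half-open `[00:00, 05:00)`.
* The series container is a per-colony directory of plain-text parts
  (JSON metadata, CSV frames, full-precision CSV amplitudes); round
  trips are bit-identical.
* Degenerate inputs: zero-variance training databases, single-class
  labels, empty containers, windows outside the series span, and
  sub-Nyquist pipe sample rates all raise immediate errors; missing data
  propagate as missing, never as zeros.
* The pipe detector estimates fundamentals by per-frame argmax ridge
  within 200–550 Hz, median-smoothed over 3 frames; with 0.05 s frames
  the bin width (~20 Hz) hides the toots' gentle FM but resolves the
  quacks' much deeper modulation, which—together with the presence of
  the long leading pipe—separates the two classes.  Hourly pipe
  presence in averaged spectra compares each hour against the same hour
  of the preceding days (a night-only baseline would flag the broadened
  foraging buzz in the quack band); multi-day piping blocks therefore
  fade from the presence flags after their first day or two, and the
  chronology checks are best driven from detected or logged events.
* DF2/DF3 carry no class separation by construction; they add benign
  spread to both centroid distances.  Models with `n_df = 2` are
  available through `swarm_dfa(..., n_df = 2)`.
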