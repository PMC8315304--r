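---
title: "Deciding whether neural activity is movement-locked: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding whether neural activity is movement-locked: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perimove)
```

## The question

In a cued forelimb task, a mouse hears a go cue and — after a variable
reaction time (RT) — pushes a lever. Neural populations recorded during the
task (calcium imaging of thalamic neurons, whole-cell and extracellular
recordings in motor cortex) show activity around movement. The scientific
question is *what that activity is locked to*. Three trial-to-trial models
compete:

* **Model i — movement-locked**: activity rises at a fixed latency before
  movement onset, regardless of RT. The population acts as a timing signal
  for movement initiation.
* **Model ii — cue-locked**: activity rises at the cue with a fixed rise
  time and plateaus until movement. Latency to movement then varies with RT.
* **Model iii — ramp-to-threshold**: activity ramps from the cue and reaches
  a fixed level exactly at movement, so the ramp slope encodes RT.

The models make distinct predictions for onset latency as a function of RT
once trials are aligned to movement: model i predicts a flat relation,
models ii and iii predict slope −1 (the onset tracks the cue). Models ii and
iii differ in when activity *peaks*: a fixed delay after the cue (ii) versus
at movement (iii).

`perimove` implements the full analysis chain needed to make that decision —
ΔF/F₀ normalization, response classification, calibrated onset detection,
RT-split comparisons, the model discrimination itself — plus the
accompanying intracellular, extracellular, behavioral, and image-domain
quantifications, and a synthetic-data generator that emulates every input
modality with known ground truth.

## The synthetic generator as the study's stand-in

Raw data of this kind are rarely deposited, so every stage here is
verified by parameter recovery on synthetic data. The generator's defaults
encode the study conditions:

* **Trials** (`simulate_trials`): inter-trial intervals uniform on 4–6 s; a
  6-kHz go cue; log-normal RTs with median 0.32 s; cued trials missed with
  probability 0.363 (63.7% task success). The log-scale RT dispersion is not
  a published quantity; the default (`rt_dispersion = 1.0`) was chosen so
  that the three RT categories used downstream — short [0, 350) ms, medium
  [350, 900) ms, long ≥ 900 ms — are all populated at realistic session
  sizes (roughly 54/31/15% of push trials).
* **Calcium** (`simulate_calcium`): each push trial receives a GCaMP6s-like
  transient — a linear ramp from a defined onset with a 0.5 s rise — placed
  according to the population model, decaying single-exponentially
  (τ = 1 s; such calibration protocols specify only the rise, and the decay
  does not affect onsets). Noise is i.i.d. Gaussian per frame in ΔF/F₀ units
  (default SD 0.05 against a default amplitude of 0.5). Miss trials carry
  no transient. Frame rate 40 Hz.
* **Membrane potential** (`simulate_vm`, 20 kHz): a smooth raised-cosine
  subthreshold deflection starting at a fixed pre-movement lag, stereotyped
  spike waveforms (sharp threshold kink, 0.4 ms rise) inserted by an
  inhomogeneous Poisson process whose rate follows the depolarization, on
  white-plus-slow noise.
* **Spike trains** (`simulate_spiketrains`): inhomogeneous Poisson with a
  multiplicative rate step in a peri-movement window.
* **Video** (`simulate_motion_frames`): i.i.d. pixel noise with
  large-amplitude frame-to-frame changes injected during true movement
  epochs.
* **Spread images** (`simulate_spread_images`): radially symmetric Gaussian
  fluorescence blobs with known scale and center.

What the generator does *not* emulate: photon shot noise statistics,
neuropil contamination, motion artifacts, bursting spike statistics,
electrode drift, or realistic video content. Passing recovery tests on this
generator therefore demonstrates the correctness of the *analysis
machinery* under the stated model assumptions, not robustness to every
pathology of real recordings.

## ΔF/F₀ and onset detection

`compute_dff` low-pass filters the raw trace at 1 Hz (zero-phase 4th-order
Butterworth — the cutoff is standard, the filter family is our choice — with
reflective padding so a constant trace stays constant) and takes F₀ as the
bottom 5th percentile of the filtered signal; ΔF/F₀ = (F − F₀)/F₀.

Onsets are detected per trial with a slope sum function (SSF): the trace is
Savitzky–Golay smoothed (27 frames, order 2), first differences are taken,
and their positive part is summed over a trailing 375 ms window (15 frames
at 40 Hz). The onset is the earliest time in a peri-movement search window
(default −1 to +0.5 s) where the SSF reaches 10% of its in-window peak.
Because the SSF is nonnegative with a strictly positive mean under noise,
the absolute floor that declares a trace onset-free is the baseline SSF
mean plus three SDs (a mean-free 3-SD bound would reject nothing).

Per cell, trial onsets are resampled 10,000 times and the onset is reported
as the median of the bootstrap medians, with its IQR. Cells whose bootstrap
IQR exceeds the cohort median IQR by more than three SDs of the IQRs are
flagged undetectable and reclassified nonresponsive. Note the rule's
behavior at small cohort sizes: a single extreme cell inflates the IQR SD
itself, so the rule only bites in cohorts of roughly ten cells or more —
which is the regime it is meant for.

### Calibration

Smoothing and the threshold rule bias the detected onset, so the detector
is calibrated exactly the way the study prescribes: 100 simulated cells ×
30 trials of linear ramps with defined onsets and a 0.5 s rise, at the
noise level of the imaging data; the median detection error is the
FOV-specific correction subtracted from all of that FOV's onsets. One
implementation detail matters: analysis traces reach the detector through
movement alignment, i.e. linear interpolation at a sub-frame phase, which
attenuates and correlates frame noise. The calibration therefore generates
its ramps on a phase-shifted frame clock and interpolates them onto the
aligned grid — the same data path — otherwise the correction systematically
overshoots (interpolated noise triggers far fewer early SSF crossings than
raw frame noise).

With that match, the post-correction median bias on an independent ramp
cohort is below one 40 Hz frame at zero noise and a few milliseconds at the
default noise level (`evaluate_calibration`).

## Response classification

`classify_response` bins movement-aligned ΔF/F₀ into 250 ms bins from
−0.5 to +1.5 s and applies a Friedman test across bins with trials as
blocks (α = 0.01). For significant cells, a Tukey–Kramer test on the
within-trial ranks identifies bins differing from the first (pre-movement)
bin at α = 0.05; response direction is the sign of the mean signal in the
earliest two significant bins minus baseline. The baseline for this rule is
the 500 ms pre-cue mean when the aligned window covers it, else the first
bin — the underlying convention ("baseline") is not pinned down by the
protocol, so we align it with the baseline used everywhere else. Early
versus late (before/after movement) is assigned afterwards from the sign of
the calibrated onset. A cell is *responsive* only if the Friedman test
passes **and** its onset is detectable (≥ 5 detected trial onsets, IQR rule
passed); on pure-noise cells that compound call fires well below the 1%
Friedman level alone.

## RT splits and the model decision

For the RT analysis, each neuron's onset is recomputed per RT category
(short/medium/long, fixed boundaries) and each FOV contributes its
across-neuron mean per category; FOVs need at least 5 trials in every
category to enter (how many trials count as sufficient is not standardized;
5 is our floor). A one-way ANOVA across categories on the
per-FOV means asks whether movement-aligned onsets depend on RT — under the
movement-locked model they must not.

Three design points here were genuinely open:

* **Trial-count matching across RT categories.** The per-trial onset
  detection error is left-skewed (noise can trigger the SSF threshold early
  but rarely late), so a per-neuron median over a category's trials carries
  a small-sample bias that depends on the category's trial count. Since the
  categories have systematically different counts (long-RT trials are
  rare), unmatched medians would manufacture a spurious onset-vs-RT effect
  of tens of milliseconds under a movement-locked model.
  `fov_rt_onsets` therefore subsamples every category to a matched trial
  count before taking onsets (mirroring the trial-count matching this kind
  of protocol applies to raster comparisons), which equalizes both the bias
  and the variance of the category estimates. Multi-FOV comparisons use one
  *experiment-wide* count (`rt_anova_experiment`): if each FOV matched only
  its own categories, the count-dependent bias would still differ *between*
  FOVs and act as an FOV-level factor shared by all of that FOV's
  categories, deflating the ANOVA's F statistic.
* **Across-FOV latency spread.** Real imaging fields differ in their
  population latency (the study's own populations span roughly −270 to
  −370 ms), so simulated experiments draw each FOV's true lag from a normal
  distribution (default SD 50 ms; `fov_lag_sd` in `default_config`). One
  statistical consequence is worth knowing: each FOV contributes one value
  to *every* RT category, so FOV latency heterogeneity correlates the
  groups and makes a one-way ANOVA — which assumes independent groups —
  conservative, not invalid. The null-level check in the acceptance suite
  therefore runs on homogeneous FOVs (`lag_sd = 0`), the regime in which
  the stated test is correctly specified and holds its ~95% level; the
  power and recovery experiments keep the heterogeneity.
* **The discrimination rule** (`discriminate_model`) is not prescribed
  anywhere; ours is: regress movement-aligned onset on RT (Theil–Sen,
  robust to trials whose transient is clipped by the alignment window at
  extreme RTs). |slope| < 0.5 → model i. Otherwise regress the
  movement-aligned time of the 90%-of-peak point on RT: slope near −1 means
  the peak tracks the cue (model ii), near 0 means it tracks movement
  (model iii). The per-trial features are 10%/90% rise times of the
  smoothed trace found by *backward* search from the peak, over one common
  RT-independent window: an earliest-threshold-crossing detector over the
  long windows this comparison needs is dominated by noise crossings pinned
  to the window start (which makes every model look movement-locked), and
  per-trial RT-dependent windows couple the detector's bias to RT and tilt
  the slopes. Fewer than 20 usable trials or an RT range under 100 ms
  returns "indeterminate".

On synthetic data at default noise the rule recovers the generating model
in ≥ 90% of simulated FOV datasets for all three models (the acceptance
suite measures this at 100 datasets per model).

## Intracellular analysis

Spikes are detected by amplitude-plus-slope prominence (local maxima over
20 mV above the trace median preceded by a ≥ 15 mV/ms upstroke within 1 ms,
2 ms dedup); the detection contract — perfect recall and precision at the
generator's default SNR — is what the pipeline relies on, not the specific
algorithm. AP threshold is the Vm at the maximal second difference within
3 ms before the peak (earliest sample on ties). Subthreshold traces are
obtained by clipping −1 to +9 ms around each threshold (exactly 200 samples
at 20 kHz per isolated spike, overlapping spans merged) and filling gaps by
linear interpolation, which keeps sampling uniform for the downstream
filters; ΔVm trajectories subtract the 1 s pre-cue baseline per trial,
average, decimate to 1 kHz (a decimation target the protocol leaves open),
and apply a 50 ms sliding median. Trajectory significance compares the
bootstrap CI of the epoch-mean change (200 ms pre-cue baseline versus
−100..+100 ms peri-movement) to zero; onsets are 10% rise times searched
backward from the peri-movement peak; population trajectories normalize to
their largest absolute value within ±0.75 s of movement. Silencing
comparisons integrate |ΔVm| from cue to the median reward time
(trapezoid rule at 50 ms) and report the post/pre ratio, plus a
proportional firing-rate change ((response − baseline)/baseline with the
baseline floored at 0.1 Hz to avoid division blow-ups — the exact formula
of the "proportional difference" is unstated).

Long-RT trials deserve one note: a movement-aligned window cannot always
contain a full 1 s pre-cue baseline. The per-trial baseline window is
clamped to the aligned support and falls back to the earliest 500 ms of the
trace when the cue precedes the window entirely.

## Extracellular and behavioral stages

Unit rate changes convolve spike times with a 200 ms Gaussian kernel
(unit-area per spike, truncated at ±4 SD with tapering so rates integrate
exactly to spike counts), subtract the 200 ms pre-cue baseline epoch from
the −100..+100 ms peri-movement epoch per trial, and bootstrap the mean
across trials; depth inclusion is 500–1200 µm; spike width is
trough-to-peak. The muscimol diffusion check normalizes each unit's binned
rate to its pre-injection baseline and correlates suppression with distance
from the injection center over time.

The motion index is the per-frame-pair sum of squared pixel gray-level
differences over the forelimb ROI. Baseline statistics come from
inter-trial frames at least 1 s from any event (the baseline epoch is
unspecified; this is our choice); movement calls require MI above
mean + 3 SD within 500 ms of the event (10 SD for licks). Push-like
movements have an initial 50 ms paw-trajectory vector between 170° and 210°
inclusive (0° = image-right, counterclockwise; the camera frame is
arbitrary, only self-consistency with the generator matters; "between" is
read inclusively for determinism). Push probabilities are corrected by
subtracting the shutter-only control rate, clipped at zero.

## Spatial maps

Spread profiles threshold fluorescence at the pixel value equivalent to an
EC₂₀ concentration under the stated intensity∝concentration assumption (the
EC₂₀ itself is a free calibration input, default 0.2× the injected
concentration equivalent); the modal spread intersects the per-animal masks
after integer-pixel alignment of injection centers (no rotation or
scaling). Channel overlap is the elementwise √a·√b smoothed with a 2-D
Gaussian of SD 5 pixels, renormalized at borders so constants are preserved.

## Statistics, seeds, and numerical choices

* Bootstrap CIs are percentile intervals, 10,000 resamples, 95% by default.
  When several measurements come from one animal, observations are
  resampled with probability proportional to per-animal weights.
* All Monte-Carlo entry points take explicit seeds; `run_experiment`
  expands one run seed into fixed per-stage seeds so stages are
  independently reproducible, and two runs from the same configuration
  produce bit-identical reports. Units that must be statistically
  independent (FOVs, cells) never receive adjacent integer seeds: R's
  Mersenne-Twister initialization leaves measurable correlation between
  streams seeded with consecutive integers, so the per-stage derivation
  spaces unit seeds by a large stride.
* Intervals are half-open `[lo, hi)`; time is in seconds; alignment puts
  t = 0 at the event (movement or cue); frames are stamped at frame start.
* Savitzky–Golay smoothing of equal-length trial sets is applied through a
  cached linear operator (identical to the per-trial filter, row-wise).

### Problem sizes

The simulation-based checks in the test suite and `scripts/acceptance.R`
use the calibration cohort the study itself prescribes (100 cells × 30
trials), 100 simulated FOV datasets per population model, 300 simulated
multi-FOV experiments for the ANOVA level (a ±2-point band around 95%
cannot be resolved on 100 runs: even a perfectly calibrated test lands
outside it roughly a quarter of the time), 1,000-cell null cohorts for the
classification false-positive rate, and 1,000 null simulations per type-I
check. Sessions default to 60–80 cued trials, in the range of a ~30-minute
behavioral session at a 4–6 s ITI.

## Known limitations

* The SSF detector's noise behavior depends on the noise spectrum; the
  calibration absorbs its bias under the generator's noise model, and a
  FOV-specific correction should be recomputed per dataset, as done here.
* The discrimination rule assumes a single homogeneous response model per
  FOV; mixed populations will be classified by their dominant component.
* The exclusion rule, the FOV inclusion floor, the decimation target, the
  MI baseline epoch, and the proportional-rate-change formula are
  implementation choices where the protocol is silent; each is flagged
  above and exposed as a parameter.
* Weighted bootstrap resampling treats weights as sampling probabilities;
  alternative weighted-statistic schemes would differ at extreme weight
  ratios.
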