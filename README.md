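# perimove

Peri-movement timing analysis of neural population signals.

## The problem

In cued movement tasks, neural activity recorded around movement onset can
reflect at least three different trial-to-trial codes, with very different
interpretations:

* **model i** — a *movement-locked* signal: activity rises at a fixed
  latency before movement onset, independent of reaction time (RT);
* **model ii** — a *cue-locked* signal: activity rises at the go cue with a
  fixed rise time and plateaus until movement;
* **model iii** — a *ramp-to-threshold* signal: activity ramps from cue to
  movement, so its slope encodes RT.

Aligned to movement, the models separate by how onset latency depends on
RT: model i predicts slope ≈ 0, models ii/iii slope ≈ −1 (and ii/iii
separate by whether the activity *peak* tracks the cue or the movement).

`perimove` implements the complete analysis chain needed to make that
decision on calcium-imaging data — ΔF/F₀ normalization (F₀ = bottom 5th
percentile of the 1 Hz low-passed trace), Friedman-test response
classification with Tukey–Kramer post hoc (250 ms bins, −0.5 to +1.5 s,
p < 0.01), slope-sum-function onset detection (10% of peak, 375 ms window,
Savitzky–Golay 27 frames order 2) calibrated on simulated ramps (100 cells
× 30 trials, 0.5 s rise), 10,000-sample bootstrap onset estimates with an
IQR exclusion rule, RT-split comparisons (short/medium/long at 350/900 ms)
with one-way ANOVA, and the model discrimination itself — together with the
surrounding stages of such a study: subthreshold membrane-potential
trajectory analysis for whole-cell recordings (spike clipping at −1..+9 ms
peri-threshold, ΔVm trajectories, 10% rise-time onsets, muscimol pre/post
AUC ratios), peri-event firing-rate change detection for sorted units
(200 ms Gaussian kernels, bootstrap CI against zero), behavioral
motion-index analysis (MI = Σ(c_{f+1,i} − c_{f,i})², 3 SD / 10 SD
thresholds, 170°–210° push vectors, error-corrected push probabilities),
and image-domain quantification of pharmacological spread (EC₂₀-equivalent
thresholding, modal spread) and dual-channel overlap (√a·√b, SD = 5 px
smoothing).

Because raw data of this kind are typically unavailable, the package ships
a synthetic-data generator (`simulate_trials`, `simulate_calcium`,
`simulate_vm`, `simulate_spiketrains`, `simulate_motion_frames`,
`simulate_spread_images`) that emulates every input modality with ground
truth, so each stage is verifiable by parameter recovery. It is first-class,
tested code — see the methods vignette (`vignettes/perimove-methods.Rmd`)
for what it does and does not emulate.

## Worked example

Simulate one imaged field of view under the movement-locked model
(true latency −300 ms), calibrate the onset detector at the imaging noise
level, and run the analysis:

```r
library(perimove)

spec    <- session_spec(n_trials = 60, seed = 42)
trials  <- simulate_trials(spec)
model   <- population_model_spec("i", onset_lag = -0.3, amplitude = 0.5,
                                 noise_sd = 0.05)
calcium <- simulate_calcium(trials, n_rois = 6, model, seed = 43)

cal <- calibrate_onset_detector(noise_sd = 0.05, seed = 44)
fov <- analyze_fov(calcium, trials, correction = cal$correction,
                   n_boot = 10000, seed = 45)
fov$cells[, c("roi", "category", "friedman_p", "median_onset", "iqr")]
```

```
  roi       category friedman_p median_onset   iqr
1   1 early_increase   4.17e-45       -0.343 0.075
2   2 early_increase   6.41e-45       -0.293 0.050
3   3 early_increase   5.14e-45       -0.293 0.025
4   4 early_increase   3.39e-45       -0.293 0.025
5   5 early_increase   1.95e-45       -0.293 0.050
6   6 early_increase   2.45e-45       -0.268 0.000
```

All six cells classify as early-increasing, and the population median onset
(−293 ms) recovers the generator's −300 ms latency within half a frame. The
model discrimination then regresses per-trial onsets and near-peak times on
RT:

```r
push <- trials[trials$outcome == "push", ]
win  <- c(-min(3.5, max(push$reaction_time) + 0.6), 1.5)
feats <- do.call(rbind, lapply(1:6, function(r) {
  d  <- compute_dff(calcium$F[, r], 40)$dff
  al <- align_trials(d, calcium$frame_times, push$movement_time, win)
  trial_onset_table(al$mat, al$rel_times, push$reaction_time)
}))
discriminate_model(feats)
```

```
verdict: model i (onset slope 0.00, near-peak slope 0.00, 198 trials)
```

A movement-aligned onset slope of ~0 versus RT is the movement-locked
signature; a cue-locked or ramping population would show slope ≈ −1, and the
near-peak slope would then separate the two (≈ −1 for a cue-locked plateau,
≈ 0 for a ramp peaking at movement).

`run_experiment(default_config(seed = 1))` chains the whole pipeline —
generation, calibration, classification, onsets, RT ANOVA, discrimination,
ground-truth recovery — into one reproducible report, bit-identical across
runs for the same configuration.

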