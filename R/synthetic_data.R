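#' Session specification for the cued lever-push task
#'
#' Bundles the behavioral parameters of a simulated session: trials are cued
#' after a randomized 4-6 s inter-trial interval, reaction times are
#' log-normal around a median of 0.32 s, and a fixed fraction of cues is
#' missed (default 0.363, i.e. 63.7% task success).
#'
#' @param n_trials Number of cued trials.
#' @param iti_range Inter-trial interval bounds in seconds (uniform draw).
#' @param rt_median Median reaction time in seconds.
#' @param rt_dispersion Log-scale SD of the reaction-time distribution. The
#'   default 1.0 populates all three reaction-time categories
#'   (short/medium/long) at realistic session sizes.
#' @param miss_prob Probability that a cued trial is a miss.
#' @param frame_rate Imaging frame rate in Hz.
#' @param seed Integer seed.
#' @return List of class `session_spec`.
#' @export
session_spec <- function(n_trials = 60, iti_range = c(4, 6), rt_median = 0.32,
                         rt_dispersion = 1.0, miss_prob = 0.363,
                         frame_rate = 40, seed = 1) {
  stopifnot(n_trials >= 1, length(iti_range) == 2, iti_range[1] > 0,
            iti_range[1] < iti_range[2], rt_median > 0, rt_dispersion > 0,
            miss_prob >= 0, miss_prob <= 1, frame_rate > 0)
  structure(list(n_trials = as.integer(n_trials), iti_range = iti_range,
                 rt_median = rt_median, rt_dispersion = rt_dispersion,
                 miss_prob = miss_prob, frame_rate = frame_rate,
                 seed = as.integer(seed)),
            class = "session_spec")
}

#' Simulate a trial table for a cued-movement session
#'
#' Draws inter-trial intervals i.i.d. uniform over `iti_range`, log-normal
#' reaction times, and Bernoulli miss outcomes. Push trials get a movement
#' time (cue + RT) and a reward time; miss trials have no movement. Trial
#' times are strictly increasing. Deterministic for a fixed seed.
#'
#' @param spec A [session_spec()].
#' @return Data frame with columns `trial_id`, `cue_time`, `movement_time`,
#'   `reaction_time`, `outcome` (`"push"` or `"miss"`), `reward_time`.
#'   Missing events are `NA`.
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- spec$n_trials
  iti <- stats::runif(n, spec$iti_range[1], spec$iti_range[2])
  rt <- stats::rlnorm(n, meanlog = log(spec$rt_median), sdlog = spec$rt_dispersion)
  miss <- stats::runif(n) < spec$miss_prob
  # response window + consummatory period before the next ITI starts
  trial_span <- 3.5
  cue <- numeric(n)
  t <- 2.0
  for (i in seq_len(n)) {
    cue[i] <- t + iti[i]
    t <- cue[i] + trial_span
  }
  movement <- ifelse(miss, NA_real_, cue + rt)
  reward <- ifelse(miss, NA_real_, movement + 0.5)
  data.frame(
    trial_id = seq_len(n),
    cue_time = cue,
    movement_time = movement,
    reaction_time = ifelse(miss, NA_real_, rt),
    outcome = ifelse(miss, "miss", "push"),
    reward_time = reward,
    stringsAsFactors = FALSE
  )
}

#' Population response model specification
#'
#' The three competing trial-to-trial response models:
#' \describe{
#'   \item{i}{movement-locked: a transient starting at a fixed (negative) lag
#'     before movement onset, rising linearly over `rise_time`.}
#'   \item{ii}{cue-locked: a transient starting at the cue, rising over
#'     `rise_time` and holding a plateau until movement.}
#'   \item{iii}{ramp-to-threshold: a ramp starting at the cue that reaches a
#'     fixed level exactly at movement onset, so its slope encodes the
#'     reaction time.}
#' }
#'
#' @param model `"i"`, `"ii"` or `"iii"`.
#' @param onset_lag Model-i onset relative to movement (seconds, negative).
#' @param amplitude Transient amplitude in dF/F0 units.
#' @param rise_time Rise time in seconds (default 0.5, GCaMP6s-like).
#' @param noise_sd Additive noise SD in dF/F0 units.
#' @export
population_model_spec <- function(model = c("i", "ii", "iii"), onset_lag = -0.3,
                                  amplitude = 0.5, rise_time = 0.5,
                                  noise_sd = 0.05) {
  model <- match.arg(model)
  stopifnot(rise_time > 0, noise_sd >= 0)
  if (amplitude <= 0) stop("amplitude must be positive for increase-type cells")
  structure(list(model = model, onset_lag = onset_lag, amplitude = amplitude,
                 rise_time = rise_time, noise_sd = noise_sd),
            class = "population_model_spec")
}

# dF/F transient for one trial on absolute frame times; linear rise from
# onset over `rise` to `amp`, optional plateau to `hold_until`, then
# single-exponential decay with time constant `tau`.
ramp_transient <- function(frame_times, onset, rise, amp, hold_until = NULL, tau = 1.0) {
  peak_t <- onset + rise
  plateau_end <- if (is.null(hold_until)) peak_t else max(peak_t, hold_until)
  y <- numeric(length(frame_times))
  ris <- frame_times >= onset & frame_times < peak_t
  y[ris] <- amp * (frame_times[ris] - onset) / rise
  pla <- frame_times >= peak_t & frame_times < plateau_end
  y[pla] <- amp
  dec <- frame_times >= plateau_end
  y[dec] <- amp * exp(-(frame_times[dec] - plateau_end) / tau)
  y
}

#' Simulate raw calcium fluorescence for a population of ROIs
#'
#' Each push trial of each ROI receives a GCaMP6s-like transient: a linear
#' ramp with a defined onset time, rise over `model$rise_time` to
#' `model$amplitude`, then single-exponential decay. Onset placement follows
#' the population model (see [population_model_spec()]). Miss trials carry no
#' transient. Gaussian noise of SD `model$noise_sd` (dF/F0 units) is added
#' per frame, and traces are offset to a positive raw-fluorescence baseline.
#'
#' @param trials Trial table from [simulate_trials()].
#' @param n_rois Number of ROIs sharing the frame clock (one FOV).
#' @param model A [population_model_spec()].
#' @param frame_rate Frames per second (default 40).
#' @param decay_tau Decay time constant in seconds (default 1.0).
#' @param f_baseline Baseline raw fluorescence (arbitrary units, default 100).
#' @param seed Integer seed.
#' @return List of class `calcium_set`: `frame_times`, `F` (frames x ROIs
#'   matrix of raw fluorescence), `frame_rate`, `f_baseline`, `model`, and
#'   `ground_truth` (data frame: `roi`, `trial_id`, `true_onset` absolute
#'   seconds, `true_onset_rel` relative to movement, `true_peak_time`,
#'   `true_class`).
#' @export
simulate_calcium <- function(trials, n_rois, model, frame_rate = 40,
                             decay_tau = 1.0, f_baseline = 100, seed = 1) {
  stopifnot(inherits(model, "population_model_spec"), n_rois >= 1)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dur <- max(trials$cue_time, trials$reward_time, na.rm = TRUE) + 3
  frame_times <- seq(0, dur, by = 1 / frame_rate)
  push <- trials[trials$outcome == "push", ]
  gt <- vector("list", n_rois)
  F <- matrix(0, nrow = length(frame_times), ncol = n_rois)
  for (r in seq_len(n_rois)) {
    dff <- numeric(length(frame_times))
    if (nrow(push) > 0) {
      onset <- switch(model$model,
        i = push$movement_time + model$onset_lag,
        ii = push$cue_time,
        iii = push$cue_time)
      rise <- switch(model$model,
        i = rep(model$rise_time, nrow(push)),
        ii = rep(model$rise_time, nrow(push)),
        iii = pmax(push$reaction_time, 1 / frame_rate))
      hold <- switch(model$model,
        i = NULL,
        ii = push$movement_time,
        iii = NULL)
      for (k in seq_len(nrow(push))) {
        # transients are local; evaluate on a slice around the trial only
        end_t <- max(onset[k] + rise[k],
                     if (is.null(hold)) -Inf else hold[k]) + 8 * decay_tau
        i0 <- max(1L, findInterval(onset[k], frame_times))
        i1 <- min(length(frame_times), findInterval(end_t, frame_times) + 1L)
        idx <- i0:i1
        dff[idx] <- dff[idx] + ramp_transient(frame_times[idx], onset[k], rise[k],
                                              model$amplitude,
                                              if (is.null(hold)) NULL else hold[k],
                                              decay_tau)
      }
      gt[[r]] <- data.frame(
        roi = r, trial_id = push$trial_id, true_onset = onset,
        true_onset_rel = onset - push$movement_time,
        true_peak_time = onset + rise,
        true_class = "early_increase", stringsAsFactors = FALSE)
    } else {
      gt[[r]] <- data.frame(roi = integer(0), trial_id = integer(0),
                            true_onset = numeric(0), true_onset_rel = numeric(0),
                            true_peak_time = numeric(0), true_class = character(0))
    }
    noise <- stats::rnorm(length(frame_times), 0, model$noise_sd)
    F[, r] <- f_baseline * (1 + dff + noise)
  }
  structure(list(frame_times = frame_times, F = F, frame_rate = frame_rate,
                 f_baseline = f_baseline, model = model,
                 ground_truth = do.call(rbind, gt)),
            class = "calcium_set")
}

#' Simulate a whole-cell membrane-potential recording
#'
#' Builds a 20 kHz voltage trace around a resting potential with, per push
#' trial, a smooth subthreshold deflection starting at a fixed pre-movement
#' lag, plus stereotyped action-potential waveforms inserted at a rate that
#' increases with depolarization, on a pink-plus-white noise background.
#' Ground-truth spike threshold times and the deflection profile are
#' recorded.
#'
#' The inserted spike waveform rises linearly from the threshold kink to its
#' peak in 0.4 ms, falls to an after-hyperpolarization and recovers, so the
#' maximal second derivative before the peak sits at the ground-truth
#' threshold time.
#'
#' @param trials Trial table.
#' @param profile `"depolarizing"`, `"hyperpolarizing"` or `"none"`.
#' @param sample_rate Samples per second (default 20000).
#' @param deflection_amp Peak deflection in mV (positive; sign follows
#'   `profile`).
#' @param deflection_lag Deflection onset relative to movement (s, negative).
#' @param rise Deflection 0-to-peak time in seconds.
#' @param resting_vm Resting potential in mV.
#' @param baseline_rate Baseline firing rate in Hz.
#' @param rate_gain Extra firing rate per mV of depolarization (Hz/mV).
#' @param noise_sd White-noise SD in mV (0 disables all noise).
#' @param seed Integer seed.
#' @return List of class `vm_recording_sim`: `times`, `vm`, `sample_rate`,
#'   `ground_truth` (list with `spike_threshold_times`, `spike_peak_times`,
#'   `deflection_onsets`, `deflection_amp`, `profile`, `dvm` trace).
#' @export
simulate_vm <- function(trials, profile = c("depolarizing", "hyperpolarizing", "none"),
                        sample_rate = 20000, deflection_amp = 5,
                        deflection_lag = -0.2, rise = 0.3, resting_vm = -65,
                        baseline_rate = 1, rate_gain = 1.5, noise_sd = 0.3,
                        seed = 1) {
  profile <- match.arg(profile)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dur <- max(trials$cue_time, trials$reward_time, na.rm = TRUE) + 2
  dt <- 1 / sample_rate
  times <- seq(0, dur, by = dt)
  n <- length(times)
  sgn <- switch(profile, depolarizing = 1, hyperpolarizing = -1, none = 0)
  push <- trials[trials$outcome == "push", ]
  defl <- numeric(n)
  onsets <- numeric(0)
  if (sgn != 0 && nrow(push) > 0) {
    for (k in seq_len(nrow(push))) {
      on_t <- push$movement_time[k] + deflection_lag
      onsets <- c(onsets, on_t)
      # smooth raised-cosine rise, hold 0.3 s, raised-cosine fall over 0.5 s
      rel <- times - on_t
      up <- rel >= 0 & rel < rise
      defl[up] <- defl[up] + 0.5 * (1 - cos(pi * rel[up] / rise))
      hold <- rel >= rise & rel < rise + 0.3
      defl[hold] <- defl[hold] + 1
      dn <- rel >= rise + 0.3 & rel < rise + 0.8
      defl[dn] <- defl[dn] + 0.5 * (1 + cos(pi * (rel[dn] - rise - 0.3) / 0.5))
    }
    defl <- sgn * deflection_amp * defl
  }
  vm <- resting_vm + defl
  if (noise_sd > 0) {
    white <- stats::rnorm(n, 0, noise_sd)
    # slow (pink-like) component: low-passed noise, ~2 Hz corner
    slow <- stats::filter(stats::rnorm(n, 0, noise_sd), 0.999, method = "recursive")
    slow <- as.numeric(slow) / stats::sd(as.numeric(slow)) * noise_sd
    vm <- vm + white + slow
  }
  # inhomogeneous Poisson spiking driven by depolarization
  rate <- baseline_rate + rate_gain * pmax(defl, 0)
  spike_thr <- numeric(0)
  if (max(rate) > 0) {
    rmax <- max(rate)
    cand <- sort(stats::runif(stats::rpois(1, rmax * dur), 0, dur))
    keep <- stats::runif(length(cand)) < rate[pmin(n, floor(cand / dt) + 1)] / rmax
    spike_thr <- cand[keep]
    # enforce a 5 ms refractory period
    if (length(spike_thr) > 1) {
      ok <- c(TRUE, diff(spike_thr) > 0.005)
      spike_thr <- spike_thr[ok]
    }
    spike_thr <- spike_thr[spike_thr > 0.01 & spike_thr < dur - 0.01]
  }
  wf <- spike_waveform(sample_rate)
  thr_idx <- round(spike_thr / dt) + 1
  spike_thr <- times[thr_idx]
  for (i in thr_idx) {
    j <- i:min(n, i + length(wf$shape) - 1L)
    vm[j] <- vm[j] + wf$shape[seq_along(j)]
  }
  structure(list(
    times = times, vm = vm, sample_rate = sample_rate,
    ground_truth = list(
      spike_threshold_times = spike_thr,
      spike_peak_times = spike_thr + wf$peak_offset,
      deflection_onsets = onsets,
      deflection_amp = sgn * deflection_amp,
      profile = profile,
      dvm = defl)),
    class = "vm_recording_sim")
}

# Stereotyped AP waveform: linear rise 0->48 mV over 0.4 ms, linear fall to
# -5 mV AHP at 1.4 ms, linear recovery to 0 at 4 ms.
spike_waveform <- function(sample_rate) {
  dt <- 1 / sample_rate
  t <- seq(0, 0.004, by = dt)
  shape <- numeric(length(t))
  ris <- t <= 0.0004
  shape[ris] <- 48 * t[ris] / 0.0004
  fal <- t > 0.0004 & t <= 0.0014
  shape[fal] <- 48 - 53 * (t[fal] - 0.0004) / 0.001
  rec <- t > 0.0014
  shape[rec] <- -5 * (1 - (t[rec] - 0.0014) / 0.0026)
  list(shape = shape, peak_offset = 0.0004)
}

#' Simulate spike trains with a peri-movement rate step
#'
#' Inhomogeneous Poisson process: `baseline_rate` everywhere except inside a
#' peri-movement window of each push trial, where the rate is
#' `baseline_rate * response_gain`.
#'
#' @param trials Trial table.
#' @param baseline_rate Baseline rate in Hz (> 0).
#' @param response_gain Multiplicative rate factor inside the window.
#' @param window Two-element window relative to movement onset (seconds).
#' @param n_units Number of independent units.
#' @param seed Integer seed.
#' @return List of class `spiketrain_set`: `spikes` (list of per-unit sorted
#'   spike-time vectors), `duration`, `ground_truth` (baseline rate, gain,
#'   window, per-trial response intervals).
#' @export
simulate_spiketrains <- function(trials, baseline_rate, response_gain = 1,
                                 window = c(-0.1, 0.1), n_units = 1, seed = 1) {
  stopifnot(baseline_rate > 0, response_gain >= 0)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dur <- max(trials$cue_time, trials$reward_time, na.rm = TRUE) + 2
  mv <- trials$movement_time[!is.na(trials$movement_time)]
  iv <- cbind(mv + window[1], mv + window[2])
  rmax <- baseline_rate * max(1, response_gain)
  spikes <- lapply(seq_len(n_units), function(u) {
    cand <- sort(stats::runif(stats::rpois(1, rmax * dur), 0, dur))
    if (length(cand) == 0) return(numeric(0))
    inwin <- rep(FALSE, length(cand))
    for (k in seq_len(nrow(iv)))
      inwin <- inwin | (cand >= iv[k, 1] & cand < iv[k, 2])
    r <- ifelse(inwin, baseline_rate * response_gain, baseline_rate)
    cand[stats::runif(length(cand)) < r / rmax]
  })
  structure(list(spikes = spikes, duration = dur,
                 ground_truth = list(baseline_rate = baseline_rate,
                                     response_gain = response_gain,
                                     window = window, intervals = iv)),
            class = "spiketrain_set")
}

#' Simulate behavioral video frames for motion-index analysis
#'
#' Frames are i.i.d. Gaussian pixel noise around a mid-gray level; during
#' ground-truth movement epochs (starting at each push trial's movement
#' onset) large-amplitude frame-to-frame pixel changes are injected.
#'
#' @param trials Trial table.
#' @param roi_pixels Number of pixels in the forelimb ROI.
#' @param frame_rate Video frame rate in Hz (default 100).
#' @param movement_amp Amplitude of injected pixel changes (gray levels);
#'   0 disables movement epochs entirely.
#' @param noise_sd Pixel noise SD (gray levels).
#' @param epoch_dur Movement-epoch duration in seconds.
#' @param seed Integer seed.
#' @return List of class `motion_frames`: `frames` (n_frames x roi_pixels),
#'   `frame_times`, `ground_truth` (data frame `trial_id`, `t0`, `t1`).
#' @export
simulate_motion_frames <- function(trials, roi_pixels = 200, frame_rate = 100,
                                   movement_amp = 40, noise_sd = 2,
                                   epoch_dur = 0.3, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  dur <- max(trials$cue_time, trials$reward_time, na.rm = TRUE) + 2
  frame_times <- seq(0, dur, by = 1 / frame_rate)
  nf <- length(frame_times)
  frames <- matrix(128 + stats::rnorm(nf * roi_pixels, 0, noise_sd),
                   nrow = nf, ncol = roi_pixels)
  push <- trials[trials$outcome == "push", ]
  gt <- data.frame(trial_id = integer(0), t0 = numeric(0), t1 = numeric(0))
  if (movement_amp > 0 && nrow(push) > 0) {
    gt <- data.frame(trial_id = push$trial_id,
                     t0 = push$movement_time,
                     t1 = push$movement_time + epoch_dur)
    for (k in seq_len(nrow(gt))) {
      sel <- which(frame_times >= gt$t0[k] & frame_times < gt$t1[k])
      frames[sel, ] <- frames[sel, ] +
        matrix(stats::rnorm(length(sel) * roi_pixels, 0, movement_amp),
               nrow = length(sel))
    }
  }
  structure(list(frames = frames, frame_times = frame_times, ground_truth = gt),
            class = "motion_frames")
}

#' Simulate injection-spread fluorescence images
#'
#' Each image is a radially symmetric Gaussian blob (peak at the injection
#' center, scale `sigma_px`) plus optional pixel noise; the injection center
#' is jittered per mouse and recorded as ground truth.
#'
#' @param n_mice Number of images.
#' @param sigma_px Gaussian blob scale in pixels.
#' @param center_jitter SD of the per-mouse center jitter in pixels.
#' @param peak Peak gray level.
#' @param size Image side length in pixels (odd).
#' @param noise_sd Pixel noise SD (gray levels).
#' @param seed Integer seed.
#' @return List of class `spread_images`: `images` (list of matrices),
#'   `centers` (n x 2, x/y pixel coordinates), `ground_truth` (data frame
#'   `mouse`, `sigma_px`, `cx`, `cy`, `peak`).
#' @export
simulate_spread_images <- function(n_mice, sigma_px = 15, center_jitter = 0,
                                   peak = 255, size = 101, noise_sd = 0, seed = 1) {
  stopifnot(n_mice >= 1, sigma_px > 0, size >= 5)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  c0 <- (size + 1) / 2
  images <- vector("list", n_mice)
  centers <- matrix(0, n_mice, 2)
  for (m in seq_len(n_mice)) {
    cx <- c0 + round(stats::rnorm(1, 0, center_jitter))
    cy <- c0 + round(stats::rnorm(1, 0, center_jitter))
    xs <- matrix(rep(seq_len(size), each = size), size)   # column index
    ys <- matrix(rep(seq_len(size), times = size), size)  # row index
    img <- peak * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma_px^2))
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size)
    images[[m]] <- img
    centers[m, ] <- c(cx, cy)
  }
  structure(list(images = images, centers = centers,
                 ground_truth = data.frame(mouse = seq_len(n_mice),
                                           sigma_px = sigma_px,
                                           cx = centers[, 1], cy = centers[, 2],
                                           peak = peak)),
            class = "spread_images")
}
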