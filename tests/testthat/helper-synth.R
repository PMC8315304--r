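# Small fixtures shared across test files; everything is generated in code.

quick_trials <- function(n = 20, seed = 1, ...) {
  simulate_trials(session_spec(n_trials = n, seed = seed, ...))
}

# Aligned dF/F matrix for one ROI of a calcium set (push trials only).
aligned_dff <- function(calcium, trials, roi = 1, window = c(-1.5, 1.5)) {
  push <- trials[trials$outcome == "push", ]
  d <- compute_dff(calcium$F[, roi], calcium$frame_rate)$dff
  al <- align_trials(d, calcium$frame_times, push$movement_time, window)
  al
}

# Movement-aligned features (onset/t90 vs RT) pooled over ROIs, as used by
# the model discrimination.
model_features <- function(model = "i", seed = 1, n_trials = 40, n_rois = 3,
                           noise_sd = 0.05, onset_lag = -0.3) {
  tr <- quick_trials(n_trials, seed)
  m <- population_model_spec(model, onset_lag = onset_lag, noise_sd = noise_sd)
  ca <- simulate_calcium(tr, n_rois, m, seed = seed + 1000)
  push <- tr[tr$outcome == "push", ]
  win <- c(-min(3.5, max(push$reaction_time) + 0.6), 1.5)
  do.call(rbind, lapply(seq_len(n_rois), function(r) {
    d <- compute_dff(ca$F[, r], 40)$dff
    al <- align_trials(d, ca$frame_times, push$movement_time, win)
    trial_onset_table(al$mat, al$rel_times, push$reaction_time)
  }))
}
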