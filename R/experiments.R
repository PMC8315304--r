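#' Calibration recovery: correct on one cohort, score on a fresh one
#'
#' Runs the detector calibration at a given noise level (100 cells x 30
#' trials of 0.5 s ramps by default), then generates an independent cohort
#' of ramp trials at the same noise level and reports the post-correction
#' median onset bias.
#'
#' @param noise_sd Per-frame noise SD in dF/F0 units.
#' @param n_eval Number of fresh evaluation trials (default 3000).
#' @param seed Integer seed; calibration and evaluation use derived,
#'   distinct streams.
#' @param ... Passed to [calibrate_onset_detector()].
#' @return List: `correction` (seconds), `post_bias` (seconds, median
#'   detected-minus-true on the fresh cohort after correction),
#'   `detect_frac`.
#' @export
evaluate_calibration <- function(noise_sd, n_eval = 3000, seed = 1, ...) {
  cal <- calibrate_onset_detector(noise_sd,
                                  seed = derive_seed(seed, "calibration"), ...)
  old <- local_seed(derive_seed(seed, "analysis"))
  on.exit(restore_seed(old), add = TRUE)
  fr <- 40
  times <- seq(-2, 1.5, by = 1 / fr)
  trs <- t(vapply(seq_len(n_eval), function(k)
    sim_ramp_trial(times, stats::runif(1, -0.6, -0.1), 0.5, 0.5, noise_sd, fr),
    numeric(length(times) + 1)))
  det <- detect_onset_mat(trs[, -1, drop = FALSE], times)
  err <- det - trs[, 1]
  list(correction = cal$correction,
       post_bias = stats::median(err, na.rm = TRUE) - cal$correction,
       detect_frac = mean(!is.na(err)))
}

#' Simulate one FOV dataset and discriminate its population model
#'
#' Generates a session and calcium data under the requested model, extracts
#' per-trial rise-time features pooled across ROIs, and runs
#' [discriminate_model()].
#'
#' @param model Generating model (`"i"`, `"ii"`, `"iii"`).
#' @param seed Integer seed.
#' @param n_trials Cued trials in the session (default 60).
#' @param n_rois ROIs per FOV (default 3).
#' @param onset_lag Model-i latency (seconds, default -0.3).
#' @param noise_sd Imaging noise (dF/F0 units, default 0.05).
#' @return A `model_verdict` (see [discriminate_model()]).
#' @export
discrimination_experiment <- function(model, seed, n_trials = 60, n_rois = 3,
                                      onset_lag = -0.3, noise_sd = 0.05) {
  tr <- simulate_trials(session_spec(n_trials = n_trials, seed = seed))
  m <- population_model_spec(model, onset_lag = onset_lag, noise_sd = noise_sd)
  ca <- simulate_calcium(tr, n_rois, m, seed = derive_seed(seed, "calcium"))
  push <- tr[tr$outcome == "push", ]
  win <- c(-min(3.5, max(push$reaction_time) + 0.6), 1.5)
  feats <- do.call(rbind, lapply(seq_len(n_rois), function(r) {
    d <- compute_dff(ca$F[, r], ca$frame_rate)$dff
    al <- align_trials(d, ca$frame_times, push$movement_time, win)
    trial_onset_table(al$mat, al$rel_times, push$reaction_time)
  }))
  discriminate_model(feats)
}

#' Simulate a multi-FOV experiment and test onsets across RT groups
#'
#' Builds several FOVs (each with its own session and a true latency drawn
#' around `onset_lag` with SD `lag_sd`, reflecting across-population latency
#' heterogeneity), detects per-trial onsets, splits them by reaction-time
#' category, and runs the across-group one-way ANOVA on the per-FOV group
#' means. Under a movement-locked model the group means share one mean and
#' the ANOVA p-value is uniform.
#'
#' @param seed Integer seed.
#' @param model Generating model (default `"i"`).
#' @param n_fovs,n_rois,n_trials Experiment dimensions.
#' @param onset_lag Mean latency (seconds).
#' @param lag_sd Across-FOV latency SD (seconds, default 0.05).
#' @param noise_sd Imaging noise (dF/F0 units).
#' @param min_trials FOV-inclusion floor per RT category.
#' @return `anova_p`, or `NA` when fewer than two groups are populated.
#' @export
rt_anova_experiment <- function(seed, model = "i", n_fovs = 6, n_rois = 4,
                                n_trials = 80, onset_lag = -0.3, lag_sd = 0.05,
                                noise_sd = 0.05, min_trials = 5) {
  old <- local_seed(derive_seed(seed, "analysis"))
  lags <- stats::rnorm(n_fovs, onset_lag, lag_sd)
  restore_seed(old)
  dat <- lapply(seq_len(n_fovs), function(f) {
    tr <- simulate_trials(session_spec(n_trials = n_trials,
                                       seed = derive_seed(seed, "trials", f)))
    m <- population_model_spec(model, onset_lag = lags[f], noise_sd = noise_sd)
    ca <- simulate_calcium(tr, n_rois, m,
                           seed = derive_seed(seed, "calcium", f))
    push <- tr[tr$outcome == "push", ]
    # shared interpolation stencil across ROIs (same events, same clock),
    # one batched detection call for the whole FOV
    dt <- 1 / ca$frame_rate
    rel <- seq(-1.5, 1.5, by = dt)
    pos <- outer(push$movement_time, rel, "+")
    pos <- (pos - ca$frame_times[1]) / dt + 1
    i0 <- floor(pos)
    w <- pos - i0
    big <- do.call(rbind, lapply(seq_len(n_rois), function(r) {
      d <- compute_dff(ca$F[, r], ca$frame_rate)$dff
      matrix(d[i0] * (1 - w) + d[i0 + 1] * w, nrow(push), length(rel))
    }))
    ons <- detect_onset_mat(big, rel)
    list(onsets = matrix(ons, nrow = n_rois, byrow = TRUE), trials = tr,
         min_count = min(table(factor(split_by_rt(push),
                                      levels = c("short", "medium", "long")))))
  })
  # one experiment-wide subsample count so every FOV/category estimate has
  # the same sampling distribution under the null
  counts <- vapply(dat, `[[`, numeric(1), "min_count")
  keep <- which(counts >= min_trials)
  if (length(keep) < 2) return(NA_real_)
  m_common <- min(counts[keep])
  rt_tab <- do.call(rbind, lapply(keep, function(f)
    fov_rt_onsets(dat[[f]]$onsets, dat[[f]]$trials, fov = f,
                  n_sub = m_common)))
  tryCatch(compare_onsets_across_rt(rt_tab, min_trials = min_trials)$anova_p,
           error = function(e) NA_real_)
}

#' Null false-positive rate of the response classification
#'
#' Generates pure-noise cells, runs the Friedman classification and, for
#' cells passing it, the onset-detectability requirement (five detected
#' trial onsets and the bootstrap validity flag), and reports the fraction
#' called responsive.
#'
#' @param n_cells Number of null cells (default 1000).
#' @param n_trials Trials per cell (default 20).
#' @param noise_sd Noise SD in dF/F0 units (default 0.05).
#' @param seed Integer seed.
#' @return Fraction of null cells classified responsive.
#' @export
null_classification_fpr <- function(n_cells = 1000, n_trials = 20,
                                    noise_sd = 0.05, seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  times <- seq(-1.5, 1.5, by = 1 / 40)
  hits <- vapply(seq_len(n_cells), function(i) {
    m <- matrix(stats::rnorm(n_trials * length(times), 0, noise_sd),
                nrow = n_trials)
    cls <- classify_response(m, times)
    if (cls$category == "nonresponsive") return(FALSE)
    est <- bootstrap_onset(detect_onset_mat(m, times), n_boot = 200,
                           seed = i)
    est$valid
  }, logical(1))
  mean(hits)
}
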