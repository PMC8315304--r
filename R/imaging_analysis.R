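#' Normalize a raw fluorescence trace to dF/F0
#'
#' F0 is the bottom 5th percentile of the 1 Hz low-pass-filtered raw signal
#' (zero-phase 4th-order Butterworth), and dF/F0 = (F - F0) / F0.
#'
#' @param raw Raw fluorescence vector (positive).
#' @param frame_rate Frames per second.
#' @return List with `dff`, `f0`, `filtered`.
#' @export
compute_dff <- function(raw, frame_rate) {
  if (length(raw) < 30 * frame_rate)
    stop("need at least 30 s of data")
  filt <- lowpass_zero_phase(raw, frame_rate, cutoff = 1)
  f0 <- stats::quantile(filt, 0.05, names = FALSE)
  if (f0 <= 0) stop("nonpositive baseline")
  list(dff = (raw - f0) / f0, f0 = f0, filtered = filt)
}

# Zero-phase Butterworth low-pass (order 4) with reflective padding so the
# filter is settled at both ends (a constant trace stays constant);
# pass-through when the cutoff is at or above Nyquist.
lowpass_zero_phase <- function(x, fs, cutoff) {
  wn <- cutoff / (fs / 2)
  if (wn >= 1) return(x)
  bf <- signal::butter(4, wn, type = "low")
  n <- length(x)
  pad <- min(n - 1, ceiling(5 * fs / cutoff))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1):(pad + n)]
}

#' Align a trace into a trials x time matrix around per-trial events
#'
#' Linear interpolation onto a common relative time grid; `t = 0` is the
#' event (movement or cue onset).
#'
#' @param x Trace values.
#' @param times Sample times (seconds).
#' @param events Per-trial event times (seconds); `NA` events are dropped.
#' @param window Two-element relative window `c(lo, hi)`.
#' @param dt Relative grid step; defaults to the trace's median sample step.
#' @return List with `mat` (trials x samples), `rel_times`, `trial_idx`
#'   (indices of the retained events).
#' @export
align_trials <- function(x, times, events, window, dt = NULL) {
  keep <- which(!is.na(events))
  if (is.null(dt)) dt <- stats::median(diff(times))
  rel <- seq(window[1], window[2], by = dt)
  mat <- t(vapply(events[keep], function(ev) {
    # interpolate against a local slice only; the full trace can be long
    i0 <- max(1L, findInterval(ev + window[1], times) - 1L)
    i1 <- min(length(times), findInterval(ev + window[2], times) + 2L)
    stats::approx(times[i0:i1], x[i0:i1], xout = ev + rel, rule = 1)$y
  }, numeric(length(rel))))
  list(mat = mat, rel_times = rel, trial_idx = keep)
}

#' Slope sum function of a fluorescence trace
#'
#' Savitzky-Golay smooths the trace (27 frames, polynomial order 2), takes
#' first differences, and sums their positive part over a trailing window
#' (375 ms; 15 frames at 40 Hz). The SSF localizes signal upstrokes: it is
#' zero on non-increasing traces and invariant to additive constants.
#'
#' @param trace Per-trial dF/F trace.
#' @param frame_rate Frames per second.
#' @param window SSF window in seconds (default 0.375).
#' @param sg_frames Savitzky-Golay frame count (odd, default 27).
#' @param sg_order Savitzky-Golay polynomial order (default 2).
#' @param smooth Set `FALSE` to bypass smoothing (diagnostics).
#' @return Numeric SSF, same length as `trace`.
#' @export
slope_sum <- function(trace, frame_rate, window = 0.375, sg_frames = 27,
                      sg_order = 2, smooth = TRUE) {
  w <- max(1L, round(window * frame_rate))
  if (length(trace) <= w) stop("trace shorter than SSF window")
  x <- trace
  if (smooth) {
    n <- min(sg_frames, length(x) - (1 - length(x) %% 2))
    if (n %% 2 == 0) n <- n - 1
    x <- sg_smooth(x, sg_order, n)
  }
  pos <- pmax(diff(x), 0)
  cp <- c(0, cumsum(pos))           # cp[i+1] = sum pos[1..i]
  i <- seq_along(trace)
  # trailing window: positive differences ending at samples i-w+1 .. i
  lo <- pmax(i - w, 1)
  hi <- pmin(i, length(pos) + 1)
  cp[hi] - cp[lo]
}

# Savitzky-Golay smoothing with the projection matrix cached per
# (order, frames): building it involves an SVD and dominates the per-trial
# detection cost otherwise.
.sg_cache <- new.env(parent = emptyenv())
sg_smooth <- function(x, p, n) {
  key <- paste(p, n)
  fm <- .sg_cache[[key]]
  if (is.null(fm)) {
    fm <- signal::sgolay(p = p, n = n)
    .sg_cache[[key]] <- fm
  }
  signal::sgolayfilt(x, fm)
}

# Full linear operator of sg_smooth for traces of length L, cached per
# (L, p, n): smoothing many equal-length trials becomes one matrix product.
sg_operator <- function(L, p, n) {
  key <- paste("op", L, p, n)
  B <- .sg_cache[[key]]
  if (is.null(B)) {
    B <- vapply(seq_len(L), function(j) {
      e <- numeric(L); e[j] <- 1
      sg_smooth(e, p, n)
    }, numeric(L))
    .sg_cache[[key]] <- B
  }
  B
}

# Batch SSF: rows of `mat` are equal-length trials. Identical to slope_sum()
# applied row-wise.
slope_sum_mat <- function(mat, frame_rate, window = 0.375, sg_frames = 27,
                          sg_order = 2, smooth = TRUE) {
  mat <- as.matrix(mat)
  L <- ncol(mat)
  w <- max(1L, round(window * frame_rate))
  if (L <= w) stop("trace shorter than SSF window")
  x <- mat
  if (smooth) {
    n <- min(sg_frames, L - (1 - L %% 2))
    if (n %% 2 == 0) n <- n - 1
    x <- mat %*% t(sg_operator(L, sg_order, n))
  }
  pos <- pmax(x[, -1, drop = FALSE] - x[, -L, drop = FALSE], 0)
  cp <- cbind(0, t(apply(pos, 1, cumsum)))   # cp[, i+1] = sum pos[, 1..i]
  i <- seq_len(L)
  # trailing window: positive differences ending at samples i-w+1 .. i
  lo <- pmax(i - w, 1)
  hi <- pmin(i, L)
  cp[, hi, drop = FALSE] - cp[, lo, drop = FALSE]
}

#' Detect response onsets for a matrix of trials
#'
#' Row-wise equivalent of [detect_onset_trial()] sharing one smoothing
#' operator across trials; each trial's detection is independent of the
#' others.
#'
#' @param mat Trials x samples matrix.
#' @inheritParams detect_onset_trial
#' @return Numeric vector of onsets (seconds), `NA` where undetectable.
#' @export
detect_onset_mat <- function(mat, times, search_window = c(-1, 0.5),
                             threshold_frac = 0.10, noise_floor = NULL, ...) {
  mat <- as.matrix(mat)
  frame_rate <- 1 / stats::median(diff(times))
  ssf <- slope_sum_mat(mat, frame_rate, ...)
  sel <- which(times >= search_window[1] & times <= search_window[2])
  if (length(sel) == 0) stop("empty search window")
  base_idx <- which(times < search_window[1])
  vapply(seq_len(nrow(mat)), function(r) {
    s <- ssf[r, ]
    floor_r <- noise_floor
    if (is.null(floor_r)) {
      # SSF is nonnegative with a positive mean under pure noise, so the
      # floor is baseline mean + 3 SD; a plain 3-SD bound would sit below
      # the noise mean and reject nothing
      floor_r <- if (length(base_idx) >= 3)
        mean(s[base_idx]) + 3 * stats::sd(s[base_idx]) else 0
    }
    m <- max(s[sel])
    if (m <= 0 || m <= floor_r) return(NA_real_)
    times[sel[s[sel] >= threshold_frac * m][1]]
  }, numeric(1))
}

#' Detect the response onset in one trial
#'
#' Onset is the earliest time inside the search window where the SSF reaches
#' `threshold_frac` of its in-window maximum (default 10% of peak). Returns
#' `NA` when the SSF maximum does not clear an absolute noise floor (by
#' default the baseline SSF mean plus three SDs, over the samples before the
#' search window), so flat or pure-noise traces yield no onset.
#'
#' @param trace Per-trial dF/F trace.
#' @param times Trial times (seconds, relative to the alignment event).
#' @param search_window Two-element window (default `c(-1, 0.5)`).
#' @param threshold_frac Fraction of the SSF peak (default 0.10).
#' @param noise_floor Absolute SSF floor; `NULL` derives it from the
#'   baseline samples before the search window.
#' @param ... Passed to [slope_sum()].
#' @return Onset time in seconds, or `NA_real_`.
#' @export
detect_onset_trial <- function(trace, times, search_window = c(-1, 0.5),
                               threshold_frac = 0.10, noise_floor = NULL, ...) {
  detect_onset_mat(matrix(trace, nrow = 1), times,
                   search_window = search_window,
                   threshold_frac = threshold_frac,
                   noise_floor = noise_floor, ...)[1]
}

#' Bootstrap distribution of a cell's onset latency
#'
#' Resamples per-trial onsets with replacement, takes the median of each
#' resample, and reports the median of the bootstrap medians (minus any
#' calibration correction) with its IQR. Cells with fewer than `min_onsets`
#' detected trial onsets are flagged undetectable.
#'
#' @param trial_onsets Per-trial onset times (seconds, `NA` = undetected).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @param correction Calibration correction (seconds) subtracted from the
#'   bootstrap median.
#' @param min_onsets Minimum detected onsets (default 5).
#' @return List of class `onset_estimate`: `trial_onsets`, `boot_medians`,
#'   `median_onset`, `iqr`, `valid`, `correction`, `n_detected`.
#' @export
bootstrap_onset <- function(trial_onsets, n_boot = 10000, seed = NULL,
                            correction = 0, min_onsets = 5) {
  x <- trial_onsets[!is.na(trial_onsets)]
  if (length(x) < min_onsets) {
    return(structure(list(trial_onsets = trial_onsets, boot_medians = numeric(0),
                          median_onset = NA_real_, iqr = NA_real_, valid = FALSE,
                          correction = correction, n_detected = length(x)),
                     class = "onset_estimate"))
  }
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  draws <- matrix(sample(x, length(x) * n_boot, replace = TRUE), nrow = length(x))
  boots <- apply(draws, 2, stats::median)
  structure(list(trial_onsets = trial_onsets, boot_medians = boots,
                 median_onset = stats::median(boots) - correction,
                 iqr = stats::IQR(boots), valid = TRUE,
                 correction = correction, n_detected = length(x)),
            class = "onset_estimate")
}

#' Flag cells whose bootstrap onset distribution is too wide
#'
#' Cells whose bootstrap IQR exceeds the median IQR by more than three SDs of
#' the IQRs are marked invalid (undetectable onset; reclassified
#' nonresponsive downstream). Order-invariant.
#'
#' @param estimates List of [bootstrap_onset()] results.
#' @return The list with updated `valid` flags.
#' @export
apply_exclusion <- function(estimates) {
  if (length(estimates) < 3) stop("need at least 3 estimates")
  iqrs <- vapply(estimates, function(e) e$iqr, numeric(1))
  ok <- !is.na(iqrs)
  thr <- stats::median(iqrs[ok]) + 3 * stats::sd(iqrs[ok])
  if (is.na(thr)) return(estimates)
  lapply(estimates, function(e) {
    if (!is.na(e$iqr) && e$iqr > thr) e$valid <- FALSE
    e
  })
}

# One simulated calibration trial, reproducing the analysis data path:
# the ramp (plus frame noise) lives on the acquisition frame clock, which is
# offset from the movement-aligned grid by a random sub-frame phase, and is
# linearly interpolated onto the aligned grid exactly as align_trials()
# does. Returns c(true_onset, trace).
sim_ramp_trial <- function(times, true_onset, rise_time, amplitude, noise_sd,
                           frame_rate) {
  dt <- 1 / frame_rate
  phase <- stats::runif(1, 0, dt)
  raw_t <- c(times[1] - dt, times, times[length(times)] + dt) + phase
  raw <- ramp_transient(raw_t, true_onset, rise_time, amplitude) +
    stats::rnorm(length(raw_t), 0, noise_sd)
  c(true_onset, stats::approx(raw_t, raw, xout = times)$y)
}

#' Calibrate the onset detector on simulated ramps
#'
#' Generates linear-ramp transients with defined onset times and a 0.5 s rise
#' (GCaMP6s-like), adds Gaussian noise at the level of the imaging data, runs
#' the detector, and returns the median detection bias as the FOV-specific
#' correction factor to be subtracted from all onsets of that FOV.
#'
#' @param noise_sd Per-frame noise SD in dF/F0 units.
#' @param n_cells Number of simulated cells (default 100).
#' @param n_trials Trials per cell (default 30).
#' @param frame_rate Frames per second (default 40).
#' @param amplitude Ramp amplitude (dF/F0 units, default 0.5).
#' @param rise_time Ramp rise time in seconds (default 0.5).
#' @param onset_range True-onset range relative to movement (seconds).
#' @param seed Integer seed.
#' @param ... Passed to [detect_onset_trial()].
#' @return List of class `calibration_model`: `noise_sd`, `bias`,
#'   `correction`, `detect_frac`, `residual_bias` (per-trial detected-true
#'   after correction).
#' @export
calibrate_onset_detector <- function(noise_sd, n_cells = 100, n_trials = 30,
                                     frame_rate = 40, amplitude = 0.5,
                                     rise_time = 0.5,
                                     onset_range = c(-0.6, -0.1), seed = 1, ...) {
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  times <- seq(-2, 1.5, by = 1 / frame_rate)
  err <- matrix(NA_real_, n_cells, n_trials)
  for (c_ in seq_len(n_cells)) {
    trs <- t(vapply(seq_len(n_trials), function(k)
      sim_ramp_trial(times, stats::runif(1, onset_range[1], onset_range[2]),
                     rise_time, amplitude, noise_sd, frame_rate),
      numeric(length(times) + 1)))
    true_onsets <- trs[, 1]
    det <- detect_onset_mat(trs[, -1, drop = FALSE], times, ...)
    err[c_, ] <- det - true_onsets
  }
  frac <- mean(!is.na(err))
  if (frac < 0.5) stop("uncalibratable noise level")
  bias <- stats::median(err, na.rm = TRUE)
  structure(list(noise_sd = noise_sd, bias = bias, correction = bias,
                 detect_frac = frac,
                 residual_bias = as.numeric(err) - bias),
            class = "calibration_model")
}

#' Classify a cell's movement-aligned response
#'
#' Compares 250 ms-binned dF/F signals from 500 ms before to 1500 ms after
#' movement with a Friedman test (trials as blocks, significance threshold
#' p < 0.01). When significant, a Tukey-Kramer post hoc on the within-trial
#' ranks identifies bins that differ from the first (pre-movement) bin, and
#' the response direction is the sign of the mean signal in the earliest two
#' significant bins minus baseline.
#'
#' @param trials_dff Trials x samples matrix aligned to movement.
#' @param times Relative sample times (seconds).
#' @param window Classification window (default `c(-0.5, 1.5)`).
#' @param bin_width Bin width in seconds (default 0.25).
#' @param alpha Friedman significance threshold (default 0.01).
#' @param baseline Baseline dF/F value for the direction rule; `NULL` uses
#'   the mean over `baseline_window` when covered, else the first bin.
#' @param baseline_window Window for the baseline (default `c(-1, -0.5)`,
#'   i.e. the 500 ms preceding the classification window).
#' @return List of class `response_classification`: `friedman_p`,
#'   `significant_bins`, `direction_effect`, `category` (`"increase"`,
#'   `"decrease"` or `"nonresponsive"`; early/late refinement happens after
#'   onset estimation), `bin_means`.
#' @export
classify_response <- function(trials_dff, times, window = c(-0.5, 1.5),
                              bin_width = 0.25, alpha = 0.01, baseline = NULL,
                              baseline_window = c(-1, -0.5)) {
  trials_dff <- as.matrix(trials_dff)
  if (nrow(trials_dff) < 3) stop("need at least 3 trials")
  edges <- seq(window[1], window[2], by = bin_width)
  k <- length(edges) - 1
  if (k < 2) stop("need at least 2 bins")
  binm <- sapply(seq_len(k), function(b) {
    sel <- times >= edges[b] & times < edges[b + 1]
    rowMeans(trials_dff[, sel, drop = FALSE])
  })
  ft <- stats::friedman.test(as.matrix(binm))
  p <- ft$p.value
  sig_bins <- integer(0)
  effect <- NA_real_
  category <- "nonresponsive"
  if (!is.na(p) && p < alpha) {
    sig_bins <- friedman_posthoc_vs_first(binm)
    if (length(sig_bins) > 0) {
      if (is.null(baseline)) {
        bsel <- times >= baseline_window[1] & times < baseline_window[2]
        baseline <- if (any(bsel)) mean(trials_dff[, bsel]) else mean(binm[, 1])
      }
      first2 <- utils::head(sort(sig_bins), 2)
      effect <- mean(binm[, first2]) - baseline
      category <- if (effect >= 0) "increase" else "decrease"
    }
  }
  structure(list(friedman_p = p, significant_bins = sig_bins,
                 direction_effect = effect, category = category,
                 bin_means = binm),
            class = "response_classification")
}

# Tukey-Kramer post hoc on Friedman ranks: bins whose mean within-trial rank
# differs from bin 1 by more than the studentized-range critical difference
# at alpha = 0.05.
friedman_posthoc_vs_first <- function(binm, alpha = 0.05) {
  n <- nrow(binm); k <- ncol(binm)
  ranks <- t(apply(binm, 1, rank))
  rbar <- colMeans(ranks)
  crit <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  setdiff(which(abs(rbar - rbar[1]) > crit), 1L)
}

#' Assign reaction-time categories to push trials
#'
#' Fixed boundaries: short `[0, 0.35)`, medium `[0.35, 0.9)`, long
#' `[0.9, Inf)` seconds.
#'
#' @param trials Trial table.
#' @return Character vector per trial (`NA` for non-push trials).
#' @export
split_by_rt <- function(trials) {
  rt <- ifelse(trials$outcome == "push", trials$reaction_time, NA_real_)
  out <- rep(NA_character_, nrow(trials))
  out[!is.na(rt) & rt < 0.35] <- "short"
  out[!is.na(rt) & rt >= 0.35 & rt < 0.9] <- "medium"
  out[!is.na(rt) & rt >= 0.9] <- "long"
  out
}

#' One-way ANOVA of onset latency across reaction-time groups
#'
#' Operates on per-FOV per-group mean onsets. A FOV enters the comparison
#' only when every reaction-time category has at least `min_trials` trials.
#'
#' @param onsets_by_group Data frame with columns `fov`, `group`
#'   (short/medium/long), `mean_onset`, `n_trials`.
#' @param min_trials FOV-inclusion floor per category (default 5).
#' @return List of class `rt_group_result`: `anova_p`, `group_means`,
#'   `included_fovs`, `table` (the retained rows).
#' @export
compare_onsets_across_rt <- function(onsets_by_group, min_trials = 5) {
  d <- onsets_by_group
  ok_fov <- vapply(split(d, d$fov), function(g) {
    all(c("short", "medium", "long") %in% g$group[g$n_trials >= min_trials])
  }, logical(1))
  keep <- names(ok_fov)[ok_fov]
  d <- d[d$fov %in% keep & d$n_trials >= min_trials & !is.na(d$mean_onset), ]
  if (length(unique(d$group)) < 2) stop("fewer than 2 reaction-time groups populated")
  gm <- tapply(d$mean_onset, d$group, mean)
  if (stats::var(d$mean_onset) == 0 || max(gm) - min(gm) == 0) {
    p <- 1
  } else {
    fit <- stats::aov(mean_onset ~ factor(group), data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(p)) p <- 1
  }
  structure(list(anova_p = p, group_means = gm, included_fovs = keep, table = d),
            class = "rt_group_result")
}

#' Trial-averaged aligned trace with loess smoothing and bootstrap ribbon
#'
#' Mean across trials, loess-smoothed over a 40-frame sliding window, and
#' baseline-corrected to the mean over the 500 ms pre-cue period (supplied as
#' `baseline_window` in the aligned frame). The ribbon is a pointwise
#' percentile bootstrap over trials.
#'
#' @param trials_dff Trials x samples aligned matrix.
#' @param times Relative sample times.
#' @param baseline_window Baseline window (default `c(-1, -0.5)`).
#' @param span_frames Loess window length in frames (default 40).
#' @param n_boot Bootstrap resamples for the ribbon (default 1000).
#' @param level Ribbon confidence level.
#' @param seed Integer seed.
#' @return List: `times`, `mean` (smoothed, baseline-corrected), `lo`, `hi`.
#' @export
aligned_average <- function(trials_dff, times, baseline_window = c(-1, -0.5),
                            span_frames = 40, n_boot = 1000, level = 0.95,
                            seed = NULL) {
  trials_dff <- as.matrix(trials_dff)
  if (nrow(trials_dff) < 3) stop("need at least 3 trials")
  m <- colMeans(trials_dff)
  sm <- loess_smooth(m, times, span_frames)
  bsel <- times >= baseline_window[1] & times < baseline_window[2]
  b <- if (any(bsel)) mean(sm[bsel]) else 0
  sm <- sm - b
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  n <- nrow(trials_dff)
  boots <- replicate(n_boot, {
    mm <- colMeans(trials_dff[sample.int(n, n, replace = TRUE), , drop = FALSE])
    mm - if (any(bsel)) mean(mm[bsel]) else 0
  })
  alpha <- (1 - level) / 2
  qs <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  list(times = times, mean = sm, lo = qs[1, ], hi = qs[2, ])
}

loess_smooth <- function(y, x, span_frames) {
  span <- min(1, span_frames / length(x))
  fit <- stats::loess(y ~ x, span = span, degree = 2,
                      family = "gaussian", surface = "direct")
  stats::predict(fit, x)
}

#' Kernel density estimate of pooled onset latencies
#'
#' Gaussian KDE across all trial onsets with its trapezoid-rule area over the
#' evaluation support (approximately 1 when the support covers the kernel
#' tails).
#'
#' @param trial_onsets Pooled onset times (seconds), `NA` dropped.
#' @param bandwidth Kernel SD in seconds (default 0.05).
#' @param n_eval Evaluation grid size.
#' @return List: `x`, `density`, `auc`, `mean` (density-weighted mean).
#' @export
population_onset_kde <- function(trial_onsets, bandwidth = 0.05, n_eval = 512) {
  x <- trial_onsets[!is.na(trial_onsets)]
  if (length(x) < 10) stop("need at least 10 onsets")
  d <- stats::density(x, bw = bandwidth, kernel = "gaussian",
                      from = min(x) - 5 * bandwidth, to = max(x) + 5 * bandwidth,
                      n = n_eval)
  auc <- pracma::trapz(d$x, d$y)
  list(x = d$x, density = d$y, auc = auc,
       mean = pracma::trapz(d$x, d$x * d$y) / auc)
}

#' Per-trial rise-time features for model discrimination
#'
#' For each push trial, finds the peak of the Savitzky-Golay-smoothed trace
#' within a common RT-independent window (from just before the earliest cue
#' to 0.7 s after movement), then walks backward from the peak to the 10%
#' rise time (`onset_rel`) and takes the first 90%-of-peak crossing on the
#' rising flank (`t90_rel`). The backward search makes the features robust
#' to noise excursions far from the transient; a per-trial search window
#' would couple detection noise to reaction time and bias the regression
#' slopes the discrimination rule relies on.
#'
#' @param dff_mat Trials x samples matrix aligned to movement (push trials).
#' @param times Relative sample times.
#' @param rts Per-trial reaction times (seconds), same order as rows.
#' @param sg_frames,sg_order Savitzky-Golay smoothing parameters.
#' @return Data frame: `trial`, `rt`, `onset_rel`, `t90_rel`.
#' @export
trial_onset_table <- function(dff_mat, times, rts, sg_frames = 27,
                              sg_order = 2) {
  dff_mat <- as.matrix(dff_mat)
  win <- c(max(min(times) + 0.05, -max(rts) - 0.3), 0.7)
  sel <- which(times >= win[1] & times <= win[2])
  bsel <- which(times >= win[1] & times <= win[1] + 0.2)
  smooth_mat <- dff_mat %*% t(sg_operator(ncol(dff_mat), sg_order, sg_frames))
  out <- lapply(seq_len(nrow(dff_mat)), function(i) {
    sm <- smooth_mat[i, ]
    base <- stats::median(sm[bsel])
    y <- sm - base
    ipk <- sel[which.max(y[sel])]
    pk <- y[ipk]
    if (pk <= 0) {
      return(data.frame(trial = i, rt = rts[i], onset_rel = NA_real_,
                        t90_rel = NA_real_))
    }
    j <- ipk
    first <- min(sel)
    while (j > first && y[j - 1] >= 0.1 * pk) j <- j - 1
    onset <- times[j]
    k <- ipk
    while (k > first && y[k - 1] >= 0.9 * pk) k <- k - 1
    data.frame(trial = i, rt = rts[i], onset_rel = onset, t90_rel = times[k])
  })
  do.call(rbind, out)
}

# Theil-Sen estimator: median of pairwise slopes. Robust to the occasional
# trial whose transient is clipped by the alignment window (extreme reaction
# times), which would act as a high-leverage point in least squares.
theil_sen_slope <- function(x, y) {
  if (length(x) < 2) return(NA_real_)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  ok <- upper.tri(dx) & abs(dx) > 1e-9
  stats::median(dy[ok] / dx[ok])
}

#' Discriminate among the three population-response models
#'
#' Regresses movement-aligned onset latency on reaction time: a
#' movement-locked signal (model i) has slope near 0, while cue-anchored
#' signals (models ii and iii) have slope near -1. Cue-anchored signals are
#' separated by how the time of the near-peak (90% of maximum) tracks
#' reaction time: a fixed-rise cue-locked transient (model ii) peaks a fixed
#' delay after the cue (movement-aligned slope near -1), whereas a
#' ramp-to-threshold transient (model iii) peaks at movement (slope near 0).
#'
#' @param features Data frame from [trial_onset_table()] (rows with `NA`
#'   onsets are dropped).
#' @param min_trials Minimum usable trials (default 20).
#' @param min_rt_spread Minimum reaction-time range in seconds (default 0.1).
#' @return List of class `model_verdict`: `model` (`"i"`, `"ii"`, `"iii"` or
#'   `"indeterminate"`), `onset_slope`, `t90_slope`, `n_trials`.
#' @export
discriminate_model <- function(features, min_trials = 20, min_rt_spread = 0.1) {
  d <- features[!is.na(features$onset_rel), ]
  if (nrow(d) < min_trials || diff(range(d$rt)) < min_rt_spread) {
    return(structure(list(model = "indeterminate", onset_slope = NA_real_,
                          t90_slope = NA_real_, n_trials = nrow(d)),
                     class = "model_verdict"))
  }
  b_on <- theil_sen_slope(d$rt, d$onset_rel)
  dk <- d[!is.na(d$t90_rel), ]
  b_t90 <- theil_sen_slope(dk$rt, dk$t90_rel)
  model <- if (abs(b_on) < 0.5) "i" else if (b_t90 < -0.5) "ii" else "iii"
  structure(list(model = model, onset_slope = b_on, t90_slope = b_t90,
                 n_trials = nrow(d)),
            class = "model_verdict")
}
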