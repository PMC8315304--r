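#' Detect action potentials in a membrane-potential trace
#'
#' Amplitude-plus-derivative prominence detection: candidate peaks are local
#' maxima exceeding `min_height` above the trace median that are preceded
#' (within 1 ms) by a rising slope of at least `min_slope`; duplicates within
#' 2 ms are merged to the larger peak. Detection is invariant to a DC offset.
#'
#' @param vm Membrane potential (mV).
#' @param times Sample times (seconds); sample rate must be at least 10 kHz.
#' @param min_height Peak height above the trace median, mV (default 20).
#' @param min_slope Minimum pre-peak slope in mV/ms (default 15).
#' @return List of `spike_event`s from [ap_threshold()] (fields `peak_time`,
#'   `threshold_time`, `threshold_vm`, `peak_vm`).
#' @export
detect_spikes <- function(vm, times, min_height = 20, min_slope = 15) {
  dt <- stats::median(diff(times))
  if (1 / dt < 10000 - 1e-6) stop("sample rate must be >= 10 kHz")
  thr <- stats::median(vm) + min_height
  above <- vm > thr
  if (!any(above)) return(list())
  d <- c(0, diff(vm)) / (dt * 1000)  # mV/ms
  # local maxima above threshold
  cand <- which(above & c(TRUE, diff(vm) >= 0) & c(diff(vm) <= 0, TRUE))
  if (length(cand) == 0) return(list())
  # slope criterion within 1 ms before the peak
  w <- max(1L, round(0.001 / dt))
  keep <- vapply(cand, function(i) {
    j <- max(1L, i - w):i
    max(d[j]) >= min_slope
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) return(list())
  # merge peaks within 2 ms, keeping the larger
  merged <- integer(0)
  gap <- round(0.002 / dt)
  for (i in cand) {
    if (length(merged) > 0 && i - merged[length(merged)] < gap) {
      if (vm[i] > vm[merged[length(merged)]]) merged[length(merged)] <- i
    } else {
      merged <- c(merged, i)
    }
  }
  evs <- lapply(merged, function(i) ap_threshold(vm, times, times[i]))
  evs[!vapply(evs, is.null, logical(1))]
}

#' Action-potential threshold from the second derivative
#'
#' The AP threshold is the membrane potential at the maximal second
#' derivative of Vm up to 3 ms before the AP peak (earliest sample on ties).
#' Events whose 3 ms pre-peak window is truncated by the recording edge are
#' dropped with a warning.
#'
#' @param vm Membrane potential (mV).
#' @param times Sample times (seconds).
#' @param peak_time Time of the AP peak (seconds).
#' @return List of class `spike_event` (`peak_time`, `threshold_time`,
#'   `threshold_vm`, `peak_vm`), or `NULL` for truncated events.
#' @export
ap_threshold <- function(vm, times, peak_time) {
  dt <- stats::median(diff(times))
  ip <- which.min(abs(times - peak_time))
  nback <- round(0.003 / dt)
  if (ip - nback < 2) {
    warning("AP at recording edge dropped")
    return(NULL)
  }
  idx <- (ip - nback):(ip - 1)
  d2 <- vm[idx + 1] - 2 * vm[idx] + vm[idx - 1]
  it <- idx[which.max(d2)]  # which.max returns the earliest maximum
  structure(list(peak_time = times[ip], threshold_time = times[it],
                 threshold_vm = vm[it], peak_vm = vm[ip]),
            class = "spike_event")
}

#' Remove action potentials from a Vm trace
#'
#' Clips samples between -1 and +9 ms peri-AP-threshold (10 ms per isolated
#' spike; overlapping spans are merged) and fills the gaps by linear
#' interpolation so the subthreshold trace keeps uniform sampling. Non-spike
#' samples are returned unchanged.
#'
#' @param vm Membrane potential (mV).
#' @param times Sample times (seconds).
#' @param spikes List of `spike_event`s.
#' @param clip_window Clip window around each threshold time, seconds
#'   (default `c(-0.001, 0.009)`).
#' @return Subthreshold Vm vector, same length as `vm`.
#' @export
clip_spikes <- function(vm, times, spikes, clip_window = c(-0.001, 0.009)) {
  if (length(spikes) == 0) return(vm)
  dt <- stats::median(diff(times))
  nclip <- round(diff(clip_window) / dt)
  drop <- logical(length(vm))
  for (sp in spikes) {
    i0 <- round((sp$threshold_time + clip_window[1] - times[1]) / dt) + 1L
    idx <- i0:(i0 + nclip - 1L)
    idx <- idx[idx >= 1 & idx <= length(vm)]
    drop[idx] <- TRUE
  }
  out <- vm
  out[drop] <- NA
  keep <- which(!drop)
  out[drop] <- stats::approx(times[keep], vm[keep], xout = times[drop],
                             rule = 2)$y
  out
}

#' Movement-aligned subthreshold trajectory
#'
#' Per trial, the mean Vm over a 1 s pre-cue baseline is subtracted; the
#' trial-mean trajectory is decimated to 1 kHz and median-filtered with a
#' 50 ms sliding window. Significance of the peri-movement change is tested
#' by comparing the bootstrap CI of the epoch-mean change (baseline 200 ms
#' pre-cue vs -100..+100 ms peri-movement) to zero.
#'
#' @param sub_trials Trials x samples matrix of subthreshold Vm aligned to
#'   movement onset.
#' @param times Relative sample times (seconds).
#' @param cue_rel Per-trial cue times relative to movement (negative
#'   seconds).
#' @param decimate_to Target rate in Hz after decimation (default 1000).
#' @param median_window Sliding-median window in seconds (default 0.05).
#' @param n_boot,level,seed Passed to [epoch_significance()].
#' @return List of class `dvm_trajectory`: `times` (decimated), `dvm`,
#'   `significance`, `baseline_per_trial`.
#' @export
delta_vm_trajectory <- function(sub_trials, times, cue_rel,
                                decimate_to = 1000, median_window = 0.05,
                                n_boot = 10000, level = 0.95, seed = NULL) {
  sub_trials <- as.matrix(sub_trials)
  if (nrow(sub_trials) < 3) stop("need at least 3 trials")
  base <- vapply(seq_len(nrow(sub_trials)), function(i) {
    # 1 s pre-cue epoch, clamped into the aligned support; trials whose cue
    # precedes the window (very long reaction times) fall back to the
    # earliest 0.5 s of the aligned trace
    sel <- times >= max(cue_rel[i] - 1, times[1]) & times < cue_rel[i]
    if (!any(sel)) sel <- times < times[1] + 0.5
    mean(sub_trials[i, sel])
  }, numeric(1))
  d <- sub_trials - base
  mcue <- stats::median(cue_rel)
  sig <- epoch_significance(d, times,
                            baseline_window = c(mcue - 0.2, mcue),
                            response_window = c(-0.1, 0.1),
                            level = level, n_boot = n_boot, seed = seed)
  m <- colMeans(d)
  dt <- stats::median(diff(times))
  dec <- max(1L, round(1 / (decimate_to * dt)))
  keep <- seq(1, length(m), by = dec)
  td <- times[keep]
  md <- m[keep]
  wl <- max(1L, round(median_window * decimate_to))
  if (wl %% 2 == 0) wl <- wl + 1L
  md <- stats::runmed(md, wl, endrule = "keep")
  structure(list(times = td, dvm = as.numeric(md), significance = sig,
                 baseline_per_trial = base),
            class = "dvm_trajectory")
}

#' Normalize trajectories to their peri-movement extremum
#'
#' Each trajectory is divided by its own largest absolute value within the
#' 1.5 s peri-movement window (+/-0.75 s of movement onset), so values lie in
#' [-1, 1] with the peri-movement extremum at +/-1.
#'
#' @param trajectories List of `dvm_trajectory` objects (or lists with
#'   `times` and `dvm`).
#' @param window Peri-movement window half-width in seconds (default 0.75).
#' @return The list with `dvm` replaced by `normalized`.
#' @export
normalize_population <- function(trajectories, window = 0.75) {
  lapply(trajectories, function(tr) {
    sel <- tr$times >= -window & tr$times <= window
    mx <- max(abs(tr$dvm[sel]))
    if (mx == 0) stop("zero normalizer")
    tr$normalized <- tr$dvm / mx
    tr
  })
}

#' Subthreshold trajectory onset as the 10% rise time
#'
#' Finds the peri-movement peak of |dVm| and searches backward from it for
#' the latest time the trajectory was below 10% of the peak; the onset is the
#' first sample at or above 10% after that. Hyperpolarizing trajectories
#' mirror the depolarizing case.
#'
#' @param trajectory A `dvm_trajectory` (must be significant unless
#'   `force = TRUE`).
#' @param window Peri-movement search window (default `c(-0.75, 0.75)`).
#' @param frac Rise fraction (default 0.10).
#' @param force Compute even when nonsignificant.
#' @return Onset time in seconds, or `NA_real_` when nonsignificant.
#' @export
vm_onset <- function(trajectory, window = c(-0.75, 0.75), frac = 0.10,
                     force = FALSE) {
  if (!force && !is.null(trajectory$significance) &&
      !trajectory$significance$significant) return(NA_real_)
  sel <- which(trajectory$times >= window[1] & trajectory$times <= window[2])
  y <- abs(trajectory$dvm[sel])
  ipk <- sel[which.max(y)]
  pk <- abs(trajectory$dvm[ipk])
  if (pk == 0) return(NA_real_)
  i <- ipk
  first <- min(sel)
  while (i > first && abs(trajectory$dvm[i - 1]) >= frac * pk) i <- i - 1
  trajectory$times[i]
}

#' Pre/post silencing comparison of subthreshold dynamics
#'
#' Computes the area under the |dVm| trajectory from cue onset to the median
#' reward time (per epoch) by trapezoidal integration at a 50 ms sample rate,
#' their post/pre ratio, and the proportional firing-rate change
#' ((response - baseline) / baseline, baseline floored at `rate_floor`) in
#' each epoch from Gaussian-kernel rates around the median reaction time.
#'
#' @param pre,post Lists with `dvm_trials` (trials x samples, cue-aligned,
#'   baseline-subtracted), `times` (relative to cue), `spike_trials` (list of
#'   per-trial spike-time vectors relative to cue), `reward_rel` (per-trial
#'   reward time relative to cue), `rt` (per-trial reaction times).
#' @param kernel_sd Rate kernel SD in seconds (default 0.05).
#' @param dt AUC sample interval in seconds (default 0.05).
#' @param rate_floor Baseline-rate floor in Hz (default 0.1).
#' @return List of class `muscimol_comparison`: `auc_pre`, `auc_post`,
#'   `ratio` (`NA` and flagged when `auc_pre` is 0), `rate_change_pre`,
#'   `rate_change_post`, `ratio_defined`.
#' @export
muscimol_auc_comparison <- function(pre, post, kernel_sd = 0.05, dt = 0.05,
                                    rate_floor = 0.1) {
  auc_epoch <- function(ep) {
    m <- abs(colMeans(as.matrix(ep$dvm_trials)))
    t1 <- stats::median(ep$reward_rel)
    trapezoid_auc(m, ep$times, 0, min(t1, max(ep$times)), dt = dt)
  }
  rate_epoch <- function(ep) {
    mrt <- stats::median(ep$rt)
    grid <- seq(min(ep$times), max(ep$times), by = 0.001)
    rates <- vapply(ep$spike_trials, function(s)
      gaussian_rate(s, kernel_sd, grid)$rate, numeric(length(grid)))
    m <- rowMeans(rates)
    bsel <- grid >= -0.2 & grid < 0
    rsel <- grid >= mrt - 0.1 & grid < mrt + 0.1
    b <- max(mean(m[bsel]), rate_floor)
    (mean(m[rsel]) - mean(m[bsel])) / b
  }
  auc_pre <- auc_epoch(pre)
  auc_post <- auc_epoch(post)
  defined <- auc_pre > 0
  structure(list(auc_pre = auc_pre, auc_post = auc_post,
                 ratio = if (defined) auc_post / auc_pre else NA_real_,
                 rate_change_pre = rate_epoch(pre),
                 rate_change_post = rate_epoch(post),
                 ratio_defined = defined),
            class = "muscimol_comparison")
}

#' Correlation between subthreshold and firing-rate effects
#'
#' Pearson correlation with a least-squares linear fit over paired per-cell
#' effects.
#'
#' @param dvm_effects Per-cell dVm effects (mV).
#' @param rate_effects Per-cell rate effects (Hz).
#' @return List: `r`, `slope`, `intercept`, `n`, `p`.
#' @export
correlate_dvm_rate <- function(dvm_effects, rate_effects) {
  if (length(dvm_effects) != length(rate_effects)) stop("inputs must be paired")
  if (length(dvm_effects) < 3) stop("need at least 3 pairs")
  ct <- stats::cor.test(dvm_effects, rate_effects)
  fit <- stats::lm(rate_effects ~ dvm_effects)
  list(r = unname(ct$estimate), slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(dvm_effects),
       p = ct$p.value)
}
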