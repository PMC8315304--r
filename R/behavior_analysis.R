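#' Motion index of a behavioral video ROI
#'
#' For consecutive frame pairs, the motion index is the sum over ROI pixels
#' of squared gray-level differences: MI_f = sum_i (c_{f+1,i} - c_{f,i})^2.
#' Identical frames give MI = 0; a common offset added to both frames leaves
#' MI unchanged.
#'
#' @param frames Matrix, frames x pixels (each row one frame's ROI pixels).
#' @param frame_times Optional frame times (seconds).
#' @return List of class `motion_index_trace`: `mi` (length frames-1, the
#'   value at index f compares frames f and f+1), `frame_times` (times of
#'   the leading frame of each pair).
#' @export
motion_index <- function(frames, frame_times = NULL) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 2) stop("need at least 2 frames")
  d <- diff(frames)
  mi <- rowSums(d^2)
  if (is.null(frame_times)) frame_times <- seq_len(nrow(frames))
  if (length(frame_times) != nrow(frames)) stop("frame shape mismatch")
  structure(list(mi = mi, frame_times = frame_times[-length(frame_times)]),
            class = "motion_index_trace")
}

#' Baseline statistics and detection thresholds for a motion-index trace
#'
#' Baseline frames are inter-trial samples at least `margin` seconds from
#' any event. The forelimb-movement threshold is mean + 3 SD of the baseline
#' MI; the lick threshold is mean + 10 SD.
#'
#' @param mi A `motion_index_trace`.
#' @param event_times All event times (cues, movements, rewards; seconds).
#' @param margin Exclusion margin around events (default 1 s).
#' @return List: `mean`, `sd`, `theta_move`, `theta_lick`, `n_baseline`.
#' @export
motion_baseline <- function(mi, event_times, margin = 1) {
  ev <- event_times[!is.na(event_times)]
  t <- mi$frame_times
  far <- rep(TRUE, length(t))
  for (e in ev) far <- far & abs(t - e) >= margin
  if (!any(far)) stop("no baseline epochs")
  m <- mean(mi$mi[far]); s <- stats::sd(mi$mi[far])
  list(mean = m, sd = s, theta_move = m + 3 * s, theta_lick = m + 10 * s,
       n_baseline = sum(far))
}

#' Event-triggered movement / lick detection
#'
#' An event counts as moved when any motion-index sample within 500 ms after
#' the event exceeds the threshold of the requested kind (3 SD above the
#' baseline mean for forelimb movement, 10 SD for licking); the latency is
#' the first crossing time.
#'
#' @param mi A `motion_index_trace`.
#' @param baseline Output of [motion_baseline()].
#' @param event_times Event (cue/photostimulation) onset times in seconds.
#' @param kind `"forelimb"` or `"lick"`.
#' @param window Detection window after the event in seconds (default 0.5).
#' @return Data frame: `event_time`, `moved`, `latency` (seconds after the
#'   event; `NA` when not moved).
#' @export
detect_movement <- function(mi, baseline, event_times,
                            kind = c("forelimb", "lick"), window = 0.5) {
  kind <- match.arg(kind)
  theta <- if (kind == "forelimb") baseline$theta_move else baseline$theta_lick
  out <- lapply(event_times, function(ev) {
    sel <- which(mi$frame_times > ev & mi$frame_times <= ev + window)
    hit <- sel[mi$mi[sel] > theta]
    data.frame(event_time = ev, moved = length(hit) > 0,
               latency = if (length(hit) > 0) mi$frame_times[hit[1]] - ev
                         else NA_real_)
  })
  do.call(rbind, out)
}

#' Classify the initial paw trajectory vector
#'
#' Takes the displacement vector over a 50 ms epoch starting at
#' `epoch_start` (movement onset in the learned context; 50 ms after the
#' learned-context median reaction time in altered contexts) and classifies
#' the movement as push-like when its angle lies in [170, 210] degrees
#' (0 degrees = image-right, counterclockwise positive; bounds inclusive).
#' Invariant to trajectory translation and uniform spatial scaling.
#'
#' @param trajectory Data frame with columns `time`, `x`, `y`.
#' @param epoch_start Epoch start time (seconds).
#' @param epoch Epoch duration in seconds (default 0.05).
#' @param angle_range Push-like angular window in degrees (default
#'   `c(170, 210)`).
#' @return List of class `movement_call`: `movement_type` (`"push_like"`,
#'   `"discrete"` or `"none"`), `vector_angle` (degrees, `NA` for zero
#'   displacement), `displacement`.
#' @export
classify_push_vector <- function(trajectory, epoch_start, epoch = 0.05,
                                 angle_range = c(170, 210)) {
  p0 <- c(stats::approx(trajectory$time, trajectory$x, epoch_start, rule = 2)$y,
          stats::approx(trajectory$time, trajectory$y, epoch_start, rule = 2)$y)
  p1 <- c(stats::approx(trajectory$time, trajectory$x, epoch_start + epoch, rule = 2)$y,
          stats::approx(trajectory$time, trajectory$y, epoch_start + epoch, rule = 2)$y)
  d <- p1 - p0
  disp <- sqrt(sum(d^2))
  if (disp == 0) {
    return(structure(list(movement_type = "none", vector_angle = NA_real_,
                          displacement = 0), class = "movement_call"))
  }
  ang <- (atan2(d[2], d[1]) * 180 / pi) %% 360
  push <- ang >= angle_range[1] & ang <= angle_range[2]
  structure(list(movement_type = if (push) "push_like" else "discrete",
                 vector_angle = ang, displacement = disp),
            class = "movement_call")
}

#' Error-rate-corrected push probability
#'
#' Lower-bound push probability: the raw proportion of pushes minus the
#' proportion observed in shutter-only control trials, clipped at zero.
#'
#' @param n_push,n_trials Push count and trial count for the condition.
#' @param n_push_control,n_trials_control Same for shutter-only trials.
#' @return List of class `push_probability`: `p_raw`, `p_control`,
#'   `p_corrected`.
#' @export
corrected_push_probability <- function(n_push, n_trials, n_push_control,
                                       n_trials_control) {
  if (n_trials < 1 || n_trials_control < 1) stop("need at least 1 trial per type")
  p_raw <- n_push / n_trials
  p_control <- n_push_control / n_trials_control
  structure(list(p_raw = p_raw, p_control = p_control,
                 p_corrected = max(0, p_raw - p_control)),
            class = "push_probability")
}

#' Session-level behavioral summary and cohort comparison
#'
#' Reaction-time and push-duration distributions and task success (rewarded
#' over cued trials); optionally a two-sample Kolmogorov-Smirnov comparison
#' of each metric against a second cohort.
#'
#' @param trials Trial table.
#' @param other Optional second trial table for the KS comparison.
#' @return List: `rt`, `push_duration`, `success`, and (when `other` is
#'   given) `ks_rt_p`, `ks_duration_p`.
#' @export
session_metrics <- function(trials, other = NULL) {
  rt <- trials$reaction_time[!is.na(trials$reaction_time)]
  dur <- with(trials, reward_time - movement_time)
  dur <- dur[!is.na(dur)]
  out <- list(rt = rt, push_duration = dur,
              success = sum(!is.na(trials$reward_time)) / nrow(trials))
  if (!is.null(other)) {
    rt2 <- other$reaction_time[!is.na(other$reaction_time)]
    dur2 <- with(other, reward_time - movement_time)
    dur2 <- dur2[!is.na(dur2)]
    out$ks_rt_p <- if (identical(rt, rt2)) 1 else
      suppressWarnings(stats::ks.test(rt, rt2)$p.value)
    out$ks_duration_p <- if (identical(dur, dur2)) 1 else
      suppressWarnings(stats::ks.test(dur, dur2)$p.value)
  }
  out
}

#' Paw-placement accuracy
#'
#' Proportion of trials with the contralateral forepaw on the lever at cue
#' onset, with a weighted bootstrap CI (weights e.g. proportional to each
#' animal's trial contribution).
#'
#' @param holding Logical per-trial flags.
#' @param weights Optional per-trial weights.
#' @param ... Passed to [weighted_bootstrap_ci()].
#' @return List: `fraction`, `ci`.
#' @export
paw_placement_accuracy <- function(holding, weights = NULL, ...) {
  if (length(holding) == 0) stop("no data")
  ci <- weighted_bootstrap_ci(as.numeric(holding), weights = weights,
                              stat = "mean", ...)
  list(fraction = mean(holding), ci = ci)
}
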