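#' Peri-movement firing-rate change of a sorted unit
#'
#' Per trial, the spike train is aligned to its event, smoothed with a 200 ms
#' Gaussian kernel, and the mean rate over a response window (-100..+100 ms
#' peri-movement) minus a baseline window (200 ms pre-cue/pre-laser) is
#' computed; the across-trial mean change is tested against zero with a
#' bootstrap CI.
#'
#' @param spike_times Unit spike times (seconds, whole session).
#' @param align_events Per-trial alignment (movement) times in seconds.
#' @param baseline_window Window relative to the alignment event (default
#'   200 ms ending at the median cue time requires caller-supplied window;
#'   the default `c(-0.5, -0.3)` corresponds to a 200 ms pre-cue epoch at
#'   short reaction times).
#' @param response_window Response window (default `c(-0.1, 0.1)`).
#' @param kernel_sd Rate kernel SD in seconds (default 0.2).
#' @param span Aligned support half-width in seconds (default 1.5).
#' @param dt Rate grid step (default 0.01).
#' @param n_boot,level,seed Passed to [epoch_significance()].
#' @return List of class `rate_change`: `delta_rate` (Hz), `significance`,
#'   `trial_changes`.
#' @export
rate_change <- function(spike_times, align_events,
                        baseline_window = c(-0.5, -0.3),
                        response_window = c(-0.1, 0.1), kernel_sd = 0.2,
                        span = 1.5, dt = 0.01, n_boot = 10000, level = 0.95,
                        seed = NULL) {
  align_events <- align_events[!is.na(align_events)]
  if (length(align_events) < 5) stop("need at least 5 trials")
  grid <- seq(-span, span, by = dt)
  traces <- t(vapply(align_events, function(ev) {
    s <- spike_times[spike_times >= ev - span - 1 & spike_times <= ev + span + 1] - ev
    gaussian_rate(s, kernel_sd, grid)$rate
  }, numeric(length(grid))))
  if (all(traces == 0)) {
    return(structure(list(delta_rate = 0, significance = NULL,
                          trial_changes = rep(0, length(align_events))),
                     class = "rate_change"))
  }
  sig <- epoch_significance(traces, grid, baseline_window, response_window,
                            level = level, n_boot = n_boot, seed = seed)
  structure(list(delta_rate = sig$effect, significance = sig,
                 trial_changes = sig$trial_effects),
            class = "rate_change")
}

#' Trough-to-peak spike width
#'
#' Duration from the global waveform trough (earliest on ties) to the
#' subsequent peak. Invariant to amplitude scaling.
#'
#' @param waveform Spike waveform samples.
#' @param sample_rate Samples per second.
#' @return Width in seconds.
#' @export
spike_width <- function(waveform, sample_rate) {
  it <- which.min(waveform)           # earliest global trough on ties
  if (it == length(waveform)) stop("non-canonical waveform")
  ip <- it - 1 + which.max(waveform[it:length(waveform)])
  if (ip <= it) stop("non-canonical waveform")
  (ip - it) / sample_rate
}

#' Depth filter for sorted units
#'
#' Pure predicate keeping units between 500 and 1200 um below the pial
#' surface; kept plus excluded counts equal the input count.
#'
#' @param depths Per-unit depths in micrometers.
#' @param range Inclusion range (default `c(500, 1200)`).
#' @return Logical vector, `TRUE` for included units.
#' @export
depth_filter <- function(depths, range = c(500, 1200)) {
  depths >= range[1] & depths <= range[2]
}

#' Correlation between cue-evoked and photoactivated rate changes
#'
#' Paired Pearson correlation of per-unit delta rates across the two
#' conditions, plus the fraction of units responsive in both.
#'
#' @param changes_cue,changes_photo Lists of `rate_change` objects for the
#'   same units in the same order.
#' @return List: `r`, `p`, `slope`, `intercept`, `overlap_fraction`, `n`.
#' @export
cue_photo_correlation <- function(changes_cue, changes_photo) {
  if (length(changes_cue) != length(changes_photo))
    stop("conditions must contain the same units")
  x <- vapply(changes_cue, function(u) u$delta_rate, numeric(1))
  y <- vapply(changes_photo, function(u) u$delta_rate, numeric(1))
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  sig <- function(u) !is.null(u$significance) && u$significance$significant
  both <- mean(vapply(changes_cue, sig, logical(1)) &
                 vapply(changes_photo, sig, logical(1)))
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       overlap_fraction = both, n = length(x))
}

#' Time course of pharmacological silencing versus distance
#'
#' Normalizes each unit's binned rate to its pre-injection baseline mean and,
#' in each post-injection time bin, correlates suppression with the unit's
#' distance from the injection center. Also reports, for units beyond
#' `far_um`, the earliest time any of them drops below the suppression
#' threshold (`Inf` when none does).
#'
#' @param spike_trains List of per-unit spike-time vectors (seconds).
#' @param distances_um Per-unit distance from the injection center (um).
#' @param injection_time Injection time in seconds.
#' @param bin_width Time-bin width in seconds (default 60).
#' @param baseline_span Pre-injection baseline length in seconds (default
#'   300; at least 5 minutes).
#' @param duration Recording end time (seconds).
#' @param suppression_threshold Normalized-rate threshold (default 0.5).
#' @param far_um Distance bound for the "unsuppressed beyond" summary
#'   (default 600).
#' @return List of class `silencing_course`: `bin_times`, `norm_rates`
#'   (units x bins), `correlation_by_bin` (`NA` where undefined),
#'   `correlation_defined`, `far_suppression_time`.
#' @export
silencing_distance_course <- function(spike_trains, distances_um,
                                      injection_time, bin_width = 60,
                                      baseline_span = 300, duration,
                                      suppression_threshold = 0.5,
                                      far_um = 600) {
  if (baseline_span < 300) stop("baseline epoch must be >= 5 min")
  edges <- seq(injection_time, duration, by = bin_width)
  nb <- length(edges) - 1
  norm <- t(vapply(spike_trains, function(s) {
    base <- sum(s >= injection_time - baseline_span & s < injection_time) /
      baseline_span
    counts <- vapply(seq_len(nb), function(b)
      sum(s >= edges[b] & s < edges[b + 1]) / bin_width, numeric(1))
    if (base <= 0) rep(NA_real_, nb) else counts / base
  }, numeric(nb)))
  defined <- stats::sd(distances_um) > 0
  cors <- if (defined) {
    apply(norm, 2, function(col) {
      ok <- !is.na(col)
      if (sum(ok) < 3 || stats::sd(col[ok]) == 0) NA_real_
      else stats::cor(col[ok], distances_um[ok])
    })
  } else rep(NA_real_, nb)
  far <- which(distances_um > far_um)
  far_time <- Inf
  if (length(far) > 0) {
    supp <- apply(norm[far, , drop = FALSE] < suppression_threshold, 2, any)
    if (any(supp, na.rm = TRUE))
      far_time <- edges[which(supp)[1]] - injection_time
  }
  structure(list(bin_times = edges[-1] - bin_width / 2,
                 norm_rates = norm, correlation_by_bin = cors,
                 correlation_defined = defined,
                 far_suppression_time = far_time),
            class = "silencing_course")
}
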