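#' Weighted bootstrap confidence interval
#'
#' Percentile bootstrap CI of a summary statistic, resampling observations
#' with probability proportional to supplied weights. When several
#' measurements come from one animal, weights proportional to each animal's
#' contribution yield unbiased population-level resamples.
#'
#' @param values Numeric vector of observations.
#' @param weights Non-negative weights, one per observation (default equal).
#' @param stat Statistic to bootstrap: `"mean"` or `"median"`.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level as a fraction (default 0.95).
#' @param seed Integer seed; fixed seed gives reproducible intervals.
#' @return A list of class `ci_estimate` with fields `point`, `lo`, `hi`,
#'   `n_boot`, `level`, `weights_used`.
#' @examples
#' weighted_bootstrap_ci(rnorm(30), seed = 1)
#' @export
weighted_bootstrap_ci <- function(values, weights = NULL, stat = c("mean", "median"),
                                  n_boot = 10000, level = 0.95, seed = NULL) {
  stat <- match.arg(stat)
  if (length(values) == 0L) stop("no data")
  if (is.null(weights)) {
    weights_used <- FALSE
    weights <- rep(1, length(values))
  } else {
    weights_used <- TRUE
  }
  if (length(weights) != length(values)) stop("weights must match values in length")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights sum to zero")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (level <= 0 || level >= 1) stop("level must be in (0,1)")

  statfun <- switch(stat,
    mean = function(x, w) sum(x * w) / sum(w),
    median = weighted_median
  )
  point <- statfun(values, weights)

  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  n <- length(values)
  p <- weights / sum(weights)
  idx <- sample.int(n, n * n_boot, replace = TRUE, prob = p)
  draws <- matrix(values[idx], nrow = n)
  boots <- if (stat == "mean") colMeans(draws) else apply(draws, 2, stats::median)
  alpha <- (1 - level) / 2
  # type-6 quantiles realize the (B+1)*alpha order-statistic definition of
  # the percentile interval
  qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 6)
  structure(
    list(point = point, lo = qs[1], hi = qs[2], n_boot = as.integer(n_boot),
         level = level, weights_used = weights_used),
    class = "ci_estimate"
  )
}

# Weighted median: smallest x with cumulative weight >= half the total.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Firing-rate estimate by Gaussian-kernel smoothing of spike times
#'
#' Convolves spike times with a unit-area Gaussian kernel so the result is an
#' instantaneous rate in events/s. The kernel is truncated at +/-4 SD and each
#' spike's sampled kernel is renormalized so its trapezoidal area on the grid
#' is exactly one; the integral of the rate then equals the in-support spike
#' count.
#'
#' @param spike_times Spike times in seconds.
#' @param kernel_sd Kernel standard deviation in seconds (e.g. 0.05 for
#'   subthreshold-recording rates, 0.2 for unit rate-change detection).
#' @param grid Uniform time grid (seconds) on which to evaluate the rate.
#' @return A list of class `rate_trace` with `times`, `rate`, `kernel_sd`.
#' @export
gaussian_rate <- function(spike_times, kernel_sd, grid) {
  if (kernel_sd <= 0) stop("kernel_sd must be positive")
  if (length(grid) < 2L) stop("grid must have at least two samples")
  dt <- diff(grid)
  if (max(dt) - min(dt) > 1e-9 * mean(dt)) stop("grid must be uniform")
  dt <- mean(dt)
  rate <- numeric(length(grid))
  lo <- grid[1]; hi <- grid[length(grid)]
  spikes <- spike_times[spike_times >= lo & spike_times <= hi]
  half <- 4 * kernel_sd
  for (s in spikes) {
    i0 <- max(1L, ceiling((s - half - lo) / dt) + 1L)
    i1 <- min(length(grid), floor((s + half - lo) / dt) + 1L)
    if (i1 <= i0) next
    # taper to zero at the +/-4 SD truncation so the sampled kernel has
    # compact support, then renormalize to unit trapezoidal area
    k <- pmax(stats::dnorm(grid[i0:i1], mean = s, sd = kernel_sd) -
                stats::dnorm(half, 0, kernel_sd), 0)
    area <- pracma::trapz(grid[i0:i1], k)
    rate[i0:i1] <- rate[i0:i1] + k / area
  }
  structure(list(times = grid, rate = rate, kernel_sd = kernel_sd),
            class = "rate_trace")
}

#' Epoch significance by trial-bootstrap of the baseline-to-response change
#'
#' Computes, per trial, the mean over a response window minus the mean over a
#' baseline window, and bootstraps the across-trial mean of that change. The
#' change is called significant when the percentile CI excludes zero
#' (convention used for movement-aligned membrane-potential and firing-rate
#' trajectories: baseline 200 ms pre-cue, movement epoch -100..+100 ms).
#'
#' @param trial_traces Matrix, trials x time samples.
#' @param times Time (seconds) of each column.
#' @param baseline_window,response_window Two-element `c(t0, t1)` windows,
#'   half-open `[t0, t1)`, inside the time support.
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List of class `significance_result`: `effect`, `ci`, `significant`,
#'   `direction` (`"increase"`, `"decrease"` or `"none"`), `trial_effects`.
#' @export
epoch_significance <- function(trial_traces, times, baseline_window, response_window,
                               level = 0.95, n_boot = 10000, seed = NULL) {
  trial_traces <- as.matrix(trial_traces)
  if (nrow(trial_traces) < 2L) stop("need at least 2 trials")
  if (ncol(trial_traces) != length(times)) stop("times must match trace columns")
  bsel <- times >= baseline_window[1] & times < baseline_window[2]
  rsel <- times >= response_window[1] & times < response_window[2]
  if (!any(bsel) || !any(rsel)) stop("window outside time support")
  eff <- rowMeans(trial_traces[, rsel, drop = FALSE]) -
    rowMeans(trial_traces[, bsel, drop = FALSE])
  ci <- weighted_bootstrap_ci(eff, stat = "mean", n_boot = n_boot,
                              level = level, seed = seed)
  significant <- ci$lo > 0 || ci$hi < 0
  direction <- if (!significant) "none" else if (ci$lo > 0) "increase" else "decrease"
  structure(list(effect = mean(eff), ci = ci, significant = significant,
                 direction = direction, trial_effects = eff),
            class = "significance_result")
}

#' Trapezoidal area under a trace between two times
#'
#' Resamples the trace to a fixed sample interval by linear interpolation and
#' integrates with the trapezoid rule (the convention used for |dVm|
#' trajectory areas at a 50 ms sample rate).
#'
#' @param trace Numeric values of the trace.
#' @param times Time (seconds) of each sample.
#' @param t0,t1 Integration bounds, `t0 < t1`, inside the support.
#' @param dt Resampling interval in seconds (default 0.05).
#' @return Scalar area (trace units x seconds).
#' @export
trapezoid_auc <- function(trace, times, t0, t1, dt = 0.05) {
  if (t0 >= t1) stop("t0 must be < t1")
  if (dt <= 0) stop("dt must be positive")
  if (t0 < min(times) || t1 > max(times)) stop("integration bounds outside support")
  grid <- seq(t0, t1, by = dt)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  y <- stats::approx(times, trace, xout = grid)$y
  pracma::trapz(grid, y)
}

# Deterministic per-stage seed derivation from one run seed. Stage offsets
# are spaced far apart, and per-unit indices (FOVs, cells) enter through a
# large stride: R's Mersenne-Twister initialization leaves measurable
# correlation between streams seeded with adjacent integers, enough to
# couple units that must be independent. Results stay within 32-bit
# integer range.
derive_seed <- function(seed, stage, unit = 0L) {
  offsets <- c(trials = 1e6, calcium = 2e6, vm = 3e6,
               spikes = 4e6, motion = 5e6, spread = 6e6,
               calibration = 7e6, bootstrap = 8e6, analysis = 9e6,
               report = 1e7)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 11000027 + offsets[[stage]] +
                as.numeric(unit) * 977) %% .Machine$integer.max)
}

# Seed handling that leaves the caller's RNG stream untouched.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
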