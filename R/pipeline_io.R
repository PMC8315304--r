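#' Default run configuration
#'
#' All stage parameters with their standard defaults: 40 Hz imaging, 10,000
#' bootstrap samples, Friedman alpha 0.01, 375 ms SSF window, 27-frame
#' order-2 Savitzky-Golay smoothing, reaction-time boundaries 0.35/0.9 s,
#' rate-kernel SDs 0.05/0.2 s, spike-clip window (-1, +9) ms, and the
#' quoted baseline/response epochs. One global seed expands into per-stage
#' seeds deterministically (see `derive_seed`).
#'
#' @param seed Global run seed.
#' @param ... Named overrides of top-level entries.
#' @return Config list of class `run_config`.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_fovs = 3,
    n_rois = 8,
    session = list(n_trials = 80, iti_range = c(4, 6), rt_median = 0.32,
                   rt_dispersion = 1.0, miss_prob = 0.363, frame_rate = 40),
    model = list(model = "i", onset_lag = -0.3, amplitude = 0.5,
                 rise_time = 0.5, noise_sd = 0.05),
    fov_lag_sd = 0.05,
    calibration = list(n_cells = 100, n_trials = 30),
    n_boot = 10000,
    friedman_alpha = 0.01,
    min_trials_per_rt = 5
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

#' Validate trial tables and trace files
#'
#' Schema, monotonic-time, and cross-field invariant checks. Returns a
#' character vector of named violations; an empty vector means a clean table.
#'
#' @param trials Trial table data frame.
#' @return Character vector of diagnostics (possibly empty).
#' @export
validate_tables <- function(trials) {
  diags <- character(0)
  need <- c("trial_id", "cue_time", "movement_time", "reaction_time",
            "outcome", "reward_time")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0)
    return(paste0("missing column: ", missing))
  if (any(diff(trials$cue_time) <= 0))
    diags <- c(diags, "non-monotone cue times")
  both <- !is.na(trials$movement_time) & !is.na(trials$reaction_time)
  bad_rt <- abs(trials$reaction_time[both] -
                  (trials$movement_time[both] - trials$cue_time[both])) > 1e-9
  if (any(bad_rt))
    diags <- c(diags, "reaction_time != movement_time - cue_time")
  if (any(trials$outcome == "miss" & !is.na(trials$movement_time)))
    diags <- c(diags, "miss trial with movement_time")
  diags
}

# -- CSV / JSON dialects ----------------------------------------------------
# Comma-separated, header row, '.' decimal, times in seconds. Numeric
# columns are written with 17 significant digits so doubles round-trip
# bit-identically.

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write / read a trial table as CSV
#' @param trials Trial table.
#' @param path File path.
#' @export
write_trials_csv <- function(trials, path) {
  d <- trials
  for (nm in c("cue_time", "movement_time", "reaction_time", "reward_time"))
    d[[nm]] <- fmt_num(d[[nm]])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(trial_id = "integer", cue_time = "numeric",
                                 movement_time = "numeric",
                                 reaction_time = "numeric",
                                 outcome = "character",
                                 reward_time = "numeric"))
}

#' Write / read a fluorescence trace set as long-format CSV
#'
#' Columns: `roi`, `frame`, `time`, `F`.
#' @param calcium A `calcium_set` (or list with `frame_times`, `F`,
#'   `frame_rate`).
#' @param path File path.
#' @export
write_traces_csv <- function(calcium, path) {
  nf <- length(calcium$frame_times)
  nr <- ncol(calcium$F)
  d <- data.frame(
    roi = rep(seq_len(nr), each = nf),
    frame = rep(seq_len(nf), times = nr),
    time = fmt_num(rep(calcium$frame_times, times = nr)),
    F = fmt_num(as.numeric(calcium$F)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(roi = "integer", frame = "integer",
                                            time = "numeric", F = "numeric"))
  nr <- max(d$roi)
  nf <- max(d$frame)
  frame_times <- d$time[d$roi == 1]
  F <- matrix(d$F, nrow = nf, ncol = nr)
  list(frame_times = frame_times, F = F,
       frame_rate = 1 / stats::median(diff(frame_times)))
}

#' Write / read a membrane-potential trace as CSV (`time`, `mV`)
#' @param times,vm Trace.
#' @param path File path.
#' @export
write_vm_csv <- function(times, vm, path) {
  utils::write.csv(data.frame(time = fmt_num(times), mV = fmt_num(vm)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vm_csv
#' @export
read_vm_csv <- function(path) {
  utils::read.csv(path, colClasses = c(time = "numeric", mV = "numeric"))
}

#' Write / read spike-time lists as CSV (`unit`, `spike_time`)
#' @param spikes List of per-unit spike-time vectors.
#' @param path File path.
#' @export
write_spikes_csv <- function(spikes, path) {
  d <- data.frame(
    unit = rep(seq_along(spikes), vapply(spikes, length, integer(1))),
    spike_time = fmt_num(unlist(spikes)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(unit = "integer",
                                            spike_time = "numeric"))
  split(d$spike_time, factor(d$unit, levels = sort(unique(d$unit))))
}

# -- FOV-level analysis helpers ---------------------------------------------

#' Full per-cell analysis of one imaged field of view
#'
#' Chains dF/F normalization, movement-aligned Friedman classification,
#' per-trial SSF onset detection, calibrated bootstrap onset estimation, and
#' the IQR-based exclusion rule into a per-cell results table.
#'
#' @param calcium A `calcium_set` (raw fluorescence).
#' @param trials Trial table.
#' @param correction FOV calibration correction in seconds.
#' @param n_boot Bootstrap samples per cell (default 10000).
#' @param friedman_alpha Classification threshold (default 0.01).
#' @param seed Integer seed for the bootstraps.
#' @param align_window Movement-aligned analysis window.
#' @return List: `cells` (data frame `roi`, `category`, `friedman_p`,
#'   `median_onset`, `iqr`, `valid`, `n_detected`), `estimates` (list of
#'   `onset_estimate`s), `classifications`, `trial_onsets` (matrix ROI x
#'   push-trial, uncorrected, movement-aligned).
#' @export
analyze_fov <- function(calcium, trials, correction = 0, n_boot = 10000,
                        friedman_alpha = 0.01, seed = NULL,
                        align_window = c(-1.5, 1.5)) {
  push <- trials[trials$outcome == "push", ]
  nroi <- ncol(calcium$F)
  ests <- vector("list", nroi)
  clss <- vector("list", nroi)
  onset_mat <- matrix(NA_real_, nroi, nrow(push))
  for (r in seq_len(nroi)) {
    dff <- compute_dff(calcium$F[, r], calcium$frame_rate)$dff
    al <- align_trials(dff, calcium$frame_times, push$movement_time,
                       align_window)
    clss[[r]] <- classify_response(al$mat, al$rel_times,
                                   alpha = friedman_alpha)
    onsets <- detect_onset_mat(al$mat, al$rel_times)
    onset_mat[r, ] <- onsets
    sr <- if (is.null(seed)) NULL else derive_seed(seed, "bootstrap", r)
    ests[[r]] <- bootstrap_onset(onsets, n_boot = n_boot, seed = sr,
                                 correction = correction)
  }
  if (nroi >= 3) ests <- apply_exclusion(ests)
  cells <- do.call(rbind, lapply(seq_len(nroi), function(r) {
    e <- ests[[r]]; cl <- clss[[r]]
    responsive <- cl$category != "nonresponsive" && e$valid
    category <- if (!responsive) "nonresponsive" else
      paste0(if (e$median_onset < 0) "early_" else "late_", cl$category)
    data.frame(roi = r, category = category, friedman_p = cl$friedman_p,
               median_onset = if (responsive) e$median_onset else NA_real_,
               iqr = e$iqr, valid = e$valid, n_detected = e$n_detected,
               stringsAsFactors = FALSE)
  }))
  list(cells = cells, estimates = ests, classifications = clss,
       trial_onsets = onset_mat)
}

#' Per-FOV mean onsets split by reaction-time category
#'
#' Onset of each neuron is recomputed using only the trials of each
#' reaction-time category; the FOV's entry per category is the across-neuron
#' mean (corrected), with the category's trial count for the inclusion
#' floor. By default every category is subsampled to the smallest
#' category's trial count before the onset is taken: the per-trial
#' detection-error distribution is skewed, so a median over unequal trial
#' counts carries a count-dependent small-sample bias that would masquerade
#' as a reaction-time effect (trial-count matching mirrors the convention
#' used for raster comparisons).
#'
#' @param trial_onsets ROI x push-trial matrix of uncorrected movement-
#'   aligned onsets (from [analyze_fov()]).
#' @param trials Trial table (the push subset defines the columns).
#' @param fov FOV identifier.
#' @param correction Calibration correction (seconds).
#' @param equalize Subsample categories to a common trial count
#'   (default `TRUE`).
#' @param n_sub Common trial count to subsample to; `NULL` (default) uses
#'   the FOV's smallest category. Multi-FOV comparisons should pass one
#'   experiment-wide count (the smallest category of any included FOV) so
#'   the onset estimator's small-sample bias is identical for every value
#'   entering the ANOVA (see [rt_anova_experiment()]).
#' @param seed Seed for the subsampling (default derived from `fov`).
#' @return Data frame: `fov`, `group`, `mean_onset`, `n_trials` (the raw
#'   category count, used for the inclusion floor).
#' @export
fov_rt_onsets <- function(trial_onsets, trials, fov = 1, correction = 0,
                          equalize = TRUE, n_sub = NULL, seed = NULL) {
  push <- trials[trials$outcome == "push", ]
  groups <- split_by_rt(push)
  sels <- lapply(c(short = "short", medium = "medium", long = "long"),
                 function(g) which(groups == g))
  counts <- lengths(sels)
  if (equalize && all(counts > 0)) {
    if (is.null(seed)) seed <- derive_seed(fov + 1, "analysis")
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    nmin <- if (is.null(n_sub)) min(counts) else n_sub
    sels <- lapply(sels, function(s) sort(sample(s, min(nmin, length(s)))))
  }
  out <- lapply(names(sels), function(g) {
    sel <- sels[[g]]
    roi_onsets <- if (length(sel) > 0)
      apply(trial_onsets[, sel, drop = FALSE], 1, stats::median, na.rm = TRUE)
    else numeric(0)
    roi_onsets <- roi_onsets[!is.na(roi_onsets)]
    data.frame(fov = fov, group = g,
               mean_onset = if (length(roi_onsets) > 0)
                 mean(roi_onsets) - correction else NA_real_,
               n_trials = counts[[g]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full synthetic-to-analysis experiment
#'
#' Generates synthetic sessions and calcium data for several FOVs under the
#' configured population model, calibrates the onset detector at the
#' configured noise level, analyzes every FOV (classification, onsets,
#' exclusion), compares onsets across reaction-time categories, runs the
#' model discrimination, and scores parameter recovery against the
#' generator's ground truth. The report is a plain list that regenerates
#' bit-identically from (config, seed).
#'
#' @param config A [default_config()] list.
#' @return List of class `run_report`.
#' @export
run_experiment <- function(config = default_config()) {
  seed <- config$seed
  cal <- calibrate_onset_detector(
    noise_sd = config$model$noise_sd,
    n_cells = config$calibration$n_cells,
    n_trials = config$calibration$n_trials,
    frame_rate = config$session$frame_rate,
    amplitude = config$model$amplitude,
    rise_time = config$model$rise_time,
    seed = derive_seed(seed, "calibration"))
  # per-FOV true latency: populations differ in their lead on movement
  old <- local_seed(derive_seed(seed, "analysis"))
  fov_lags <- stats::rnorm(config$n_fovs, config$model$onset_lag,
                           config$fov_lag_sd)
  restore_seed(old)

  fovs <- vector("list", config$n_fovs)
  rt_rows <- list()
  feats <- list()
  all_cells <- list()
  for (f in seq_len(config$n_fovs)) {
    sseed <- derive_seed(seed, "trials", f)
    spec <- session_spec(n_trials = config$session$n_trials,
                         iti_range = config$session$iti_range,
                         rt_median = config$session$rt_median,
                         rt_dispersion = config$session$rt_dispersion,
                         miss_prob = config$session$miss_prob,
                         frame_rate = config$session$frame_rate,
                         seed = sseed)
    trials <- simulate_trials(spec)
    model <- population_model_spec(
      model = config$model$model, onset_lag = fov_lags[f],
      amplitude = config$model$amplitude, rise_time = config$model$rise_time,
      noise_sd = config$model$noise_sd)
    calcium <- simulate_calcium(trials, config$n_rois, model,
                                frame_rate = spec$frame_rate,
                                seed = derive_seed(seed, "calcium", f))
    fa <- analyze_fov(calcium, trials, correction = cal$correction,
                      n_boot = config$n_boot,
                      friedman_alpha = config$friedman_alpha,
                      seed = seed + f)
    rt_rows[[f]] <- fov_rt_onsets(fa$trial_onsets, trials, fov = f,
                                  correction = cal$correction)
    push <- trials[trials$outcome == "push", ]
    dff1 <- compute_dff(calcium$F[, 1], calcium$frame_rate)$dff
    al <- align_trials(dff1, calcium$frame_times, push$movement_time,
                       c(-3, 1.5))
    feats[[f]] <- trial_onset_table(al$mat, al$rel_times, push$reaction_time)
    all_cells[[f]] <- cbind(fov = f, fa$cells)
    fovs[[f]] <- list(trials = trials, ground_truth = calcium$ground_truth)
  }
  cells <- do.call(rbind, all_cells)
  rt_tab <- do.call(rbind, rt_rows)
  anova_p <- tryCatch(
    compare_onsets_across_rt(rt_tab,
                             min_trials = config$min_trials_per_rt)$anova_p,
    error = function(e) NA_real_)
  features <- do.call(rbind, feats)
  verdict <- discriminate_model(features)
  valid_onsets <- cells$median_onset[!is.na(cells$median_onset)]
  truth_lag <- if (config$model$model == "i") config$model$onset_lag else NA_real_
  report <- list(
    config = unclass(config),
    calibration = list(noise_sd = cal$noise_sd, bias = cal$bias,
                       correction = cal$correction,
                       detect_frac = cal$detect_frac),
    session = list(
      n_trials = config$session$n_trials * config$n_fovs,
      n_push = sum(vapply(fovs, function(f)
        sum(f$trials$outcome == "push"), numeric(1))),
      rt_median = stats::median(unlist(lapply(fovs, function(f)
        f$trials$reaction_time)), na.rm = TRUE)),
    cells = cells,
    population = list(
      n_responsive = sum(!is.na(cells$median_onset)),
      median_onset = if (length(valid_onsets) > 0)
        stats::median(valid_onsets) else NA_real_),
    rt_anova_p = anova_p,
    verdict = list(model = verdict$model, onset_slope = verdict$onset_slope,
                   t90_slope = verdict$t90_slope),
    recovery = list(
      true_onset_lag = truth_lag,
      onset_error = if (!is.na(truth_lag) && length(valid_onsets) > 0)
        stats::median(valid_onsets) - truth_lag else NA_real_)
  )
  structure(report, class = "run_report")
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output file path.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
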