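test_that("dF/F normalization matches a brute-force percentile oracle", {
  fr <- 40
  n <- 40 * fr
  raw <- rep(100, n)
  d <- compute_dff(raw, fr)
  expect_equal(d$f0, 100)
  expect_equal(d$dff, rep(0, n))

  # isolated transient event: F0 from an independently filtered copy
  # (reflection-padded zero-phase Butterworth written out by hand)
  raw2 <- raw
  raw2[800:820] <- 200
  d2 <- compute_dff(raw2, fr)
  bf <- signal::butter(4, 1 / (fr / 2), type = "low")
  pad <- 5 * fr
  xp <- c(2 * raw2[1] - raw2[(pad + 1):2], raw2,
          2 * raw2[n] - raw2[(n - 1):(n - pad)])
  ref <- as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + n)]
  ref_f0 <- quantile(ref, 0.05, names = FALSE)
  expect_equal(d2$f0, ref_f0)
  expect_equal(d2$dff[810], (200 - ref_f0) / ref_f0)

  # scale invariance
  d3 <- compute_dff(raw2 * 7, fr)
  expect_equal(d3$dff, d2$dff, tolerance = 1e-9)
  expect_error(compute_dff(rep(-5, n), fr), "baseline")
})

test_that("slope sum function matches hand evaluation and its invariances", {
  fr <- 40
  dec <- seq(5, 1, length.out = 200)
  expect_true(all(slope_sum(dec, fr) == 0))

  # unit step at frame k, smoothing bypassed: SSF = 1 on k..k+w-1
  k <- 100; w <- 15
  step <- c(rep(0, k - 1), rep(1, 200 - k + 1))
  s <- slope_sum(step, fr, smooth = FALSE)
  expect_equal(which(s > 0), k:(k + w - 1))
  expect_true(all(s[s > 0] == 1))

  set.seed(1)
  x <- cumsum(rnorm(300))
  expect_equal(slope_sum(x, fr), slope_sum(x + 17.3, fr), tolerance = 1e-9)
  expect_error(slope_sum(1:10, fr), "shorter")
})

test_that("batched SSF detection equals the single-trial path", {
  set.seed(3)
  times <- seq(-1.5, 1.5, by = 0.025)
  mat <- matrix(rnorm(20 * length(times), 0, 0.05), nrow = 20)
  mat[, times >= -0.3] <- mat[, times >= -0.3] + 0.5
  batch <- detect_onset_mat(mat, times)
  single <- apply(mat, 1, detect_onset_trial, times = times)
  expect_equal(batch, single)
})

test_that("onset detection finds noiseless ramps, ignores flat traces, and is amplitude invariant", {
  times <- seq(-2, 1.5, by = 0.025)
  tr <- perimove:::ramp_transient(times, -0.3, 0.5, 0.5)
  expect_equal(detect_onset_trial(tr, times), -0.3, tolerance = 0.026)
  expect_true(is.na(detect_onset_trial(rep(0, length(times)), times)))
  expect_equal(detect_onset_trial(tr * 2, times),
               detect_onset_trial(tr, times))
  expect_error(detect_onset_trial(tr, times, search_window = c(5, 6)), "empty")
})

test_that("onset detection on one trial does not leak across trials", {
  times <- seq(-1.5, 1.5, by = 0.025)
  tr1 <- perimove:::ramp_transient(times, -0.3, 0.5, 0.5)
  set.seed(8)
  alone <- detect_onset_trial(tr1 + rnorm(length(times), 0, 0.03), times)
  set.seed(8)
  noisy1 <- tr1 + rnorm(length(times), 0, 0.03)
  other <- matrix(rnorm(5 * length(times)), nrow = 5)
  expect_equal(detect_onset_mat(rbind(noisy1, other), times)[1], alone)
})

test_that("bootstrap onset statistics match the small-n enumeration oracle", {
  est0 <- bootstrap_onset(rep(-0.3, 8), n_boot = 500, seed = 1)
  expect_equal(est0$median_onset, -0.3)
  expect_equal(est0$iqr, 0)
  expect_true(est0$valid)

  # {-0.4, -0.2} in equal numbers: the bootstrap-median distribution has
  # CDF 0.344 at -0.4 and 0.656 at -0.3, so its median is -0.3
  est <- bootstrap_onset(rep(c(-0.4, -0.2), each = 3), n_boot = 10000, seed = 2)
  expect_equal(est$median_onset, -0.3, tolerance = 0.051)

  und <- bootstrap_onset(c(-0.3, -0.3, NA, NA, NA, NA), n_boot = 100)
  expect_false(und$valid)
  expect_equal(und$n_detected, 2L)

  expect_equal(bootstrap_onset(rep(-0.3, 8), n_boot = 500, seed = 7,
                               correction = -0.05)$median_onset, -0.25)
})

test_that("IQR exclusion flags only extreme cells and ignores ordering", {
  mk <- function(iqr) list(iqr = iqr, valid = TRUE)
  same <- apply_exclusion(replicate(5, mk(0.1), simplify = FALSE))
  expect_true(all(vapply(same, `[[`, logical(1), "valid")))

  # a 100x IQR outlier in a realistic cohort (the outlier itself inflates
  # the SD, so the rule needs ~10+ cells to trigger, as in real FOVs)
  ests <- c(replicate(12, mk(0.1), simplify = FALSE), list(mk(10)))
  out <- apply_exclusion(ests)
  expect_equal(vapply(out, `[[`, logical(1), "valid"),
               c(rep(TRUE, 12), FALSE))
  perm <- apply_exclusion(rev(ests))
  expect_equal(vapply(perm, `[[`, logical(1), "valid"),
               c(FALSE, rep(TRUE, 12)))
  expect_error(apply_exclusion(ests[1:2]), "at least 3")
})

test_that("response classification separates noiseless steps by direction", {
  times <- seq(-1.5, 1.5, by = 0.025)
  up <- t(replicate(8, as.numeric(times >= 0)))
  dn <- -up
  cu <- classify_response(up, times)
  cd <- classify_response(dn, times)
  expect_lt(cu$friedman_p, 0.01)
  expect_equal(cu$category, "increase")
  expect_equal(cd$category, "decrease")
  expect_true(all(cu$significant_bins > 2))  # steps at movement, bins after
  expect_error(classify_response(up[1:2, ], times), "3 trials")
})

test_that("null traces are rarely classified responsive", {
  set.seed(21)
  times <- seq(-1.5, 1.5, by = 0.025)
  hits <- replicate(200, {
    m <- matrix(rnorm(15 * length(times), 0, 0.05), nrow = 15)
    classify_response(m, times)$category != "nonresponsive"
  })
  expect_lte(mean(hits), 0.03)
})

test_that("reaction-time splitting uses the fixed half-open boundaries", {
  tr <- data.frame(outcome = rep("push", 6),
                   reaction_time = c(0.2, 0.349, 0.35, 0.5, 0.9, 1.2))
  expect_equal(split_by_rt(tr),
               c("short", "short", "medium", "medium", "long", "long"))
  tr$outcome[1] <- "miss"
  expect_true(is.na(split_by_rt(tr)[1]))
})

test_that("RT-group ANOVA is exact on degenerate input and enforces the FOV floor", {
  d <- expand.grid(fov = 1:4, group = c("short", "medium", "long"))
  d$mean_onset <- -0.3
  d$n_trials <- 10
  res <- compare_onsets_across_rt(d)
  expect_equal(res$anova_p, 1)
  expect_equal(sort(res$included_fovs), as.character(1:4))

  d2 <- d
  d2$n_trials[d2$fov == 1 & d2$group == "long"] <- 2
  res2 <- compare_onsets_across_rt(d2)
  expect_false("1" %in% res2$included_fovs)

  d3 <- d[d$group == "short", ]
  expect_error(compare_onsets_across_rt(d3), "2 reaction-time groups")
})

test_that("the RT comparison rejects cue-anchored onsets and retains movement-locked ones", {
  # model iii: onset tracks the cue, so movement-aligned onsets differ
  # across RT groups by construction
  p_iii <- vapply(1:5, function(s)
    rt_anova_experiment(seed = 4000 + s, model = "iii", n_fovs = 6),
    numeric(1))
  expect_true(all(p_iii < 0.05))
  p_i <- vapply(1:5, function(s)
    rt_anova_experiment(seed = 4100 + s, model = "i", n_fovs = 6),
    numeric(1))
  expect_gt(mean(p_i > 0.05), 0.5)
})

test_that("aligned averages are flat for constant trials and loess preserves linear interiors", {
  times <- seq(-1.5, 1.5, by = 0.025)
  const <- matrix(2.5, 6, length(times))
  av <- aligned_average(const, times, n_boot = 100, seed = 1)
  expect_equal(av$mean, rep(0, length(times)), tolerance = 1e-9)

  lin <- matrix(rep(times, each = 6), nrow = 6)
  av2 <- aligned_average(lin, times, n_boot = 100, seed = 1)
  interior <- times > -1 & times < 1
  base <- mean(times[times >= -1 & times < -0.5])
  expect_equal(av2$mean[interior], times[interior] - base, tolerance = 1e-6)
})

test_that("onset KDE integrates to one and preserves the sample mean", {
  set.seed(9)
  x <- rnorm(200, -0.3, 0.1)
  k <- population_onset_kde(x, bandwidth = 0.05)
  expect_equal(k$auc, 1, tolerance = 1e-3)
  expect_equal(k$mean, mean(x), tolerance = 1e-3)
  x1 <- rep(-0.25, 50)
  k1 <- population_onset_kde(x1)
  expect_equal(k1$x[which.max(k1$density)], -0.25, tolerance = 0.01)
  expect_error(population_onset_kde(rnorm(5)), "10 onsets")
})

test_that("calibration is unbiased at zero noise and fails on uncalibratable noise", {
  cal <- calibrate_onset_detector(0, n_cells = 10, n_trials = 10, seed = 1)
  expect_lt(abs(cal$bias), 0.026)
  expect_equal(cal$detect_frac, 1)
  expect_error(calibrate_onset_detector(50, n_cells = 5, n_trials = 5, seed = 1),
               "uncalibratable")
})

test_that("model discrimination recovers each generating model and guards RT spread", {
  expect_equal(discriminate_model(model_features("i", seed = 3))$model, "i")
  expect_equal(discriminate_model(model_features("ii", seed = 3))$model, "ii")
  expect_equal(discriminate_model(model_features("iii", seed = 3))$model, "iii")

  f <- model_features("i", seed = 4)
  f$rt <- 0.3 + runif(nrow(f), 0, 0.05)  # spread below 100 ms
  expect_equal(discriminate_model(f)$model, "indeterminate")
  expect_equal(discriminate_model(f[1:5, ])$model, "indeterminate")
})

test_that("onset estimates are invariant to uniform time shifts of the session", {
  tr <- quick_trials(n = 25, seed = 17)
  m <- population_model_spec("i", noise_sd = 0.05)
  ca <- simulate_calcium(tr, 1, m, seed = 18)
  al1 <- aligned_dff(ca, tr)
  ons1 <- detect_onset_mat(al1$mat, al1$rel_times)

  shift <- 100
  tr2 <- tr
  for (nm in c("cue_time", "movement_time", "reward_time"))
    tr2[[nm]] <- tr2[[nm]] + shift
  ca2 <- ca
  ca2$frame_times <- ca$frame_times + shift
  al2 <- aligned_dff(ca2, tr2)
  ons2 <- detect_onset_mat(al2$mat, al2$rel_times)
  expect_equal(ons1, ons2, tolerance = 1e-9)
})

test_that("the pipeline recovers movement-locked population latencies", {
  # end-to-end parameter recovery across several true lags
  cal <- calibrate_onset_detector(0.05, n_cells = 30, n_trials = 20, seed = 5)
  for (L in c(-0.2, -0.3, -0.4)) {
    tr <- quick_trials(n = 50, seed = 19 - round(10 * L))
    m <- population_model_spec("i", onset_lag = L, noise_sd = 0.05)
    ca <- simulate_calcium(tr, 4, m, seed = 20 - round(10 * L))
    meds <- sapply(1:4, function(r) {
      al <- aligned_dff(ca, tr, roi = r)
      ons <- detect_onset_mat(al$mat, al$rel_times)
      bootstrap_onset(ons, n_boot = 1000, seed = r,
                      correction = cal$correction)$median_onset
    })
    expect_lt(abs(median(meds) - L), 0.05)
  }
})
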