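test_that("spike detection recovers all ground-truth spikes and nothing else", {
  tr <- quick_trials(n = 10, seed = 1)
  v <- simulate_vm(tr, "depolarizing", seed = 2)
  gt <- v$ground_truth
  sp <- detect_spikes(v$vm, v$times)
  det <- vapply(sp, `[[`, numeric(1), "peak_time")
  expect_equal(length(det), length(gt$spike_peak_times))
  expect_true(all(vapply(det, function(t)
    min(abs(gt$spike_peak_times - t)) < 0.002, logical(1))))
  # flat trace and DC invariance
  expect_length(detect_spikes(rep(-65, 20000), seq(0, 1, length.out = 20000)), 0)
  sp2 <- detect_spikes(v$vm + 30, v$times)
  expect_equal(length(sp2), length(sp))
})

test_that("AP threshold sits at the waveform kink with the earliest-tie rule", {
  tr <- quick_trials(n = 10, seed = 3)
  v <- simulate_vm(tr, "depolarizing", seed = 4)
  gt <- v$ground_truth
  sp <- detect_spikes(v$vm, v$times)
  errs <- vapply(sp, function(s)
    min(abs(gt$spike_threshold_times - s$threshold_time)), numeric(1))
  expect_lt(max(errs), 2e-4)
  expect_true(all(vapply(sp, function(s) s$threshold_vm <= s$peak_vm,
                         logical(1))))

  # exactly constant second difference before the peak (integer squares
  # scaled by a power of two are float-exact): earliest sample wins the tie
  dt <- 5e-5
  t <- seq(0, 0.01, by = dt)
  par <- (seq_along(t) - 1)^2 / 1024 - 65
  ev <- ap_threshold(par, t, 0.01)
  expect_equal(ev$threshold_time, 0.01 - 0.003, tolerance = dt / 10)

  expect_warning(ap_threshold(par, t, 0.001), "edge")
})

test_that("spike clipping removes exactly the -1..+9 ms span and merges overlaps", {
  dt <- 5e-5
  t <- seq(0, 1, by = dt)
  vm <- rep(-60, length(t))
  sp1 <- list(structure(list(threshold_time = 0.5, peak_time = 0.5004),
                        class = "spike_event"))
  vm_sp <- vm
  vm_sp[t >= 0.499 & t < 0.509] <- 0
  out <- clip_spikes(vm_sp, t, sp1)
  expect_equal(sum(out != vm_sp), 200)
  expect_equal(out, vm)

  # untouched without spikes
  expect_identical(clip_spikes(vm_sp, t, list()), vm_sp)

  # two spikes 5 ms apart: one merged span of 15 ms
  sp2 <- list(structure(list(threshold_time = 0.5), class = "spike_event"),
              structure(list(threshold_time = 0.505), class = "spike_event"))
  out2 <- clip_spikes(vm_sp, t, sp2)
  changed <- which(out2 != vm_sp | (t >= 0.499 & t < 0.514))
  expect_equal(range(t[changed]), c(0.499, 0.514 - dt), tolerance = dt / 2)
})

test_that("clipped traces contain no redetectable spikes", {
  tr <- quick_trials(n = 8, seed = 5)
  v <- simulate_vm(tr, "depolarizing", seed = 6)
  sp <- detect_spikes(v$vm, v$times)
  sub <- clip_spikes(v$vm, v$times, sp)
  expect_length(detect_spikes(sub, v$times), 0)
})

test_that("dVm trajectories are exact on constant and step inputs", {
  times <- seq(-2, 1, by = 5e-5)
  cue_rel <- rep(-0.5, 4)
  const <- matrix(-63, 4, length(times))
  d0 <- delta_vm_trajectory(const, times, cue_rel, n_boot = 200, seed = 1)
  expect_equal(max(abs(d0$dvm)), 0)
  expect_false(d0$significance$significant)

  step <- matrix(rep(ifelse(times >= 0, -58, -63), each = 4), nrow = 4)
  d5 <- delta_vm_trajectory(step, times, cue_rel, n_boot = 200, seed = 1)
  expect_equal(d5$significance$effect, 2.5, tolerance = 1e-6)  # half-window step
  expect_equal(d5$significance$direction, "increase")
  # decimated to 1 kHz
  expect_equal(median(diff(d5$times)), 0.001, tolerance = 1e-9)
  # median filter leaves a monotone ramp's interior unchanged
  ramp <- matrix(rep(pmax(times, 0) * 10, each = 4), nrow = 4)
  dr <- delta_vm_trajectory(ramp, times, cue_rel, n_boot = 200, seed = 1)
  interior <- dr$times > 0.1 & dr$times < 0.9
  expect_equal(dr$dvm[interior], pmax(dr$times[interior], 0) * 10,
               tolerance = 1e-6)
})

test_that("population normalization scales each trajectory to unit extremum", {
  tt <- seq(-1, 1, by = 0.001)
  tr1 <- list(times = tt, dvm = -4 * exp(-(tt)^2 / 0.02))
  tr2 <- list(times = tt, dvm = 2 * exp(-(tt)^2 / 0.02))
  out <- normalize_population(list(tr1, tr2))
  expect_equal(min(out[[1]]$normalized), -1)
  expect_equal(max(out[[2]]$normalized), 1)
  # scale invariance
  tr3 <- list(times = tt, dvm = tr2$dvm * 13)
  expect_equal(normalize_population(list(tr3))[[1]]$normalized,
               out[[2]]$normalized)
  expect_error(normalize_population(list(list(times = tt, dvm = tt * 0))),
               "zero normalizer")
})

test_that("Vm onsets follow the 10% rise-time rule with sign symmetry", {
  tt <- seq(-1, 1.4, by = 0.001)
  ramp <- ifelse(tt < 0, 0, ifelse(tt < 1, 10 * tt, 10))
  traj <- list(times = tt, dvm = ramp,
               significance = list(significant = TRUE))
  expect_equal(vm_onset(traj, window = c(-0.5, 1.4)), 0.1, tolerance = 1e-6)

  neg <- traj
  neg$dvm <- -ramp
  expect_equal(vm_onset(neg, window = c(-0.5, 1.4)), 0.1, tolerance = 1e-6)

  step <- traj
  step$dvm <- ifelse(tt >= 0.2, 5, 0)
  expect_lt(abs(vm_onset(step, window = c(-0.5, 1)) - 0.2), 0.0015)

  ns <- traj
  ns$significance$significant <- FALSE
  expect_true(is.na(vm_onset(ns)))
})

test_that("simulated Vm deflections are recovered within tolerance", {
  tr <- quick_trials(n = 12, seed = 7)
  v <- simulate_vm(tr, "depolarizing", deflection_amp = 5,
                   deflection_lag = -0.2, seed = 8)
  sp <- detect_spikes(v$vm, v$times)
  sub <- clip_spikes(v$vm, v$times, sp)
  push <- tr[tr$outcome == "push", ]
  al <- align_trials(sub, v$times, push$movement_time, c(-2, 1))
  d <- delta_vm_trajectory(al$mat, al$rel_times,
                           push$cue_time - push$movement_time,
                           n_boot = 500, seed = 1)
  expect_equal(d$significance$direction, "increase")
  # 10% rise of the raised-cosine deflection: 0.5*(1-cos(pi*t/rise)) = 0.1
  # at t = 0.205 * rise, i.e. onset_lag + 0.205 * 0.3 = -0.139
  on <- vm_onset(d)
  expect_lt(abs(on - (-0.139)), 0.02)
  expect_equal(max(d$dvm), 5, tolerance = 0.25)
})

test_that("muscimol AUC comparison is exact on identity and zero and matches an analytic integral", {
  tt <- seq(-0.5, 2, by = 0.001)
  dvm <- matrix(rep(sin(pi * pmax(tt, 0)), each = 4), nrow = 4)
  ep <- list(dvm_trials = dvm, times = tt,
             spike_trials = replicate(4, c(0.1, 0.5), simplify = FALSE),
             reward_rel = rep(1, 4), rt = rep(0.4, 4))
  mc <- muscimol_auc_comparison(ep, ep)
  expect_equal(mc$ratio, 1)
  expect_equal(mc$rate_change_pre, mc$rate_change_post)
  # |sin(pi t)| over [0, 1] integrates to 2/pi
  expect_equal(mc$auc_pre, 2 / pi, tolerance = 0.01)

  ep0 <- ep
  ep0$dvm_trials <- dvm * 0
  mc0 <- muscimol_auc_comparison(ep, ep0)
  expect_equal(mc0$ratio, 0)
  mcz <- muscimol_auc_comparison(ep0, ep)
  expect_false(mcz$ratio_defined)
  expect_true(is.na(mcz$ratio))
})

test_that("dVm-rate correlation handles exact linear relations", {
  x <- c(1, 2, 3, 4)
  expect_equal(correlate_dvm_rate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate_dvm_rate(x, -x)$r, -1)
  a <- c(0.3, 1.1, 2.2, 2.9, 4.1)
  b <- c(1.2, 0.8, 2.5, 3.9, 3.1)
  expect_equal(correlate_dvm_rate(a, b)$r,
               correlate_dvm_rate(10 * a + 3, b)$r, tolerance = 1e-12)
  expect_error(correlate_dvm_rate(1:2, 1:2), "3 pairs")
})
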