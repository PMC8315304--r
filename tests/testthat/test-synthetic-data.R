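test_that("trial tables respect the task structure and are reproducible", {
  tr <- quick_trials(n = 50, seed = 2)
  expect_true(all(diff(tr$cue_time) > 4))  # ITI lower bound plus trial span
  itis <- diff(tr$cue_time) - 3.5
  expect_true(all(itis >= 4 & itis <= 6))
  push <- tr$outcome == "push"
  expect_equal(tr$reaction_time[push],
               tr$movement_time[push] - tr$cue_time[push])
  expect_true(all(is.na(tr$movement_time[!push])))
  expect_identical(tr, quick_trials(n = 50, seed = 2))
  expect_false(identical(tr, quick_trials(n = 50, seed = 3)))
})

test_that("reaction times recover the configured median and populate all categories", {
  tr <- quick_trials(n = 10000, seed = 4)
  rt <- tr$reaction_time[!is.na(tr$reaction_time)]
  expect_equal(median(rt), 0.32, tolerance = 0.02)
  groups <- table(split_by_rt(tr))
  expect_true(all(c("short", "medium", "long") %in% names(groups)))
  expect_true(all(groups > 100))
  expect_equal(mean(tr$outcome == "miss"), 0.363, tolerance = 0.03)
})

test_that("calcium transients start at the ground-truth onset", {
  tr <- quick_trials(n = 15, seed = 5)
  m <- population_model_spec("i", onset_lag = -0.3, noise_sd = 0)
  ca <- simulate_calcium(tr, 2, m, seed = 6)
  gt <- ca$ground_truth
  push <- tr[tr$outcome == "push", ]
  expect_equal(gt$true_onset_rel[gt$roi == 1], rep(-0.3, nrow(push)))
  # noiseless trace is flat before onset and rising right after, per trial
  dt <- 1 / ca$frame_rate
  for (k in seq_len(min(5, nrow(push)))) {
    on <- gt$true_onset[gt$roi == 1][k]
    pre <- ca$F[ca$frame_times < on & ca$frame_times > on - 0.5, 1]
    # flat up to the previous trial's residual exponential tail (< 0.1%)
    expect_lt(max(abs(pre - 100)), 0.1)
    post <- ca$F[ca$frame_times >= on + dt & ca$frame_times < on + 0.2, 1]
    expect_true(all(diff(post) > 0))
  }
  # ground truth is exhaustive: one entry per ROI per push trial
  expect_equal(nrow(gt), 2 * nrow(push))
  expect_error(population_model_spec("i", amplitude = -1), "amplitude")
})

test_that("miss trials carry no transient", {
  tr <- quick_trials(n = 40, seed = 7)
  m <- population_model_spec("i", noise_sd = 0)
  ca <- simulate_calcium(tr, 1, m, seed = 8)
  miss <- tr[tr$outcome == "miss", ]
  for (k in seq_len(nrow(miss))) {
    sel <- ca$frame_times >= miss$cue_time[k] &
      ca$frame_times <= miss$cue_time[k] + 1
    # flat at baseline unless a neighboring push transient bleeds in
    prev_push <- tr$movement_time[tr$outcome == "push" &
                                    tr$cue_time < miss$cue_time[k]]
    if (length(prev_push) == 0 ||
        miss$cue_time[k] - max(prev_push) > 6) {
      # flat up to residual decay tails of earlier transients
      expect_lt(max(abs(ca$F[sel, 1] - 100)), 0.1)
    }
  }
})

test_that("model ii plateaus until movement and model iii peaks at movement", {
  tr <- quick_trials(n = 30, seed = 9)
  push <- tr[tr$outcome == "push", ]
  long <- push[push$reaction_time > 1, ]
  expect_gt(nrow(long), 0)  # fixed seed guarantees a long-RT trial
  m2 <- population_model_spec("ii", noise_sd = 0)
  ca2 <- simulate_calcium(tr, 1, m2, seed = 10)
  k <- which.max(push$reaction_time)
  sel <- ca2$frame_times >= push$cue_time[k] + 0.6 &
    ca2$frame_times <= push$movement_time[k] - 0.05
  expect_equal(diff(range(ca2$F[sel, 1])), 0, tolerance = 1e-9)  # plateau
  m3 <- population_model_spec("iii", noise_sd = 0)
  ca3 <- simulate_calcium(tr, 1, m3, seed = 10)
  ipk <- which.max(ca3$F[ca3$frame_times > push$cue_time[k] - 0.1 &
                           ca3$frame_times < push$movement_time[k] + 1, 1])
  tsel <- ca3$frame_times[ca3$frame_times > push$cue_time[k] - 0.1 &
                            ca3$frame_times < push$movement_time[k] + 1]
  expect_equal(tsel[ipk], push$movement_time[k], tolerance = 0.05)
})

test_that("vm simulation is flat when silenced and records exact spike times", {
  tr <- quick_trials(n = 5, seed = 11)
  v0 <- simulate_vm(tr, "none", noise_sd = 0, baseline_rate = 0, seed = 1)
  expect_equal(v0$vm, rep(-65, length(v0$vm)))

  v1 <- simulate_vm(tr, "depolarizing", seed = 2)
  expect_true(length(v1$ground_truth$spike_threshold_times) > 0)
  # inserted waveform peaks exactly at the recorded peak times
  dt <- 1 / v1$sample_rate
  for (pt in v1$ground_truth$spike_peak_times[1:5]) {
    i <- round(pt / dt) + 1
    expect_gt(v1$vm[i], median(v1$vm) + 30)
  }
  # deterministic
  v2 <- simulate_vm(tr, "depolarizing", seed = 2)
  expect_identical(v1$vm, v2$vm)
})

test_that("depolarizing Vm profile yields a significant increase through epoch_significance", {
  tr <- quick_trials(n = 8, seed = 12)
  v <- simulate_vm(tr, "depolarizing", noise_sd = 0, baseline_rate = 0, seed = 1)
  push <- tr[tr$outcome == "push", ]
  al <- align_trials(v$vm, v$times, push$movement_time, c(-1, 0.5), dt = 0.001)
  s <- epoch_significance(al$mat, al$rel_times, c(-0.9, -0.7), c(-0.1, 0.1),
                          n_boot = 300, seed = 1)
  expect_equal(s$direction, "increase")
})

test_that("spike trains follow the configured Poisson rates", {
  tr <- quick_trials(n = 30, seed = 13)
  st <- simulate_spiketrains(tr, baseline_rate = 8, response_gain = 1, seed = 3)
  expect_equal(length(st$spikes[[1]]) / st$duration, 8, tolerance = 0.15)
  st0 <- simulate_spiketrains(tr, baseline_rate = 8, response_gain = 0, seed = 3)
  iv <- st0$ground_truth$intervals
  inside <- sapply(st0$spikes[[1]], function(s)
    any(s >= iv[, 1] & s < iv[, 2]))
  expect_false(any(inside))
  expect_identical(st$spikes,
                   simulate_spiketrains(tr, 8, 1, seed = 3)$spikes)
})

test_that("motion frames are quiet without movement and identical frames give MI zero", {
  tr <- quick_trials(n = 10, seed = 14)
  mf <- simulate_motion_frames(tr, movement_amp = 0, seed = 4)
  expect_equal(nrow(mf$ground_truth), 0)
  mi <- motion_index(rbind(c(3, 7, 1), c(3, 7, 1)))
  expect_equal(mi$mi, 0)
  mf2 <- simulate_motion_frames(tr, seed = 4)
  expect_equal(nrow(mf2$ground_truth), sum(tr$outcome == "push"))
})

test_that("spread blobs recover monotonically larger radii for larger scales", {
  radii <- sapply(c(5, 10, 20), function(sg) {
    si <- simulate_spread_images(1, sigma_px = sg, size = 151, seed = 6)
    threshold_spread(si$images[[1]], 1, 0.2, si$centers[1, ])$equivalent_radius_px
  })
  expect_true(all(diff(radii) > 0))
})
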