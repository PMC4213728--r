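test_that("parameter constructors enforce their invariants", {
  expect_error(trajectory_params(lam_peak_range = c(260, 210)), "increasing range")
  expect_error(trajectory_params(lam_peak_range = c(150, 260)), "strictly inside")
  expect_error(trajectory_params(wag_peak_range = c(185, 205)), "strictly inside")
  expect_error(trajectory_params(frame_rate = 0), "frame_rate")
  expect_error(spike_train_params(burst_period_mean = 8, burst_duration_mean = 10),
               "ISI bands")
  expect_error(spike_train_params(burst_period_mean = 200, burst_duration_mean = 10),
               "ISI bands")
  expect_error(survival_params(doses = c(5, 10)), "brackets 50%")
  expect_error(behavior_count_params(phenotype_probabilities = list(
    control = c(a = 0.5), mn = c(a = 1.5), recovered = c(a = 0))), "\\[0, 1\\]")
})

test_that("a generator with no events and no jitter is flat at 180 degrees", {
  p <- trajectory_params(lam_rate = 0, wag_cluster_rate = 0, rest_jitter_sd = 0,
                         duration = 2, seed = 1)
  sim <- simulate_trajectory(p)
  expect_equal(nrow(sim$events), 0)
  expect_true(all(sim$angle$theta == 180))
  expect_true(all(compute_body_angle(sim$track)$theta == 180))
})

test_that("recomputed body angle reproduces the generated trace within 1e-6 deg", {
  for (preset in c("control", "mn", "recovered")) {
    sim <- simulate_trajectory(trajectory_preset(preset, seed = 13))
    trace <- compute_body_angle(sim$track)
    expect_lt(max(abs(trace$theta - sim$angle$theta)), 1e-6)
    expect_lt(max(abs(trace$signed_theta - sim$angle$signed_theta)), 1e-6)
  }
})

test_that("scheduled events are recovered exactly in count and class", {
  for (seed in 1:10) {
    sim <- simulate_trajectory(trajectory_preset("control", seed = seed))
    ev <- detect_events(compute_body_angle(sim$track))
    truth <- dplyr::arrange(sim$events, onset)
    expect_equal(nrow(ev), nrow(truth))
    expect_equal(ev$event_class, truth$event_class)
    expect_equal(ev$direction, truth$direction)
    # weak wags cross the rest band well after their scheduled onset, so
    # only LAM onsets are frame-accurate
    lam <- truth$event_class == "LAM"
    if (any(lam)) expect_lt(max(abs(ev$onset[lam] - truth$onset[lam])), 3 / 300)
  }
})

test_that("generators are bit-reproducible given (params, seed)", {
  p <- trajectory_preset("mn", seed = 77)
  expect_identical(simulate_trajectory(p), simulate_trajectory(p))
  sp <- spike_train_preset("control", seed = 77)
  expect_identical(simulate_spike_train(sp), simulate_spike_train(sp))
  expect_identical(simulate_survival(survival_params(seed = 77)),
                   simulate_survival(survival_params(seed = 77)))
  expect_identical(simulate_behavior_counts(behavior_count_params(seed = 77)),
                   simulate_behavior_counts(behavior_count_params(seed = 77)))
})

test_that("LAM counts fluctuate around the control rate across seeds", {
  counts <- vapply(1:40, function(s) {
    sim <- simulate_trajectory(trajectory_preset("control", seed = s,
                                                 duration = 20))
    sum(sim$events$event_class == "LAM")
  }, numeric(1))
  # Poisson(13.2): the 40-seed mean should sit within a few s.e. of the rate
  expect_gt(mean(counts), 13.2 - 3 * sqrt(13.2 / 40))
  expect_lt(mean(counts), 13.2 + 3 * sqrt(13.2 / 40))
})

test_that("an overfull event request fails cleanly", {
  expect_error(
    simulate_trajectory(trajectory_params(duration = 1, lam_rate = 0,
                                          wag_cluster_rate = 30,
                                          wags_per_cluster = 10, seed = 3)),
    "cannot fit"
  )
})

test_that("spike-train ground truth matches a hand-computed periodic schedule", {
  p <- spike_train_params(recording_duration = 2, episode_rate = 30,
                          bursts_per_episode = 3, burst_period_mean = 40,
                          burst_period_sd = 0, burst_duration_mean = 9,
                          burst_duration_sd = 0, spikes_per_burst = 4,
                          seed = 2)
  sim <- simulate_spike_train(p, include_trace = FALSE)
  gt <- sim$ground_truth
  expect_true(all(gt$bursts$n_spikes == 4))
  expect_true(all(abs(gt$bursts$duration_ms - 9) < 1e-9))
  expect_true(all(gt$episodes$n_bursts == 3))
  starts <- split(gt$bursts$start, gt$bursts$episode)
  for (s in starts) expect_equal(diff(s) * 1000, rep(40, 2))
  # intra-burst ISI 9/3 = 3 ms
  isis <- diff(sim$spike_times) * 1000
  expect_true(all(isis[isis < 10] > 2.9 & isis[isis < 10] < 3.1))
})

test_that("empty spike trains come back as empty segmentations", {
  p <- spike_train_params(episode_rate = 0, recording_duration = 10, seed = 1)
  sim <- simulate_spike_train(p, include_trace = FALSE)
  expect_length(sim$spike_times, 0)
  expect_equal(nrow(sim$ground_truth$episodes), 0)
})

test_that("spike-train ground truth always obeys the ISI rules it is segmented by", {
  for (preset in c("control", "mn")) {
    for (seed in 1:5) {
      sim <- simulate_spike_train(
        spike_train_preset(preset, recording_duration = 30, seed = seed),
        include_trace = FALSE
      )
      seg <- segment_spikes(sim$spike_times)
      expect_equal(nrow(seg$bursts), nrow(sim$ground_truth$bursts))
      expect_equal(nrow(seg$episodes), nrow(sim$ground_truth$episodes))
      expect_equal(seg$bursts$n_spikes, sim$ground_truth$bursts$n_spikes)
      expect_equal(seg$bursts$start, sim$ground_truth$bursts$start)
    }
  }
})

test_that("expected survival is logistic with its midpoint at the LC50", {
  p <- survival_params(lc50 = 2, hill_slope = 4, seed = 1)
  expect_equal(expected_survival(2, 2, 4), 0.5)
  d <- sort(runif(50, 0, 10))
  expect_true(all(diff(expected_survival(d, 2, 4)) <= 0))  # monotone
  tab <- simulate_survival(p)
  expect_true(all(tab$surviving >= 0 & tab$surviving <= tab$n))
})

test_that("degenerate phenotype probabilities give degenerate counts", {
  p <- behavior_count_params(
    conditions = c("a", "b"),
    phenotype_probabilities = list(a = c(x = 1), b = c(x = 0)),
    seed = 9
  )
  tab <- simulate_behavior_counts(p)
  expect_true(all(tab$affected[tab$condition == "a"] == 20))
  expect_true(all(tab$affected[tab$condition == "b"] == 0))
})

test_that("Mn vs recovered floating proportions are detected at alpha 1e-4 almost always", {
  reject <- vapply(1:200, function(s) {
    tab <- simulate_behavior_counts(behavior_count_params(
      conditions = c("mn", "recovered"), seed = s
    ))
    float <- dplyr::filter(tab, phenotype == "sideways_floating")
    chi_square_counts(float)$p_value < 1e-4
  }, logical(1))
  expect_gte(mean(reject), 0.95)
})
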