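test_that("td_update reproduces the Rescorla-Wagner arithmetic", {
  cfg <- task_config()
  set.seed(1)
  plan <- generate_block_plan(cfg)
  st <- td_state_init(plan, prior = "trained")
  big <- if (plan$left_drops[1] == 3) "left" else "right"
  big_flavor <- plan[[paste0(big, "_flavor")]][1]
  small_flavor <- setdiff(c("chocolate", "vanilla"), big_flavor)

  # expected drop 2 omitted -> value PE(2) = -1
  r <- td_update(st, big, big_flavor, 1L, 0.2, 0.2)
  expect_equal(r$value_pe[2], -1)
  expect_equal(r$value_pe[1], 0)      # drop 1 fully expected
  expect_equal(r$identity_pe, 0)      # flavor fully expected

  # maximally surprising flavor -> identity PE = 1
  r2 <- td_update(st, big, small_flavor, 3L, 0.2, 0.2)
  expect_equal(r2$identity_pe, 1)

  # unexpected delivery learned at alpha: 0 -> 0.2 after one trial
  small <- setdiff(c("left", "right"), big)
  expect_equal(unname(st$drop_prob[small, 2]), 0)
  r3 <- td_update(st, small, small_flavor, 3L, 0.2, 0.2)
  expect_equal(r3$value_pe[2], 1)
  expect_equal(unname(r3$state$drop_prob[small, 2]), 0.2)

  # unrewarded trials produce zero errors and leave the state untouched
  r4 <- td_update(st, big, NA, 0L, 0.2, 0.2)
  expect_equal(r4$value_pe, rep(0, 3))
  expect_equal(r4$identity_pe, 0)
  expect_identical(r4$state, st)
  # all outputs bounded
  expect_true(all(abs(r2$value_pe) <= 1) && r2$identity_pe <= 1)
})

test_that("with alpha_identity = 0 the identity error persists unchanged", {
  cfg <- task_config()
  set.seed(2)
  plan <- generate_block_plan(cfg)
  st <- td_state_init(plan, prior = "trained")
  big <- if (plan$left_drops[1] == 3) "left" else "right"
  new_flavor <- setdiff(c("chocolate", "vanilla"),
                        plan[[paste0(big, "_flavor")]][1])
  pes <- numeric(50)
  for (i in 1:50) {
    r <- td_update(st, big, new_flavor, 3L, 0.3, 0)
    pes[i] <- r$identity_pe
    st <- r$state
  }
  expect_equal(pes, rep(1, 50))
})

test_that("firing-rate profile is flat at baseline when all gains are zero", {
  task <- simulate_task(seed = 4)
  p0 <- sim_params(reward_gain = 0, value_gain_pos = 0, value_gain_neg = 0,
                   identity_gain = 0)
  pe <- compute_pe_events(task$trials, task$blocks, p0$alpha_value,
                          p0$alpha_identity)
  tr1 <- pe[pe$trial_id == pe$trial_id[1], ]
  prof <- firing_rate_profile(tr1, p0, t_range = c(0, 50))
  expect_true(all(prof$rate == p0$baseline_rate))
  expect_equal(min(prof$start), 0)
  expect_equal(max(prof$end), 50)
})

test_that("control profile is elevated in the reward window after an identity shift", {
  task <- simulate_task(seed = 4)
  params <- sim_params("control")
  pe <- compute_pe_events(task$trials, task$blocks, params$alpha_value,
                          params$alpha_identity)
  b3 <- task$trials[task$trials$block_id == 3 & task$trials$rewarded, ]
  first <- b3[1, ]
  ev <- pe[pe$trial_id == first$trial_id, ]
  expect_gt(max(abs(ev$identity_pe)), 0.9)  # flavor swap is fully surprising
  prof <- firing_rate_profile(ev, params,
                              t_range = c(first$trial_light_on - 1,
                                          first$well_entry + 3))
  w <- profile_rate(prof, first$drop_1 + 0.3)
  expect_gt(w, params$baseline_rate)
  expect_equal(profile_rate(prof, first$trial_light_on - 0.2),
               params$baseline_rate)
})

test_that("omission dip floors the rate below baseline after a value downshift", {
  task <- simulate_task(seed = 4)
  params <- sim_params("control")
  pe <- compute_pe_events(task$trials, task$blocks, params$alpha_value,
                          params$alpha_identity)
  om <- pe[pe$kind == "omission" & pe$block_id == 2, ]
  expect_gt(nrow(om), 0)
  first_om <- om[1, ]
  ev <- pe[pe$trial_id == first_om$trial_id, ]
  prof <- firing_rate_profile(ev, params,
                              t_range = first_om$time + c(-2, 2))
  mid <- profile_rate(prof, first_om$time + 0.3)
  expect_lt(mid, params$baseline_rate)
  expect_gte(mid, 0)
})

test_that("sample_spikes is an exact inhomogeneous Poisson sampler", {
  set.seed(10)
  # empty at rate zero
  expect_length(sample_spikes(function(t) 0 * t, 10, rate_max = 1), 0L)
  # step rate: support respected, expected count correct
  step_fn <- function(t) ifelse(t >= 1, 20, 0)
  counts <- replicate(300, {
    s <- sample_spikes(step_fn, 2, rate_max = 20)
    expect_true(all(s >= 1))
    length(s)
  })
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 300))
  # constant rate via profile: Poisson CLT on the mean count
  prof <- structure(data.frame(start = 0, end = 100, rate = 10),
                    class = c("rate_profile", "data.frame"))
  n <- replicate(500, length(sample_spikes(prof)))
  expect_lt(abs(mean(n) - 1000), 3 * sqrt(1000) / sqrt(500))
  # dispersion: variance/mean near 1
  expect_gt(var(n) / mean(n), 0.8)
  expect_lt(var(n) / mean(n), 1.2)
  # unbounded / missing bound errors
  expect_error(sample_spikes(function(t) 1 + 0 * t, 10), "rate_max")
  expect_error(sample_spikes(function(t) 50 + 0 * t, 10, rate_max = 10),
               "exceeds")
})

test_that("generated waveforms round-trip through feature extraction", {
  cl <- default_waveform_clusters()
  set.seed(20)
  feats <- t(replicate(300, {
    w <- generate_waveform(cl$dopamine)
    c(compute_half_duration(w, attr(w, "sample_rate")),
      compute_amplitude_ratio(w))
  }))
  inside <- abs(feats[, 1] - cl$dopamine$half_duration_mean) <=
    3 * cl$dopamine$half_duration_sd &
    abs(feats[, 2] - cl$dopamine$amplitude_ratio_mean) <=
    3 * cl$dopamine$amplitude_ratio_sd
  expect_gte(mean(inside), 0.99)

  # zero-s.d. cluster lands on the nominal features
  cl0 <- list(half_duration_mean = 0.40, half_duration_sd = 0,
              amplitude_ratio_mean = 0.10, amplitude_ratio_sd = 0)
  w0 <- generate_waveform(cl0)
  expect_equal(compute_half_duration(w0, attr(w0, "sample_rate")), 0.40,
               tolerance = 0.01)
  expect_lt(abs(compute_amplitude_ratio(w0) - 0.10), 0.005)

  # 6+ s.d. separated presets give non-overlapping feature clouds
  set.seed(21)
  hd_d <- replicate(500, attr(generate_waveform(cl$dopamine), "half_duration"))
  hd_o <- replicate(500, attr(generate_waveform(cl$other), "half_duration"))
  expect_gt(min(hd_d), max(hd_o))
})

test_that("simulate_session composes units, spikes and waveforms reproducibly", {
  s <- cached_mixed_session(seed = 11)
  expect_s3_class(s, "vta_session")
  expect_identical(nrow(s$units), 10L)
  expect_true(all(s$spikes$unit_id %in% s$units$unit_id))
  expect_true(all(s$spikes$time >= 0))
  by_unit <- split(s$spikes$time, s$spikes$unit_id)
  expect_true(all(vapply(by_unit, function(x) all(diff(x) > 0), logical(1))))

  task <- simulate_task(seed = 11)
  s2 <- simulate_session(task, sim_params("control", n_units = 10,
                                          frac_dopamine = 0.4,
                                          frac_reward_modulated = 0.5),
                         seed = 12)
  expect_identical(s$spikes, s2$spikes)

  # empty unit set is allowed; empty trial list is not
  s0 <- simulate_session(task, sim_params(n_units = 0), seed = 1)
  expect_identical(nrow(s0$units), 0L)
  expect_error(simulate_session(list(trials = NULL), sim_params()), "empty")
})

test_that("preset contract: class and modulation fractions follow the config", {
  task <- simulate_task(seed = 30, config = task_config())
  p <- sim_params("control", n_units = 40)
  s <- simulate_session(task, p, seed = 31)
  expect_equal(sum(s$units$ground_truth_class == "dopamine"),
               round(p$frac_dopamine * 40))
  expect_equal(sum(s$units$reward_modulated),
               round(p$frac_reward_modulated * round(p$frac_dopamine * 40)))
  # lesion presets rewire the gains as documented
  hcx <- sim_params("HCx")
  expect_equal(hcx$value_gain_pos + hcx$value_gain_neg + hcx$identity_gain, 0)
  expect_equal(hcx$alpha_value, 1)
  ofcx <- sim_params("OFCx")
  expect_equal(ofcx$alpha_identity, 0)
  expect_equal(ofcx$value_gain_neg, 0)
  expect_equal(ofcx$value_gain_pos, 0.6 * sim_params("control")$value_gain_pos)
})
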