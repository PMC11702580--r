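# Shared fixtures and independent oracles, all built in code at test time.

# Exact two-sided signed-rank p by enumeration of all sign assignments.
# Requires no zeros and no tied absolute values.
exact_signed_rank_p <- function(x) {
  stopifnot(all(x != 0), !anyDuplicated(abs(x)))
  n <- length(x)
  r <- rank(abs(x))
  w_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(p, 1)
}

# Pearson chi-square by direct O/E enumeration
brute_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Feature clouds with a known ground truth (no waveform round trip)
make_feature_cohort <- function(n_dopa = 50L, n_other = 50L,
                                dopa = list(hd = 0.40, hd_sd = 0.030,
                                            ar = 0.05, ar_sd = 0.040),
                                other = list(hd = 0.15, hd_sd = 0.020,
                                             ar = 0.50, ar_sd = 0.080)) {
  n <- n_dopa + n_other
  data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    half_duration = c(rnorm(n_dopa, dopa$hd, dopa$hd_sd),
                      rnorm(n_other, other$hd, other$hd_sd)),
    amplitude_ratio = c(rnorm(n_dopa, dopa$ar, dopa$ar_sd),
                        rnorm(n_other, other$ar, other$ar_sd)),
    valid = TRUE,
    truth = rep(c("dopamine", "other"), c(n_dopa, n_other)),
    stringsAsFactors = FALSE
  )
}

# Independent leave-one-out distance recomputation (plain loops)
brute_loo_distances <- function(feats, assignment, metric = "axiswise") {
  x <- cbind(feats$half_duration, feats$amplitude_ratio)
  ks <- sort(unique(assignment))
  d <- matrix(NA_real_, nrow(x), length(ks))
  for (u in seq_len(nrow(x))) {
    for (ci in seq_along(ks)) {
      mem <- setdiff(which(assignment == ks[ci]), u)
      ctr <- c(mean(x[mem, 1]), mean(x[mem, 2]))
      sds <- c(sd(x[mem, 1]), sd(x[mem, 2]))
      z <- abs(x[u, ] - ctr) / sds
      d[u, ci] <- if (metric == "axiswise") max(z) else sqrt(sum(z^2))
    }
  }
  d
}

# Compact synthetic trial table for screen tests: evenly spaced trials,
# one drop per trial
make_screen_trials <- function(n_trials = 60L, spacing = 10) {
  light <- 5 + spacing * (seq_len(n_trials) - 1L)
  data.frame(
    trial_id = seq_len(n_trials), block_id = 1L, odor = "free",
    chosen_well = "left", correct = TRUE, reaction_time = 0.5,
    rewarded = TRUE, outcome_flavor = "chocolate", outcome_drops = 1L,
    trial_light_on = light, odor_on = light + 0.4, odor_off = light + 0.9,
    well_entry = light + 1.4, drop_1 = light + 1.9,
    drop_2 = NA_real_, drop_3 = NA_real_, stringsAsFactors = FALSE
  )
}

# Homogeneous Poisson spike train over [0, t_end]
poisson_train <- function(rate, t_end) sort(runif(rpois(1L, rate * t_end), 0, t_end))

# One small cached mixed-population session for reuse across test files:
# 10 units, 4 dopamine-class of which 2 reward-modulated
cached_mixed_session <- local({
  cache <- NULL
  function(seed = 11L) {
    if (is.null(cache)) {
      task <- simulate_task(seed = seed)
      cache <<- simulate_session(
        task, sim_params("control", n_units = 10L, frac_dopamine = 0.4,
                         frac_reward_modulated = 0.5), seed = seed + 1L)
    }
    cache
  }
})
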