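#' Simulation parameters for the spike-train generator
#'
#' Defines the drop-wise prediction-error rate model: every delivered drop
#' opens a box kernel (`kernel_latency` to `kernel_latency + kernel_duration`
#' after the drop) whose height is an unconditional reward response
#' (`reward_gain`) plus `value_gain_pos` times the positive part of that
#' slot's value prediction error plus `identity_gain` times the trial's
#' identity prediction error; every expected-but-omitted drop opens a dip
#' window in which the rate is reduced by `value_gain_neg` times the negative
#' error magnitude (floored at zero; the default 4 spikes/s against a
#' 5 spikes/s baseline brings a fully unexpected omission to 20% of baseline).
#'
#' Group presets:
#' \describe{
#'   \item{control}{full model; value and identity errors learned away within
#'     a block (`alpha_value`, `alpha_identity` at their defaults).}
#'   \item{HCx}{hippocampus lesion: prediction-error gains zeroed and learning
#'     rates set to 1 (priors update instantly), leaving only the
#'     unconditional reward response.}
#'   \item{OFCx}{orbitofrontal lesion: `alpha_identity = 0` so identity errors
#'     never attenuate, `value_gain_pos` attenuated to 60%, and no omission
#'     dip (`value_gain_neg = 0`).}
#' }
#'
#' @param group_preset `"control"`, `"HCx"` or `"OFCx"`.
#' @param baseline_rate Tonic rate, spikes/s.
#' @param reward_gain Unconditional per-drop response, spikes/s (all presets).
#' @param value_gain_pos,value_gain_neg,identity_gain Error gains, spikes/s
#'   per unit error.
#' @param alpha_value,alpha_identity Learning rates in \[0, 1\].
#' @param kernel_latency,kernel_duration Box-kernel onset and length, s.
#' @param omission_dip_window Offsets (s) of the dip window after an expected
#'   drop time.
#' @param n_units Units to simulate.
#' @param frac_dopamine Fraction of units in the wide-waveform (putative
#'   dopamine) class; default matches 80/408.
#' @param frac_reward_modulated Fraction of dopamine units carrying the reward
#'   response; default matches 46/80.
#' @param waveform_cluster_params Named list (`dopamine`, `other`) of
#'   per-cluster means/s.d. of half-duration (ms) and amplitude ratio.
#' @param waveform_sample_rate Waveform sampling rate, Hz.
#' @param prior Prediction prior at session start, see [td_state_init()].
#' @param gain_jitter_range Per-unit multiplicative jitter on response gains.
#' @param baseline_sdlog Lognormal spread of per-unit baseline rates.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(group_preset = c("control", "HCx", "OFCx"),
                       baseline_rate = 5,
                       reward_gain = 8,
                       value_gain_pos = 10,
                       value_gain_neg = 4,
                       identity_gain = 8,
                       alpha_value = 0.3,
                       alpha_identity = 0.3,
                       kernel_latency = 0.1,
                       kernel_duration = 0.4,
                       omission_dip_window = c(0.1, 0.5),
                       n_units = 46L,
                       frac_dopamine = 80 / 408,
                       frac_reward_modulated = 46 / 80,
                       waveform_cluster_params = default_waveform_clusters(),
                       waveform_sample_rate = 40000,
                       prior = "trained",
                       gain_jitter_range = c(0.7, 1.3),
                       baseline_sdlog = 0.2) {
  group_preset <- match.arg(group_preset)
  if (group_preset == "HCx") {
    value_gain_pos <- 0; value_gain_neg <- 0; identity_gain <- 0
    alpha_value <- 1; alpha_identity <- 1
  } else if (group_preset == "OFCx") {
    value_gain_pos <- 0.6 * value_gain_pos
    value_gain_neg <- 0
    alpha_identity <- 0
  }
  p <- list(group_preset = group_preset, baseline_rate = baseline_rate,
            reward_gain = reward_gain, value_gain_pos = value_gain_pos,
            value_gain_neg = value_gain_neg, identity_gain = identity_gain,
            alpha_value = alpha_value, alpha_identity = alpha_identity,
            kernel_latency = kernel_latency, kernel_duration = kernel_duration,
            omission_dip_window = as.numeric(omission_dip_window),
            n_units = as.integer(n_units), frac_dopamine = frac_dopamine,
            frac_reward_modulated = frac_reward_modulated,
            waveform_cluster_params = waveform_cluster_params,
            waveform_sample_rate = waveform_sample_rate, prior = prior,
            gain_jitter_range = as.numeric(gain_jitter_range),
            baseline_sdlog = baseline_sdlog)
  stopifnot(p$baseline_rate >= 0, p$reward_gain >= 0, p$value_gain_pos >= 0,
            p$value_gain_neg >= 0, p$identity_gain >= 0,
            p$alpha_value >= 0, p$alpha_value <= 1,
            p$alpha_identity >= 0, p$alpha_identity <= 1,
            p$kernel_duration > 0,
            diff(p$omission_dip_window) > 0,
            p$frac_dopamine >= 0, p$frac_dopamine <= 1,
            p$frac_reward_modulated >= 0, p$frac_reward_modulated <= 1)
  class(p) <- "sim_params"
  p
}

#' Default waveform feature clusters
#'
#' Putative dopamine neurons carry wide spikes (long half-duration) with a
#' near-symmetric positive/negative amplitude ratio; the remaining population
#' has narrow spikes with a strongly negative-dominated ratio. The defaults
#' separate the clusters by more than 6 s.d. on the half-duration axis.
#' @return Named list of cluster parameter lists.
#' @export
default_waveform_clusters <- function() {
  list(
    dopamine = list(half_duration_mean = 0.40, half_duration_sd = 0.030,
                    amplitude_ratio_mean = 0.05, amplitude_ratio_sd = 0.040),
    other = list(half_duration_mean = 0.15, half_duration_sd = 0.020,
                 amplitude_ratio_mean = 0.50, amplitude_ratio_sd = 0.080)
  )
}

#' Piecewise firing-rate profile for one trial
#'
#' Evaluates the rate model on one trial's prediction-error events and returns
#' the rate as contiguous half-open constant segments over `t_range`.
#'
#' @param trial_events Rows of [compute_pe_events()] for a single trial.
#' @param params A [sim_params()].
#' @param t_range Numeric `c(start, end)` in session seconds.
#' @param gain_scale Per-unit multiplicative gain (default 1).
#' @param baseline_rate Override of `params$baseline_rate` (per-unit value).
#' @return `data.frame` of class `rate_profile` with columns `start`, `end`,
#'   `rate`; segments tile `t_range` exactly.
#' @export
firing_rate_profile <- function(trial_events, params, t_range,
                                gain_scale = 1,
                                baseline_rate = params$baseline_rate) {
  stopifnot(inherits(params, "sim_params"), length(t_range) == 2L,
            t_range[2] > t_range[1])
  ints <- rate_deltas(trial_events, params, gain_scale)
  ints <- ints[ints$end > t_range[1] & ints$start < t_range[2], , drop = FALSE]
  brk <- sort(unique(c(t_range, pmax(pmin(c(ints$start, ints$end),
                                          t_range[2]), t_range[1]))))
  seg <- data.frame(start = brk[-length(brk)], end = brk[-1])
  seg$rate <- baseline_rate
  for (i in seq_len(nrow(ints))) {
    cov <- seg$start >= ints$start[i] & seg$end <= ints$end[i]
    seg$rate[cov] <- seg$rate[cov] + ints$delta[i]
  }
  neg <- seg$rate < 0
  if (any(neg)) seg$rate[neg] <- 0
  structure(seg, class = c("rate_profile", "data.frame"),
            baseline = baseline_rate)
}

# additive rate contributions (one interval per event window)
rate_deltas <- function(trial_events, params, gain_scale) {
  if (is.null(trial_events) || nrow(trial_events) == 0L) {
    return(data.frame(start = numeric(0), end = numeric(0), delta = numeric(0)))
  }
  drops <- trial_events[trial_events$kind == "drop", , drop = FALSE]
  oms <- trial_events[trial_events$kind == "omission", , drop = FALSE]
  out <- list()
  if (nrow(drops)) {
    h <- gain_scale * (params$reward_gain +
                         params$value_gain_pos * pmax(drops$value_pe, 0) +
                         params$identity_gain * drops$identity_pe)
    out$drops <- data.frame(start = drops$time + params$kernel_latency,
                            end = drops$time + params$kernel_latency +
                              params$kernel_duration,
                            delta = h)
  }
  if (nrow(oms)) {
    d <- gain_scale * params$value_gain_neg * pmax(-oms$value_pe, 0)
    out$oms <- data.frame(start = oms$time + params$omission_dip_window[1],
                          end = oms$time + params$omission_dip_window[2],
                          delta = -d)
  }
  do.call(rbind, out)
}

#' Evaluate a rate profile at time points
#' @param profile A `rate_profile`.
#' @param t Numeric vector of times.
#' @return Rates (spikes/s); 0 outside the profile's range.
#' @export
profile_rate <- function(profile, t) {
  idx <- findInterval(t, profile$start)
  r <- ifelse(idx >= 1L & t < profile$end[pmax(idx, 1L)],
              profile$rate[pmax(idx, 1L)], 0)
  as.numeric(r)
}

#' Sample an inhomogeneous Poisson spike train
#'
#' For a `rate_profile` (piecewise-constant rate) sampling is exact: the count
#' in each segment is Poisson with mean rate x length and spike times are
#' uniform within the segment. For an arbitrary rate function, thinning is
#' used against the supplied bound `rate_max`; the bound is validated on the
#' candidate points and an error is raised if the rate exceeds it.
#'
#' @param rate A `rate_profile` or a vectorized function of time.
#' @param duration Session seconds (function form only; profiles carry their
#'   own support).
#' @param rate_max Upper bound on the rate (required for the function form).
#' @return Sorted numeric vector of spike times.
#' @export
sample_spikes <- function(rate, duration = NULL, rate_max = NULL) {
  if (inherits(rate, "rate_profile")) {
    len <- rate$end - rate$start
    n <- stats::rpois(nrow(rate), rate$rate * len)
    times <- rep(rate$start, n) + stats::runif(sum(n)) * rep(len, n)
    return(sort(times))
  }
  stopifnot(is.function(rate))
  if (is.null(duration) || duration < 0) stop("duration required", call. = FALSE)
  if (is.null(rate_max) || !is.finite(rate_max))
    stop("rate_max must be a finite bound for the rate function", call. = FALSE)
  if (duration == 0 || rate_max == 0) return(numeric(0))
  n_cand <- stats::rpois(1L, rate_max * duration)
  if (n_cand == 0L) return(numeric(0))
  t_cand <- stats::runif(n_cand, 0, duration)
  r <- rate(t_cand)
  if (any(r > rate_max + 1e-9))
    stop("rate exceeds rate_max; bound invalid", call. = FALSE)
  sort(t_cand[stats::runif(n_cand) * rate_max < r])
}

#' Generate a mean extracellular waveform
#'
#' Draws target features from the cluster's bivariate normal and constructs a
#' biphasic trace (an initial positive lobe followed by a negative lobe, both
#' Gaussian) realizing them: both lobes have full width at half maximum equal
#' to the drawn half-duration, and the lobe amplitudes p (positive) and
#' n (negative) satisfy `(n - p)/(n + p) = amplitude ratio`.
#'
#' @param cluster One entry of [default_waveform_clusters()].
#' @param sample_rate Hz.
#' @param duration_ms Trace length (ms).
#' @return Numeric voltage trace with attributes `sample_rate`,
#'   `half_duration` and `amplitude_ratio` (the drawn targets).
#' @export
generate_waveform <- function(cluster, sample_rate = 40000, duration_ms = 3.2) {
  stopifnot(cluster$half_duration_sd >= 0, cluster$amplitude_ratio_sd >= 0)
  hd <- stats::rnorm(1L, cluster$half_duration_mean, cluster$half_duration_sd)
  hd <- max(hd, 0.05)
  ar <- stats::rnorm(1L, cluster$amplitude_ratio_mean, cluster$amplitude_ratio_sd)
  ar <- min(max(ar, -0.95), 0.95)
  t_ms <- seq(0, duration_ms, by = 1000 / sample_rate)
  sigma <- hd / (2 * sqrt(2 * log(2)))  # FWHM -> s.d.
  if (ar >= 0) { n_amp <- 120; p_amp <- 120 * (1 - ar) / (1 + ar) }
  else { p_amp <- 120; n_amp <- 120 * (1 + ar) / (1 - ar) }
  w <- p_amp * exp(-(t_ms - 0.25 * duration_ms)^2 / (2 * sigma^2)) -
    n_amp * exp(-(t_ms - 0.70 * duration_ms)^2 / (2 * sigma^2))
  structure(w, sample_rate = sample_rate, half_duration = hd,
            amplitude_ratio = ar)
}

#' Simulate a full recording session
#'
#' Binds a simulated task to the prediction-error rate model: computes the
#' session's drop-wise error events, draws a unit population (a configured
#' fraction dopamine-class, of which a configured fraction carries the reward
#' and error responses), samples every unit's spike train, and attaches mean
#' waveforms drawn from the class-appropriate cluster.
#'
#' @param task Output of [simulate_task()].
#' @param params A [sim_params()].
#' @param seed Integer seed for the neural stage.
#' @return Object of class `vta_session`: list with `meta`, `blocks`,
#'   `trials`, `units`, `spikes`, `waveforms`, and the error-event table
#'   `pe_events`.
#' @export
simulate_session <- function(task, params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(task$trials) || nrow(task$trials) == 0L)
    stop("task has an empty trial list", call. = FALSE)
  set.seed(as.integer(seed))
  trials <- task$trials
  pe <- compute_pe_events(trials, task$blocks,
                          params$alpha_value, params$alpha_identity,
                          task$config$inter_drop_interval,
                          prior = params$prior)
  n <- params$n_units
  n_dopa <- round(params$frac_dopamine * n)
  n_mod <- round(params$frac_reward_modulated * n_dopa)
  duration <- max(trials$well_entry) + 5

  units <- if (n > 0L) data.frame(
    unit_id = sprintf("u%03d", seq_len(n)),
    ground_truth_class = rep(c("dopamine", "other"), c(n_dopa, n - n_dopa)),
    reward_modulated = rep(c(TRUE, FALSE, FALSE),
                           c(n_mod, n_dopa - n_mod, n - n_dopa)),
    stringsAsFactors = FALSE
  ) else data.frame(unit_id = character(0), ground_truth_class = character(0),
                    reward_modulated = logical(0))
  units$baseline_rate <- stats::rlnorm(n, log(params$baseline_rate) -
                                         params$baseline_sdlog^2 / 2,
                                       params$baseline_sdlog)
  units$gain_scale <- stats::runif(n, params$gain_jitter_range[1],
                                   params$gain_jitter_range[2])

  drops <- pe[pe$kind == "drop", , drop = FALSE]
  oms <- pe[pe$kind == "omission", , drop = FALSE]
  spk <- vector("list", n)
  wfs <- vector("list", n)
  for (u in seq_len(n)) {
    b <- units$baseline_rate[u]
    s <- sort(stats::runif(stats::rpois(1L, b * duration), 0, duration))
    if (units$reward_modulated[u]) {
      g <- units$gain_scale[u]
      if (nrow(oms) && params$value_gain_neg > 0) {
        dip <- g * params$value_gain_neg * pmax(-oms$value_pe, 0)
        w0 <- oms$time + params$omission_dip_window[1]
        w1 <- oms$time + params$omission_dip_window[2]
        idx <- findInterval(s, w0)
        inwin <- idx >= 1L & s < w1[pmax(idx, 1L)]
        p_remove <- pmin(dip[pmax(idx, 1L)] / b, 1)
        drop_spike <- inwin & stats::runif(length(s)) < p_remove
        s <- s[!drop_spike]
      }
      if (nrow(drops)) {
        h <- g * (params$reward_gain +
                    params$value_gain_pos * pmax(drops$value_pe, 0) +
                    params$identity_gain * drops$identity_pe)
        extra_n <- stats::rpois(nrow(drops), h * params$kernel_duration)
        extra <- rep(drops$time + params$kernel_latency, extra_n) +
          stats::runif(sum(extra_n)) * params$kernel_duration
        s <- sort(c(s, extra))
      }
    }
    # spike times are strictly increasing: drop measure-zero collisions
    if (length(s) > 1L) s <- s[c(TRUE, diff(s) > 0)]
    spk[[u]] <- if (length(s)) data.frame(unit_id = units$unit_id[u], time = s,
                                          stringsAsFactors = FALSE) else NULL
    cl <- params$waveform_cluster_params[[
      if (units$ground_truth_class[u] == "dopamine") "dopamine" else "other"]]
    w <- generate_waveform(cl, params$waveform_sample_rate)
    wfs[[u]] <- data.frame(unit_id = units$unit_id[u],
                           sample_index = seq_along(w),
                           voltage = as.numeric(w), stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, spk[!vapply(spk, is.null, logical(1))])
  if (is.null(spikes)) spikes <- data.frame(unit_id = character(0),
                                            time = numeric(0))
  waveforms <- if (n > 0L) do.call(rbind, wfs) else
    data.frame(unit_id = character(0), sample_index = integer(0),
               voltage = numeric(0))
  rownames(spikes) <- rownames(waveforms) <- NULL

  structure(list(
    meta = list(schema_version = "1.0", task_seed = task$seed,
                neural_seed = as.integer(seed),
                preset = params$group_preset,
                sample_rate = params$waveform_sample_rate,
                config = unclass(task$config), params = unclass(params)),
    blocks = as.data.frame(task$blocks), trials = trials, units = units,
    spikes = spikes, waveforms = waveforms, pe_events = pe
  ), class = "vta_session")
}
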