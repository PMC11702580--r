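#' Analysis windows
#'
#' All windows are half-open offsets `[start, end)` in seconds relative to
#' their anchor event. Reward responses are measured 100-500 ms after drop
#' delivery; the baseline is the 400 ms before trial onset (the pre-trial
#' inter-trial interval); omission windows share the reward offsets but are
#' anchored at the expected time of the missing drop; the comparison window
#' is 0.5-1.0 s after the small reward, a period with no shift-locked change.
#'
#' @param reward,baseline,omission,comparison Numeric `c(start, end)` offsets.
#' @param alpha Screening significance level.
#' @return Object of class `analysis_windows`.
#' @export
analysis_windows <- function(reward = c(0.1, 0.5),
                             baseline = c(-0.4, 0),
                             omission = c(0.1, 0.5),
                             comparison = c(0.5, 1.0),
                             alpha = 0.05) {
  w <- list(reward = as.numeric(reward), baseline = as.numeric(baseline),
            omission = as.numeric(omission),
            comparison = as.numeric(comparison), alpha = alpha)
  for (nm in c("reward", "baseline", "omission", "comparison"))
    if (diff(w[[nm]]) <= 0) stop(nm, " window must have positive length",
                                 call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  class(w) <- "analysis_windows"
  w
}

# spikes strictly before x, for sorted spike vector
count_before <- function(spikes, x) findInterval(x, spikes, left.open = TRUE)

#' Firing rate in an event-anchored window
#'
#' Spike count in `[anchor + window[1], anchor + window[2])` divided by the
#' window length. Vectorized over anchors; `NA` anchors give `NA` rates.
#'
#' @param spike_times Sorted numeric spike times (s).
#' @param anchor Numeric vector of anchor times (s).
#' @param window Numeric `c(start, end)` offsets (s), `end > start`.
#' @return Rates in spikes/s, one per anchor.
#' @export
firing_in_window <- function(spike_times, anchor, window) {
  if (length(window) != 2L || diff(window) <= 0)
    stop("window must have positive length", call. = FALSE)
  len <- window[2] - window[1]
  ok <- !is.na(anchor)
  out <- rep(NA_real_, length(anchor))
  a <- anchor[ok]
  out[ok] <- (count_before(spike_times, a + window[2]) -
                count_before(spike_times, a + window[1])) / len
  out
}

#' Reward-responsiveness screen for one unit
#'
#' Pairs each rewarded trial's reward-window rate (anchored at the first
#' delivered drop) with the same trial's pre-trial baseline rate and tests
#' for an increase (one-sided paired t-test at `windows$alpha`). A
#' zero-variance difference vector is flagged: a constant positive difference
#' counts as responsive, anything else as non-responsive.
#'
#' @param spike_times Sorted spike times of the unit (s).
#' @param trials Trial table.
#' @param windows An [analysis_windows()].
#' @return List: `responsive`, `statistic`, `p`, `n_trials`, `degenerate`.
#' @export
is_reward_responsive <- function(spike_times, trials,
                                 windows = analysis_windows()) {
  rew <- trials[trials$rewarded & !is.na(trials$drop_1), , drop = FALSE]
  if (nrow(rew) < 2L)
    stop("need at least 2 rewarded trials for the screen", call. = FALSE)
  r_rate <- firing_in_window(spike_times, rew$drop_1, windows$reward)
  b_rate <- firing_in_window(spike_times, rew$trial_light_on, windows$baseline)
  d <- r_rate - b_rate
  if (stats::sd(d) == 0) {
    return(list(responsive = d[1] > 0, statistic = NA_real_, p = NA_real_,
                n_trials = nrow(rew), degenerate = TRUE))
  }
  tt <- stats::t.test(r_rate, b_rate, paired = TRUE, alternative = "greater")
  list(responsive = tt$p.value < windows$alpha,
       statistic = unname(tt$statistic), p = tt$p.value,
       n_trials = nrow(rew), degenerate = FALSE)
}

#' Screen every unit of a session
#'
#' @param session A `vta_session`.
#' @param unit_ids Units to screen (default all).
#' @param windows An [analysis_windows()].
#' @return `data.frame`: `unit_id`, `reward_responsive`, `t`, `p`.
#' @export
screen_responses <- function(session, unit_ids = session$units$unit_id,
                             windows = analysis_windows()) {
  out <- lapply(unit_ids, function(id) {
    s <- session$spikes$time[session$spikes$unit_id == id]
    r <- is_reward_responsive(sort(s), session$trials, windows)
    data.frame(unit_id = id, reward_responsive = r$responsive,
               t = r$statistic, p = r$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
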