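#' Task configuration for the odor-guided choice task
#'
#' Bundles the structural parameters of the five-block task: block lengths,
#' the pseudorandom odor mix (7 free-choice and 6 of each forced-choice odor
#' per 20 trials, never more than 3 identical odors in a row), the behavioral
#' switch criterion that gates block transitions, and the reward schedule
#' (3-drop big vs 1-drop small reward, 500 ms between drops).
#'
#' @param n_blocks Number of blocks. Block 1 establishes the initial mapping;
#'   even-numbered blocks swap drop counts between wells (value shifts) and
#'   odd-numbered blocks after the first swap flavors (identity shifts).
#' @param block1_len_range Integer range (min, max) of block-1 trial counts.
#' @param later_len_range Integer range for blocks 2 onward.
#' @param free_per_20 Free-choice odors per aligned 20-trial window.
#' @param forced_per_20 Forced-choice odors per side per 20-trial window.
#' @param max_consecutive_same_odor Longest permitted run of one odor.
#' @param switch_window,switch_min_large A block may end only once the animal
#'   chose the big-reward well on at least `switch_min_large` of the last
#'   `switch_window` free-choice trials.
#' @param big_drops,small_drops Drop counts of the big and small reward.
#' @param inter_drop_interval Seconds between successive drops.
#' @param response_deadline Seconds allowed to respond after odor offset.
#' @param drop_volume_ml Nominal bolus volume (metadata only).
#' @param max_trials_per_block Hard cap before `simulate_behavior()` aborts a
#'   block that never satisfies the switch criterion.
#' @return An object of class `task_config` (a validated list).
#' @export
task_config <- function(n_blocks = 5L,
                        block1_len_range = c(30L, 50L),
                        later_len_range = c(60L, 100L),
                        free_per_20 = 7L,
                        forced_per_20 = 6L,
                        max_consecutive_same_odor = 3L,
                        switch_window = 10L,
                        switch_min_large = 6L,
                        big_drops = 3L,
                        small_drops = 1L,
                        inter_drop_interval = 0.5,
                        response_deadline = 3.0,
                        drop_volume_ml = 0.05,
                        max_trials_per_block = 500L) {
  cfg <- list(
    n_blocks = as.integer(n_blocks),
    block1_len_range = as.integer(block1_len_range),
    later_len_range = as.integer(later_len_range),
    free_per_20 = as.integer(free_per_20),
    forced_per_20 = as.integer(forced_per_20),
    max_consecutive_same_odor = as.integer(max_consecutive_same_odor),
    switch_window = as.integer(switch_window),
    switch_min_large = as.integer(switch_min_large),
    big_drops = as.integer(big_drops),
    small_drops = as.integer(small_drops),
    inter_drop_interval = as.numeric(inter_drop_interval),
    response_deadline = as.numeric(response_deadline),
    drop_volume_ml = as.numeric(drop_volume_ml),
    max_trials_per_block = as.integer(max_trials_per_block)
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$free_per_20 + 2L * cfg$forced_per_20 > 20L)
    stop("odor mix must satisfy free_per_20 + 2*forced_per_20 <= 20",
         call. = FALSE)
  if (cfg$free_per_20 < 0L || cfg$forced_per_20 < 0L)
    stop("odor counts must be nonnegative", call. = FALSE)
  if (cfg$max_consecutive_same_odor < 1L)
    stop("max_consecutive_same_odor must be >= 1 (constraint infeasible)", call. = FALSE)
  if (cfg$switch_min_large > cfg$switch_window)
    stop("switch_min_large must not exceed switch_window", call. = FALSE)
  if (!(cfg$big_drops > cfg$small_drops && cfg$small_drops >= 1L))
    stop("drop counts must satisfy big_drops > small_drops >= 1", call. = FALSE)
  for (fld in c("block1_len_range", "later_len_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
      stop(fld, " must be a positive ordered pair", call. = FALSE)
  }
  if (cfg$inter_drop_interval <= 0 || cfg$response_deadline <= 0)
    stop("time parameters must be positive", call. = FALSE)
  if (cfg$n_blocks < 1L) stop("n_blocks must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Behavioral simulation parameters
#'
#' Governs the simulated animal's choices and reaction times. Choices on
#' free-choice trials follow a softmax on the current drop-count beliefs;
#' forced-choice accuracy and reaction times depend on whether the big or
#' small reward is at stake (faster and more accurate for the big reward).
#'
#' @param choice_sensitivity Softmax inverse temperature on the belief
#'   difference (per drop). `Inf` gives greedy choice.
#' @param rt_mean_big,rt_mean_small Mean reaction time (s) when the big /
#'   small reward is at stake; must satisfy `rt_mean_big < rt_mean_small`.
#' @param accuracy_big,accuracy_small Probability of responding at the
#'   instructed well on forced-choice trials, by at-stake reward.
#' @param learning_rate_behavior Per-trial Rescorla-Wagner rate in (0, 1]
#'   moving the chosen well's drop-count belief toward the delivered count.
#'   A rate of exactly 0 is allowed for degenerate no-learning simulations.
#' @param rt_shift,rt_sdlog Shifted-lognormal reaction-time parameters:
#'   `rt = rt_shift + Lognormal(log(mean - rt_shift) - rt_sdlog^2/2, rt_sdlog)`.
#' @param initial_value_belief Optional numeric `c(left, right)` initial
#'   drop-count beliefs. Default `NULL` starts at the block-1 truth
#'   (a well-trained animal).
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(choice_sensitivity = 3,
                            rt_mean_big = 0.40,
                            rt_mean_small = 0.70,
                            accuracy_big = 0.95,
                            accuracy_small = 0.85,
                            learning_rate_behavior = 0.25,
                            rt_shift = 0.15,
                            rt_sdlog = 0.25,
                            initial_value_belief = NULL) {
  p <- list(
    choice_sensitivity = choice_sensitivity,
    rt_mean_big = rt_mean_big,
    rt_mean_small = rt_mean_small,
    accuracy_big = accuracy_big,
    accuracy_small = accuracy_small,
    learning_rate_behavior = learning_rate_behavior,
    rt_shift = rt_shift,
    rt_sdlog = rt_sdlog,
    initial_value_belief = initial_value_belief
  )
  stopifnot(
    p$rt_mean_big < p$rt_mean_small,
    p$accuracy_big > p$accuracy_small,
    p$accuracy_big >= 0, p$accuracy_big <= 1,
    p$accuracy_small >= 0, p$accuracy_small <= 1,
    p$learning_rate_behavior >= 0, p$learning_rate_behavior <= 1,
    p$rt_shift >= 0, p$rt_shift < p$rt_mean_big,
    p$choice_sensitivity >= 0
  )
  class(p) <- "behavior_params"
  p
}
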