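ODOR_LEVELS <- c("free", "forced_left", "forced_right")
WELLS <- c("left", "right")
FLAVORS <- c("chocolate", "vanilla")

#' Generate a constrained pseudorandom odor sequence
#'
#' Every aligned, completed 20-trial window contains exactly `free_per_20`
#' free-choice odors and at least `forced_per_20` of each forced odor (any
#' remaining trials in the window are forced odors with a random side, since
#' 7 + 6 + 6 fills only 19 of 20 trials), and no odor appears more than
#' `max_consecutive_same_odor` times in a row (checked across window
#' boundaries). A trailing partial window is a truncated constrained window,
#' so the run-length constraint still holds everywhere.
#'
#' Uses the current R random number generator state; call [set.seed()] (or use
#' [simulate_task()]) for reproducibility.
#'
#' @param config A [task_config()].
#' @param length Number of trials (>= 1).
#' @return Character vector of odors in `c("free", "forced_left", "forced_right")`.
#' @export
generate_odor_sequence <- function(config, length) {
  validate_task_config(config)
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  base <- rep(ODOR_LEVELS, c(config$free_per_20,
                             config$forced_per_20, config$forced_per_20))
  n_fill <- 20L - length(base)
  maxrun <- config$max_consecutive_same_odor
  n_windows <- ceiling(length / 20L)
  out <- character(0)
  for (w in seq_len(n_windows)) {
    tail_prev <- if (length(out)) out[max(1L, length(out) - maxrun + 1L):length(out)] else character(0)
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      cand <- sample(c(base, sample(c("forced_left", "forced_right"),
                                    n_fill, replace = TRUE)))
      # rle over the carried tail + candidate window catches runs that
      # straddle the window boundary
      runs <- rle(c(tail_prev, cand))
      if (max(runs$lengths) <= maxrun) { ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy odor run-length constraint after 1000 attempts; ",
                  "constraint combination is infeasible", call. = FALSE)
    out <- c(out, cand)
  }
  out[seq_len(length)]
}

#' Generate a block plan
#'
#' Draws block lengths and lays out the well-to-reward mapping across blocks:
#' block 1 assigns the big (3-drop) reward to a random well and distinct milk
#' flavors to the two wells; blocks 2 and 4 swap the drop counts between wells
#' without changing flavors (value shifts); blocks 3 and 5 swap the flavors
#' without changing drop counts (identity shifts).
#'
#' @param config A [task_config()].
#' @return A `data.frame` of class `block_plan` with one row per block:
#'   `block_id`, `shift_type`, `length`, `left_flavor`, `left_drops`,
#'   `right_flavor`, `right_drops`.
#' @export
generate_block_plan <- function(config) {
  validate_task_config(config)
  big_well <- sample(WELLS, 1L)
  left_flavor <- sample(FLAVORS, 1L)
  right_flavor <- setdiff(FLAVORS, left_flavor)
  left_drops <- if (big_well == "left") config$big_drops else config$small_drops
  right_drops <- if (big_well == "right") config$big_drops else config$small_drops
  n <- config$n_blocks
  lens <- c(
    sample(seq(config$block1_len_range[1], config$block1_len_range[2]), 1L),
    if (n > 1L)
      sample(seq(config$later_len_range[1], config$later_len_range[2]),
             n - 1L, replace = TRUE)
  )
  shift <- c("initial",
             rep_len(c("value_shift", "identity_shift"), max(0L, n - 1L)))
  plan <- data.frame(
    block_id = seq_len(n), shift_type = shift[seq_len(n)], length = lens,
    left_flavor = character(n), left_drops = integer(n),
    right_flavor = character(n), right_drops = integer(n),
    stringsAsFactors = FALSE
  )
  for (b in seq_len(n)) {
    if (b > 1L) {
      if (plan$shift_type[b] == "value_shift") {
        tmp <- left_drops; left_drops <- right_drops; right_drops <- tmp
      } else {
        tmp <- left_flavor; left_flavor <- right_flavor; right_flavor <- tmp
      }
    }
    plan$left_flavor[b] <- left_flavor
    plan$left_drops[b] <- left_drops
    plan$right_flavor[b] <- right_flavor
    plan$right_drops[b] <- right_drops
  }
  class(plan) <- c("block_plan", "data.frame")
  plan
}

#' Block-switch criterion on recent free choices
#'
#' A block may end only once the animal has chosen the big-reward well on at
#' least `switch_min_large` (default 6) of the last `switch_window` (default
#' 10) free-choice trials. With fewer than `switch_window` free choices the
#' criterion is undefined and treated as unmet.
#'
#' @param recent_free_choices Character vector of free-choice outcomes in
#'   trial order, each `"large"` or `"small"`.
#' @param config A [task_config()].
#' @return Logical scalar.
#' @export
check_switch_criterion <- function(recent_free_choices, config = task_config()) {
  stopifnot(all(recent_free_choices %in% c("large", "small")))
  n <- length(recent_free_choices)
  if (n < config$switch_window) return(FALSE)
  last <- recent_free_choices[(n - config$switch_window + 1L):n]
  sum(last == "large") >= config$switch_min_large
}

rt_draw <- function(n, mean, shift, sdlog) {
  # shifted lognormal with E[rt] = mean
  shift + stats::rlnorm(n, meanlog = log(mean - shift) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate behavior through a block plan
#'
#' Walks trial by trial through the plan. Free choices follow a softmax on the
#' current per-well drop-count beliefs (updated by a Rescorla-Wagner rule
#' after each rewarded trial); forced-choice trials go to the instructed well
#' with probability `accuracy_big`/`accuracy_small` by the value at stake, and
#' errors end the trial unrewarded. Each block runs until it reaches its drawn
#' length and the switch criterion is satisfied on the last 10 free choices.
#'
#' Event times are seconds from session start; all analysis windows downstream
#' use the half-open convention `[start, end)`.
#'
#' @param plan A [generate_block_plan()] result.
#' @param odors Odor sequence at least as long as the realized session; extend
#'   with [generate_odor_sequence()] if unsure (blocks are capped at
#'   `config$max_trials_per_block` trials).
#' @param params A [behavior_params()].
#' @param config A [task_config()].
#' @return A `data.frame` (one row per trial): identifiers, odor, choice,
#'   outcome and named event-time columns (`trial_light_on`, `odor_on`,
#'   `odor_off`, `well_entry`, `drop_1..3`; `NA` where an event did not occur).
#' @export
simulate_behavior <- function(plan, odors, params, config = task_config()) {
  stopifnot(inherits(plan, "block_plan"), inherits(params, "behavior_params"))
  validate_task_config(config)
  beta <- params$choice_sensitivity
  lr <- params$learning_rate_behavior
  V <- if (is.null(params$initial_value_belief)) {
    c(left = plan$left_drops[1], right = plan$right_drops[1])
  } else {
    v <- as.numeric(params$initial_value_belief)
    stopifnot(length(v) == 2L)
    c(left = v[1], right = v[2])
  }

  rows <- vector("list", 2048L)
  nrow_used <- 0L
  t_cursor <- 5.0  # lead-in so the first baseline window exists
  trial_id <- 0L
  odor_idx <- 0L

  for (b in seq_len(nrow(plan))) {
    drops <- c(left = plan$left_drops[b], right = plan$right_drops[b])
    flavors <- c(left = plan$left_flavor[b], right = plan$right_flavor[b])
    big_well <- names(drops)[which.max(drops)]
    free_hist <- character(0)
    in_block <- 0L
    repeat {
      if (in_block >= config$max_trials_per_block)
        stop("block ", b, ": switch criterion not met within ",
             config$max_trials_per_block, " trials", call. = FALSE)
      done_len <- in_block >= plan$length[b]
      done_crit <- check_switch_criterion(free_hist, config)
      if (done_len && done_crit) break

      trial_id <- trial_id + 1L
      in_block <- in_block + 1L
      odor_idx <- odor_idx + 1L
      if (odor_idx > length(odors))
        stop("odor sequence exhausted; supply a longer sequence", call. = FALSE)
      odor <- odors[odor_idx]

      if (odor == "free") {
        p_left <- if (is.infinite(beta)) {
          if (V["left"] > V["right"]) 1 else if (V["left"] < V["right"]) 0 else 0.5
        } else {
          1 / (1 + exp(-beta * (V[["left"]] - V[["right"]])))
        }
        chosen <- if (stats::runif(1) < p_left) "left" else "right"
        correct <- chosen == big_well
        rewarded <- TRUE
        free_hist <- c(free_hist, if (chosen == big_well) "large" else "small")
      } else {
        instructed <- if (odor == "forced_left") "left" else "right"
        acc <- if (drops[[instructed]] == config$big_drops)
          params$accuracy_big else params$accuracy_small
        went_right_way <- stats::runif(1) < acc
        chosen <- if (went_right_way) instructed else setdiff(WELLS, instructed)
        correct <- went_right_way
        rewarded <- went_right_way
      }

      at_stake <- if (drops[[chosen]] == config$big_drops)
        params$rt_mean_big else params$rt_mean_small
      rt <- min(rt_draw(1L, at_stake, params$rt_shift, params$rt_sdlog),
                config$response_deadline - 1e-3)

      light_on <- t_cursor
      odor_on <- light_on + stats::runif(1, 0.2, 0.6)
      odor_off <- odor_on + 0.5
      well_entry <- odor_off + rt
      n_drops <- if (rewarded) drops[[chosen]] else 0L
      drop_times <- if (n_drops > 0L)
        well_entry + 0.5 + config$inter_drop_interval * (seq_len(n_drops) - 1L)
      else numeric(0)

      if (rewarded && lr > 0) {
        V[chosen] <- V[[chosen]] + lr * (n_drops - V[[chosen]])
      }

      nrow_used <- nrow_used + 1L
      if (nrow_used > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nrow_used]] <- data.frame(
        trial_id = trial_id, block_id = b, odor = odor,
        chosen_well = chosen, correct = correct,
        reaction_time = rt, rewarded = rewarded,
        outcome_flavor = if (rewarded) flavors[[chosen]] else NA_character_,
        outcome_drops = as.integer(n_drops),
        trial_light_on = light_on, odor_on = odor_on, odor_off = odor_off,
        well_entry = well_entry,
        drop_1 = if (n_drops >= 1L) drop_times[1] else NA_real_,
        drop_2 = if (n_drops >= 2L) drop_times[2] else NA_real_,
        drop_3 = if (n_drops >= 3L) drop_times[3] else NA_real_,
        stringsAsFactors = FALSE
      )
      # inter-trial interval leaves a clean pre-trial baseline window
      t_cursor <- well_entry + 0.5 +
        config$inter_drop_interval * config$big_drops + stats::runif(1, 2.5, 3.5)
    }
  }
  do.call(rbind, rows[seq_len(nrow_used)])
}

#' Simulate a complete task session
#'
#' Seeds the RNG, draws a block plan and odor sequence, and simulates behavior
#' through all blocks. Identical `(config, params, seed)` give byte-identical
#' trial tables.
#'
#' @param config A [task_config()].
#' @param params A [behavior_params()].
#' @param seed Integer seed.
#' @return A list with elements `blocks` (the plan), `trials` (trial table),
#'   `config`, `behavior`, `seed`.
#' @export
simulate_task <- function(config = task_config(), params = behavior_params(),
                          seed = 1L) {
  set.seed(as.integer(seed))
  plan <- generate_block_plan(config)
  odors <- generate_odor_sequence(
    config, config$max_trials_per_block * config$n_blocks)
  trials <- simulate_behavior(plan, odors, params, config)
  list(blocks = plan, trials = trials, config = config, behavior = params,
       seed = as.integer(seed))
}
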