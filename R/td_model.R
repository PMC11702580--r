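#' Initialize reward predictions
#'
#' Per-well expectations carried by the simulated animal: a probability of
#' receiving a drop in each of the three drop slots, and a belief distribution
#' over flavors. `prior = "trained"` starts at the block-1 truth (the animals
#' are extensively trained before recording); `prior = "uniform"` starts
#' flavor beliefs at 0.5 and drop expectations at the small-reward pattern.
#'
#' @param plan A [generate_block_plan()] result (block 1 defines the truth).
#' @param prior `"trained"` or `"uniform"`.
#' @param n_slots Number of drop slots tracked (default 3).
#' @return An object of class `td_state`: list with `drop_prob` (wells x
#'   slots matrix) and `flavor_belief` (wells x flavors matrix, rows sum 1).
#' @export
td_state_init <- function(plan, prior = c("trained", "uniform"), n_slots = 3L) {
  prior <- match.arg(prior)
  drop_prob <- matrix(0, 2L, n_slots, dimnames = list(WELLS, NULL))
  flavor_belief <- matrix(0.5, 2L, 2L, dimnames = list(WELLS, FLAVORS))
  if (prior == "trained") {
    for (w in WELLS) {
      nd <- plan[[paste0(w, "_drops")]][1]
      drop_prob[w, seq_len(min(nd, n_slots))] <- 1
      flavor_belief[w, ] <- 0
      flavor_belief[w, plan[[paste0(w, "_flavor")]][1]] <- 1
    }
  } else {
    drop_prob[, 1] <- 1  # a drop-1 is always delivered when rewarded
  }
  structure(list(drop_prob = drop_prob, flavor_belief = flavor_belief),
            class = "td_state")
}

#' Drop-wise Rescorla-Wagner update
#'
#' Computes per-drop-slot signed value prediction errors and a nonnegative
#' identity prediction error for one trial's outcome, then moves the visited
#' well's expectations toward the observation. The value error in slot k is
#' `delivered_k - expected_drop_prob_k`; the identity error is
#' `1 - flavor_belief(delivered flavor)`, evaluated at drop 1. Unrewarded
#' trials (forced-choice errors) produce zero errors and no update: the
#' animal never samples the well outcome.
#'
#' @param state A `td_state`.
#' @param well `"left"` or `"right"`.
#' @param flavor Delivered flavor, or `NA` if unrewarded.
#' @param n_drops Number of drops delivered (0 for unrewarded).
#' @param alpha_value,alpha_identity Learning rates in \[0, 1\].
#' @return List: `value_pe` (numeric per slot, in \[-1, 1\]), `identity_pe`
#'   (scalar in \[0, 1\]), `state` (updated).
#' @export
td_update <- function(state, well, flavor, n_drops, alpha_value, alpha_identity) {
  stopifnot(inherits(state, "td_state"), well %in% WELLS,
            alpha_value >= 0, alpha_value <= 1,
            alpha_identity >= 0, alpha_identity <= 1)
  n_slots <- ncol(state$drop_prob)
  if (is.na(n_drops) || n_drops < 1L) {
    return(list(value_pe = rep(0, n_slots), identity_pe = 0, state = state))
  }
  stopifnot(flavor %in% FLAVORS)
  delivered <- as.numeric(seq_len(n_slots) <= n_drops)
  value_pe <- delivered - state$drop_prob[well, ]
  identity_pe <- 1 - state$flavor_belief[well, flavor]
  state$drop_prob[well, ] <- state$drop_prob[well, ] + alpha_value * value_pe
  target <- as.numeric(FLAVORS == flavor)
  state$flavor_belief[well, ] <- state$flavor_belief[well, ] +
    alpha_identity * (target - state$flavor_belief[well, ])
  list(value_pe = unname(value_pe), identity_pe = unname(identity_pe),
       state = state)
}

#' Prediction-error event table for a session
#'
#' Iterates [td_update()] over the trial table in order and emits one row per
#' reward drop (carrying that slot's value error and the trial's identity
#' error) and one row per omitted-but-expected drop (an omission event at the
#' time the drop would have occurred, carrying the negative value error).
#' A slot counts as "expected" when its pre-update expectation exceeds
#' `omission_min_expectation`.
#'
#' @param trials Trial table from [simulate_behavior()].
#' @param plan Block plan (for the initial state).
#' @param alpha_value,alpha_identity Learning rates.
#' @param inter_drop_interval Seconds between drop slots.
#' @param prior Passed to [td_state_init()].
#' @param omission_min_expectation Expectation threshold for an omission event.
#' @return `data.frame`: `trial_id`, `block_id`, `well`, `kind`
#'   (`"drop"`/`"omission"`), `drop_index`, `time`, `value_pe`, `identity_pe`.
#' @export
compute_pe_events <- function(trials, plan, alpha_value, alpha_identity,
                              inter_drop_interval = 0.5,
                              prior = "trained",
                              omission_min_expectation = 0.25) {
  state <- td_state_init(plan, prior)
  n_slots <- ncol(state$drop_prob)
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (!isTRUE(tr$rewarded) || tr$outcome_drops < 1L) next
    pre_expect <- state$drop_prob[tr$chosen_well, ]
    upd <- td_update(state, tr$chosen_well, tr$outcome_flavor,
                     tr$outcome_drops, alpha_value, alpha_identity)
    state <- upd$state
    nd <- tr$outcome_drops
    drop_t <- tr$drop_1 + inter_drop_interval * (seq_len(n_slots) - 1L)
    delivered <- seq_len(n_slots) <= nd
    omitted <- !delivered & pre_expect > omission_min_expectation
    kinds <- c(rep("drop", sum(delivered)), rep("omission", sum(omitted)))
    idx <- c(which(delivered), which(omitted))
    if (!length(idx)) next
    out[[i]] <- data.frame(
      trial_id = tr$trial_id, block_id = tr$block_id, well = tr$chosen_well,
      kind = kinds, drop_index = idx, time = drop_t[idx],
      value_pe = upd$value_pe[idx],
      identity_pe = ifelse(kinds == "drop", upd$identity_pe, 0),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(trial_id = integer(0), block_id = integer(0),
                      well = character(0), kind = character(0),
                      drop_index = integer(0), time = numeric(0),
                      value_pe = numeric(0), identity_pe = numeric(0))
  }
  rownames(res) <- NULL
  res
}
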