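#' Difference-score analysis configuration
#' @param n_early,n_late Trials per side of the early/late contrast.
#' @param normalize_identity Divide identity-analysis rates by the unit's mean
#'   baseline rate (the value analysis uses raw spikes/s).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(n_early = 5L, n_late = 5L,
                            normalize_identity = TRUE) {
  stopifnot(n_early >= 1L, n_late >= 1L)
  structure(list(n_early = as.integer(n_early), n_late = as.integer(n_late),
                 normalize_identity = normalize_identity),
            class = "analysis_config")
}

#' Peri-event time histogram
#'
#' Mean firing rate in contiguous half-open bins around a set of anchor
#' events, optionally divided by a baseline rate.
#'
#' @param spike_times Sorted spike times (s).
#' @param anchors Event times (s); trials with `NA` anchors are dropped.
#' @param window `c(start, end)` offsets around the anchor (s).
#' @param bin_width Bin width (s).
#' @param baseline Optional baseline rate for normalization (spikes/s).
#' @return List of class `psth`: `edges`, `rate` (per bin, spikes/s or
#'   baseline units), `n_trials`, `normalized`.
#' @export
build_psth <- function(spike_times, anchors, window = c(-0.5, 1.5),
                       bin_width = 0.1, baseline = NULL) {
  anchors <- anchors[!is.na(anchors)]
  if (!length(anchors)) stop("no trials with the alignment event", call. = FALSE)
  edges <- seq(window[1], window[2], by = bin_width)
  if (edges[length(edges)] < window[2]) edges <- c(edges, window[2])
  counts <- numeric(length(edges) - 1L)
  for (a in anchors) {
    counts <- counts + (count_before(spike_times, a + edges[-1]) -
                          count_before(spike_times, a + edges[-length(edges)]))
  }
  rate <- counts / (diff(edges) * length(anchors))
  if (!is.null(baseline)) {
    if (baseline <= 0) stop("baseline must be positive for normalization",
                            call. = FALSE)
    rate <- rate / baseline
  }
  structure(list(edges = edges, rate = rate, n_trials = length(anchors),
                 normalized = !is.null(baseline)), class = "psth")
}

#' Mean pre-trial baseline rate of a unit
#' @param spike_times Sorted spike times.
#' @param trials Trial table.
#' @param windows An [analysis_windows()].
#' @return Mean baseline-window rate (spikes/s).
#' @export
unit_baseline_rate <- function(spike_times, trials,
                               windows = analysis_windows()) {
  mean(firing_in_window(spike_times, trials$trial_light_on, windows$baseline))
}

# rewarded trials at one well in one block, in session order
well_trials <- function(trials, block_id, well) {
  trials[trials$block_id == block_id & trials$chosen_well == well &
           trials$rewarded & !is.na(trials$drop_1), , drop = FALSE]
}

early_late <- function(tr, n_early, n_late, what) {
  if (nrow(tr) < n_early + n_late)
    stop("fewer than n_early + n_late qualifying trials for ", what,
         call. = FALSE)
  list(early = tr[seq_len(n_early), , drop = FALSE],
       late = tr[seq(nrow(tr) - n_late + 1L, nrow(tr)), , drop = FALSE])
}

#' Value-shift difference scores for one unit
#'
#' Around each value-shift block: the delivery score contrasts the rate in the
#' reward window after the 2nd drop between the first `n_early` and last
#' `n_late` rewarded trials at the well whose reward grew (small to big); the
#' omission score does the same at the well whose reward shrank, in a window
#' anchored at the expected (no longer delivered) 2nd-drop time. Scores are
#' averaged across the session's value-shift blocks.
#'
#' @param spike_times Sorted spike times of the unit.
#' @param session A `vta_session`.
#' @param config An [analysis_config()].
#' @param windows An [analysis_windows()].
#' @return `data.frame`: `contrast` (`"delivery"`, `"omission"`), `score`
#'   (spikes/s), `n_early`, `n_late`.
#' @export
value_shift_scores <- function(spike_times, session,
                               config = analysis_config(),
                               windows = analysis_windows()) {
  blocks <- session$blocks
  trials <- session$trials
  idi <- session$meta$config$inter_drop_interval
  vb <- blocks$block_id[blocks$shift_type == "value_shift"]
  if (!length(vb)) stop("session has no value-shift blocks", call. = FALSE)
  del <- om <- numeric(0)
  for (b in vb) {
    prev <- blocks[blocks$block_id == b - 1L, ]
    cur <- blocks[blocks$block_id == b, ]
    up_well <- WELLS[c(cur$left_drops > prev$left_drops,
                       cur$right_drops > prev$right_drops)]
    down_well <- setdiff(WELLS, up_well)
    eu <- early_late(well_trials(trials, b, up_well),
                     config$n_early, config$n_late,
                     paste0("delivery, block ", b))
    del_rates <- function(tr) mean(firing_in_window(spike_times, tr$drop_2,
                                                    windows$reward))
    del <- c(del, del_rates(eu$early) - del_rates(eu$late))
    ed <- early_late(well_trials(trials, b, down_well),
                     config$n_early, config$n_late,
                     paste0("omission, block ", b))
    om_rates <- function(tr) mean(firing_in_window(spike_times,
                                                   tr$drop_1 + idi,
                                                   windows$omission))
    om <- c(om, om_rates(ed$early) - om_rates(ed$late))
  }
  data.frame(contrast = c("delivery", "omission"),
             score = c(mean(del), mean(om)),
             n_early = config$n_early, n_late = config$n_late,
             stringsAsFactors = FALSE)
}

#' Identity-shift difference scores for one unit
#'
#' Around each identity-shift block: contrasts the (optionally
#' baseline-normalized) reward-window rate between the first `n_early`
#' rewarded trials of the new block and the last `n_late` rewarded trials of
#' the previous block, separately for the 1st and 2nd drops of the big reward
#' and the single drop of the small reward. A no-shift comparison contrast
#' uses the 0.5-1.0 s window after the small reward. Scores are averaged
#' across the session's identity-shift blocks.
#'
#' @inheritParams value_shift_scores
#' @return `data.frame` with contrasts `identity_drop1_big`,
#'   `identity_drop2_big`, `identity_small`, `comparison_no_shift`.
#' @export
identity_shift_scores <- function(spike_times, session,
                                  config = analysis_config(),
                                  windows = analysis_windows()) {
  blocks <- session$blocks
  trials <- session$trials
  ib <- blocks$block_id[blocks$shift_type == "identity_shift"]
  if (!length(ib)) stop("session has no identity-shift blocks", call. = FALSE)
  norm <- 1
  if (config$normalize_identity) {
    b0 <- unit_baseline_rate(spike_times, trials, windows)
    norm <- if (is.finite(b0) && b0 > 0) b0 else 1
  }
  acc <- list(identity_drop1_big = numeric(0), identity_drop2_big = numeric(0),
              identity_small = numeric(0), comparison_no_shift = numeric(0))
  for (b in ib) {
    cur <- blocks[blocks$block_id == b, ]
    big_well <- WELLS[c(cur$left_drops > cur$right_drops,
                        cur$right_drops > cur$left_drops)]
    small_well <- setdiff(WELLS, big_well)
    sides <- function(well, what) {
      early <- well_trials(trials, b, well)
      late <- well_trials(trials, b - 1L, well)
      if (nrow(early) < config$n_early || nrow(late) < config$n_late)
        stop("fewer than n_early/n_late qualifying trials for ", what,
             call. = FALSE)
      list(early = early[seq_len(config$n_early), , drop = FALSE],
           late = late[seq(nrow(late) - config$n_late + 1L, nrow(late)), ,
                       drop = FALSE])
    }
    contrast <- function(sd, anchor_col, window) {
      m <- function(tr) mean(firing_in_window(spike_times, tr[[anchor_col]],
                                              window)) / norm
      m(sd$early) - m(sd$late)
    }
    sb <- sides(big_well, paste0("identity big well, block ", b))
    ss <- sides(small_well, paste0("identity small well, block ", b))
    acc$identity_drop1_big <- c(acc$identity_drop1_big,
                                contrast(sb, "drop_1", windows$reward))
    acc$identity_drop2_big <- c(acc$identity_drop2_big,
                                contrast(sb, "drop_2", windows$reward))
    acc$identity_small <- c(acc$identity_small,
                            contrast(ss, "drop_1", windows$reward))
    acc$comparison_no_shift <- c(acc$comparison_no_shift,
                                 contrast(ss, "drop_1", windows$comparison))
  }
  data.frame(contrast = names(acc),
             score = vapply(acc, mean, numeric(1)),
             n_early = config$n_early, n_late = config$n_late,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a set of per-unit difference scores
#'
#' Mean score and two-sided Wilcoxon signed-rank p against a zero median.
#' Zero differences are dropped before ranking (classical convention, ties
#' mid-ranked); if fewer than two nonzero scores remain, p = 1 and the
#' summary is flagged low-n.
#'
#' @param scores Numeric vector of per-unit scores.
#' @param contrast Label carried into the output.
#' @return `data.frame`: `contrast`, `u` (mean score), `p`, `n_units`,
#'   `low_n`.
#' @export
summarize_scores <- function(scores, contrast = "score") {
  if (!length(scores)) stop("empty score list", call. = FALSE)
  nz <- scores[scores != 0]
  p <- if (length(nz) < 2L) 1 else
    suppressWarnings(stats::wilcox.test(nz, mu = 0,
                                        alternative = "two.sided")$p.value)
  data.frame(contrast = contrast, u = mean(scores), p = p,
             n_units = length(scores), low_n = length(nz) < 2L,
             stringsAsFactors = FALSE)
}

#' Fixed-effects factorial ANOVA on windowed firing rates
#'
#' Fits `response ~ block + f1 * f2 * ...` by least squares (the blocking
#' factor, typically unit identity, is absorbed before the stated factors)
#' and returns the ANOVA table rows for the stated factors and their
#' interactions.
#'
#' @param data `data.frame` of observations.
#' @param response Name of the numeric response column.
#' @param factors Character vector of factor column names (crossed).
#' @param block Optional name of a blocking factor column.
#' @return `data.frame`: `effect`, `df`, `F`, `p` plus residual df as an
#'   attribute `df_resid`.
#' @export
run_factorial_anova <- function(data, response = "rate", factors,
                                block = NULL) {
  stopifnot(length(factors) >= 1L, all(c(response, factors, block) %in%
                                         names(data)))
  for (f in c(factors, block)) data[[f]] <- factor(data[[f]])
  tab <- table(data[factors])
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(ix)
      paste(mapply(function(f, i) paste0(f, "=", dimnames(tab)[[f]][i]),
                   factors, ix), collapse = ", "))
    stop("empty design cell(s): ", paste(lab, collapse = "; "), call. = FALSE)
  }
  rhs <- paste(factors, collapse = " * ")
  if (!is.null(block)) rhs <- paste(block, "+", rhs)
  fit <- stats::lm(stats::as.formula(paste(response, "~", rhs)), data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design", call. = FALSE)
  an <- suppressWarnings(stats::anova(fit))
  # a term with zero between-cell variance carries no effect: F = 0, p = 1
  zero_ss <- an$`Sum Sq` <=
    1e-12 * max(sum(data[[response]]^2), .Machine$double.xmin)
  an$`F value`[zero_ss] <- 0
  an$`Pr(>F)`[zero_ss] <- 1
  keep <- !(rownames(an) %in% c("Residuals", block))
  out <- data.frame(effect = rownames(an)[keep], df = an$Df[keep],
                    F = an$`F value`[keep], p = an$`Pr(>F)`[keep],
                    stringsAsFactors = FALSE)
  attr(out, "df_resid") <- an$Df[rownames(an) == "Residuals"]
  out
}

#' Chi-square test on classification proportions
#'
#' Pearson chi-square (no continuity correction) on the groups x
#' \{dopamine, other\} contingency table built from per-group counts of
#' putative dopamine neurons out of all recorded units.
#'
#' @param counts `data.frame` with columns `group`, `n_dopamine`, `n_total`.
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square_proportions <- function(counts) {
  stopifnot(all(c("group", "n_dopamine", "n_total") %in% names(counts)))
  if (any(counts$n_total <= 0)) stop("zero-total group", call. = FALSE)
  if (any(counts$n_dopamine < 0 | counts$n_dopamine > counts$n_total))
    stop("counts must satisfy 0 <= n_dopamine <= n_total", call. = FALSE)
  tab <- cbind(dopamine = counts$n_dopamine,
               other = counts$n_total - counts$n_dopamine)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Per-unit difference scores for a set of units
#' @param session A `vta_session`.
#' @param unit_ids Units to analyse (typically the reward-responsive ones).
#' @param config An [analysis_config()].
#' @param windows An [analysis_windows()].
#' @return Long `data.frame`: `unit_id`, `contrast`, `score`.
#' @export
difference_scores <- function(session, unit_ids,
                              config = analysis_config(),
                              windows = analysis_windows()) {
  out <- lapply(unit_ids, function(id) {
    s <- sort(session$spikes$time[session$spikes$unit_id == id])
    v <- value_shift_scores(s, session, config, windows)
    i <- identity_shift_scores(s, session, config, windows)
    cbind(unit_id = id, rbind(v, i))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Population firing time course across the first identity shift
#'
#' Baseline-normalized reward-window firing (anchored at the first drop of
#' whatever reward was delivered) for every rewarded trial of the first
#' identity-shift block, averaged across units, indexed by rewarded-trial
#' position in the block. Used to compare post-shift firing levels across
#' groups: a persistent identity error keeps this trajectory at its
#' early-shift level instead of decaying.
#'
#' @param session A `vta_session`.
#' @param unit_ids Units to average.
#' @param windows An [analysis_windows()].
#' @return `data.frame`: `trial_index`, `norm_rate`.
#' @export
identity_shift_timecourse <- function(session, unit_ids,
                                      windows = analysis_windows()) {
  blocks <- session$blocks
  b <- blocks$block_id[blocks$shift_type == "identity_shift"][1]
  if (is.na(b)) stop("session has no identity-shift blocks", call. = FALSE)
  tr <- session$trials
  tr <- tr[tr$block_id == b & tr$rewarded & !is.na(tr$drop_1), , drop = FALSE]
  mats <- vapply(unit_ids, function(id) {
    s <- sort(session$spikes$time[session$spikes$unit_id == id])
    b0 <- unit_baseline_rate(s, session$trials, windows)
    if (!is.finite(b0) || b0 <= 0) b0 <- 1
    firing_in_window(s, tr$drop_1, windows$reward) / b0
  }, numeric(nrow(tr)))
  data.frame(trial_index = seq_len(nrow(tr)),
             norm_rate = rowMeans(mats))
}
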