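#' Simulate one phenotype-study session
#'
#' A session of reward-modulated putative dopamine units under a group
#' preset, matching the study's analysed control cohort size (46
#' reward-responsive units) by default. Task and neural stages draw their
#' seeds deterministically from `seed`.
#'
#' @param preset `"control"`, `"HCx"` or `"OFCx"`.
#' @param seed Integer seed.
#' @param n_units Units per session (all dopamine-class, all modulated).
#' @param config A [task_config()].
#' @param behavior A [behavior_params()].
#' @param ... Passed to [sim_params()].
#' @return A `vta_session`.
#' @export
simulate_phenotype_session <- function(preset, seed, n_units = 46L,
                                       config = task_config(),
                                       behavior = behavior_params(), ...) {
  task <- simulate_task(config, behavior, seed = seed)
  params <- sim_params(group_preset = preset, n_units = n_units,
                       frac_dopamine = 1, frac_reward_modulated = 1, ...)
  simulate_session(task, params, seed = seed + 1L)
}

#' Early/post/late levels of an identity-shift time course
#'
#' `early` is the mean over the first `n_early` rewarded trials after the
#' shift, `post` the mean over trials `n_early + 1` to 35 (the persistence
#' window), `late` the mean over the block's last `n_early` rewarded trials.
#'
#' @param tc Output of [identity_shift_timecourse()].
#' @param n_early Early-trial count.
#' @return Named numeric: `early`, `post`, `late`, `n_post`.
#' @export
timecourse_levels <- function(tc, n_early = 5L) {
  n <- nrow(tc)
  post_idx <- seq(n_early + 1L, min(35L, n - n_early))
  c(early = mean(tc$norm_rate[seq_len(n_early)]),
    post = mean(tc$norm_rate[post_idx]),
    late = mean(tc$norm_rate[seq(n - n_early + 1L, n)]),
    n_post = length(post_idx))
}

#' Full analysis of one phenotype session
#'
#' Screens the units for reward responsiveness, computes value- and
#' identity-shift difference scores for the responsive units, summarizes each
#' contrast (mean score and signed-rank p), and extracts the post-shift
#' firing time course.
#'
#' @param session A `vta_session`.
#' @param config An [analysis_config()].
#' @param windows An [analysis_windows()].
#' @return List: `summaries` (one row per contrast), `scores`,
#'   `n_responsive`, `timecourse`, `levels`.
#' @export
analyze_phenotype <- function(session, config = analysis_config(),
                              windows = analysis_windows()) {
  screen <- screen_responses(session, windows = windows)
  resp <- screen$unit_id[screen$reward_responsive]
  if (length(resp) < 2L)
    stop("fewer than 2 reward-responsive units", call. = FALSE)
  sc <- difference_scores(session, resp, config, windows)
  summaries <- do.call(rbind, lapply(split(sc, sc$contrast), function(d)
    summarize_scores(d$score, d$contrast[1])))
  rownames(summaries) <- NULL
  tc <- identity_shift_timecourse(session, resp, windows)
  list(summaries = summaries, scores = sc, n_responsive = length(resp),
       screen = screen, timecourse = tc,
       levels = timecourse_levels(tc, config$n_early))
}

pat_get <- function(summ, contrast) summ[summ$contrast == contrast, ]

#' Expected phenotype pattern per group
#'
#' Evaluates, at `alpha` per contrast, the study's qualitative signature:
#' controls show transient value and identity errors (delivery scores above
#' zero, omission below, all three identity contrasts above); HCx shows no
#' significant shift on any contrast, with post-identity-shift firing at the
#' control late-block level; OFCx shows an attenuated delivery effect only,
#' with post-shift firing persisting at the control early level.
#'
#' @param ctrl,hcx,ofcx Outputs of [analyze_phenotype()] for the three
#'   presets of one cohort seed.
#' @param alpha Per-contrast significance level.
#' @return Named logical vector (per-group and overall flags).
#' @export
phenotype_pattern <- function(ctrl, hcx, ofcx, alpha = 0.05) {
  sig_pos <- function(s, ct) { r <- pat_get(s, ct); r$p < alpha & r$u > 0 }
  sig_neg <- function(s, ct) { r <- pat_get(s, ct); r$p < alpha & r$u < 0 }
  ns <- function(s, ct) pat_get(s, ct)$p >= alpha
  idc <- c("identity_drop1_big", "identity_drop2_big", "identity_small")

  control_ok <- sig_pos(ctrl$summaries, "delivery") &&
    sig_neg(ctrl$summaries, "omission") &&
    all(vapply(idc, function(ct) sig_pos(ctrl$summaries, ct), logical(1)))

  ce <- ctrl$levels[["early"]]; cl <- ctrl$levels[["late"]]
  hc_level <- hcx$levels[["post"]]
  of_level <- ofcx$levels[["post"]]
  hcx_ok <- all(vapply(c("delivery", "omission", idc),
                       function(ct) ns(hcx$summaries, ct), logical(1))) &&
    abs(hc_level - cl) <= abs(hc_level - ce)
  ofcx_ok <- sig_pos(ofcx$summaries, "delivery") &&
    ns(ofcx$summaries, "omission") &&
    all(vapply(idc, function(ct) ns(ofcx$summaries, ct), logical(1))) &&
    abs(of_level - ce) <= abs(of_level - cl)

  c(control = control_ok, HCx = hcx_ok, OFCx = ofcx_ok,
    all = control_ok && hcx_ok && ofcx_ok)
}

#' Run the seeded multi-cohort phenotype study
#'
#' For each of `n_seeds` cohort seeds, simulates and analyses one session per
#' group preset and evaluates the expected phenotype pattern.
#'
#' @param n_seeds Number of cohort seeds.
#' @param base_seed Base seed; cohort k uses `base_seed + 1000 * k`.
#' @param n_units Reward-modulated units per session.
#' @param config,behavior,analysis,windows Stage configurations.
#' @return List: `patterns` (`data.frame`, one row per seed),
#'   `pass_counts` (per-preset seeds matching), `analyses` (per-seed list).
#' @export
run_phenotype_study <- function(n_seeds = 20L, base_seed = 1L,
                                n_units = 46L,
                                config = task_config(),
                                behavior = behavior_params(),
                                analysis = analysis_config(),
                                windows = analysis_windows()) {
  rows <- vector("list", n_seeds)
  analyses <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    seed_k <- as.integer(base_seed + 1000L * k)
    res <- lapply(c(control = "control", HCx = "HCx", OFCx = "OFCx"),
                  function(p) {
                    s <- simulate_phenotype_session(p, seed_k, n_units,
                                                    config, behavior)
                    analyze_phenotype(s, analysis, windows)
                  })
    pat <- phenotype_pattern(res$control, res$HCx, res$OFCx, windows$alpha)
    rows[[k]] <- data.frame(seed = seed_k, t(as.matrix(pat)))
    analyses[[k]] <- res
  }
  patterns <- do.call(rbind, rows)
  list(patterns = patterns,
       pass_counts = colSums(patterns[, c("control", "HCx", "OFCx", "all")]),
       analyses = analyses)
}
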