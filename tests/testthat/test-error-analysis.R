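test_that("PSTH bin rates, pooling identity and self-normalization", {
  # one trial, one spike 0.05 s after the anchor, 0.1 s bins
  p <- build_psth(c(10.05), anchors = 10, window = c(0, 0.5), bin_width = 0.1)
  expect_equal(p$rate, c(10, 0, 0, 0, 0))
  expect_error(build_psth(1:5, anchors = NA_real_), "no trials")

  set.seed(300)
  spikes <- poisson_train(8, 500)
  a1 <- runif(10, 50, 200)
  a2 <- runif(30, 250, 450)
  p1 <- build_psth(spikes, a1)
  p2 <- build_psth(spikes, a2)
  pooled <- build_psth(spikes, c(a1, a2))
  expect_equal(pooled$rate, (10 * p1$rate + 30 * p2$rate) / 40,
               tolerance = 1e-12)

  # normalization by the unit's own rate gives ~1 everywhere
  pn <- build_psth(spikes, a2, baseline = 8)
  expect_lt(abs(mean(pn$rate) - 1), 0.2)
})

test_that("difference scores recover the preset phenotypes at desk scale", {
  s <- simulate_phenotype_session("control", seed = 901, n_units = 20)
  sc <- difference_scores(s, s$units$unit_id)
  agg <- tapply(sc$score, sc$contrast, mean)
  expect_gt(agg[["delivery"]], 0)
  expect_lt(agg[["omission"]], 0)
  expect_gt(agg[["identity_drop1_big"]], 0)
  expect_gt(agg[["identity_drop2_big"]], 0)
  expect_gt(agg[["identity_small"]], 0)
  expect_lt(abs(agg[["comparison_no_shift"]]), 0.25)
})

test_that("a unit with no spikes has zero scores everywhere", {
  s <- cached_mixed_session(seed = 11)
  v <- value_shift_scores(numeric(0), s)
  i <- identity_shift_scores(numeric(0), s)
  expect_equal(v$score, c(0, 0))
  expect_equal(i$score, rep(0, 4))
})

test_that("difference scores are antisymmetric under early/late exchange", {
  s <- cached_mixed_session(seed = 11)
  id <- s$units$unit_id[s$units$reward_modulated][1]
  spk <- sort(s$spikes$time[s$spikes$unit_id == id])
  v1 <- value_shift_scores(spk, s)
  # reversing trial order within each block swaps the first-n and last-n sets
  s_rev <- s
  s_rev$trials <- do.call(rbind, lapply(split(s$trials, s$trials$block_id),
                                        function(d) d[rev(seq_len(nrow(d))), ]))
  v2 <- value_shift_scores(spk, s_rev)
  expect_equal(v2$score, -v1$score, tolerance = 1e-12)
})

test_that("baseline normalization preserves the sign of identity scores", {
  s <- cached_mixed_session(seed = 11)
  ids <- s$units$unit_id[s$units$reward_modulated]
  for (id in ids) {
    spk <- sort(s$spikes$time[s$spikes$unit_id == id])
    raw <- identity_shift_scores(spk, s, analysis_config(normalize_identity = FALSE))
    nrm <- identity_shift_scores(spk, s, analysis_config(normalize_identity = TRUE))
    expect_equal(sign(raw$score), sign(nrm$score))
  }
})

test_that("signed-rank summaries match exact enumeration for small n", {
  set.seed(301)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n, 0.3), 6)
    while (any(x == 0) || anyDuplicated(abs(x))) x <- round(rnorm(n, 0.3), 6)
    s <- summarize_scores(x, "test")
    expect_equal(s$p, exact_signed_rank_p(x), tolerance = 1e-12)
    expect_equal(s$u, mean(x))
  }
})

test_that("signed-rank edge cases follow the documented conventions", {
  sym <- summarize_scores(c(-3, -1.5, 1.5, 3, -0.5, 0.5), "sym")
  expect_equal(sym$u, 0)
  expect_gt(sym$p, 0.9)
  allpos <- summarize_scores(rep(1, 20), "allpos")
  expect_lt(allpos$p, 0.001)
  single <- summarize_scores(0.7, "one")
  expect_equal(single$p, 1)
  expect_true(single$low_n)
  expect_error(summarize_scores(numeric(0)), "empty")
})

test_that("single-factor ANOVA F equals the squared pooled t", {
  set.seed(302)
  for (rep in 1:10) {
    d <- data.frame(rate = rnorm(40), grp = rep(c("a", "b"), each = 20))
    a <- run_factorial_anova(d, "rate", "grp")
    tt <- t.test(rate ~ grp, data = d, var.equal = TRUE)
    expect_lt(abs(a$F - unname(tt$statistic)^2), 1e-9)
  }
})

test_that("factorial ANOVA handles degenerate and malformed designs", {
  d <- expand.grid(grp = c("a", "b"), phase = c("early", "late"),
                   rep = 1:5)
  d$rate <- 1
  a <- run_factorial_anova(d, "rate", c("grp", "phase"))
  expect_equal(a$F, rep(0, 3))
  d2 <- d[!(d$grp == "a" & d$phase == "late"), ]
  expect_error(run_factorial_anova(d2, "rate", c("grp", "phase")),
               "empty design cell")
})

test_that("the control cohort shows a Reward x Early/Late interaction", {
  s <- simulate_phenotype_session("control", seed = 902, n_units = 20)
  cfg <- analysis_config()
  win <- analysis_windows()
  idi <- s$meta$config$inter_drop_interval
  obs <- list()
  for (id in s$units$unit_id) {
    spk <- sort(s$spikes$time[s$spikes$unit_id == id])
    for (b in s$blocks$block_id[s$blocks$shift_type == "value_shift"]) {
      prev <- s$blocks[s$blocks$block_id == b - 1, ]
      cur <- s$blocks[s$blocks$block_id == b, ]
      up <- if (cur$left_drops > prev$left_drops) "left" else "right"
      for (rw in c("delivery", "omission")) {
        well <- if (rw == "delivery") up else setdiff(c("left", "right"), up)
        tr <- s$trials[s$trials$block_id == b &
                         s$trials$chosen_well == well &
                         s$trials$rewarded, ]
        for (ph in c("early", "late")) {
          sel <- if (ph == "early") head(tr, cfg$n_early) else tail(tr, cfg$n_late)
          anchor <- if (rw == "delivery") sel$drop_2 else sel$drop_1 + idi
          r <- firing_in_window(spk, anchor, win$reward)
          obs[[length(obs) + 1]] <- data.frame(
            unit_id = id, reward = rw, phase = ph,
            trial = seq_along(r), rate = r)
        }
      }
    }
  }
  tab <- do.call(rbind, obs)
  res <- run_factorial_anova(tab, "rate", c("reward", "phase", "trial"),
                             block = "unit_id")
  inter <- res[res$effect == "reward:phase", ]
  expect_lt(inter$p, 0.05)
})

test_that("chi-square on classification proportions matches the worked example", {
  counts <- data.frame(group = c("control", "HCx", "OFCx"),
                       n_dopamine = c(80, 110, 90),
                       n_total = c(408, 513, 412))
  r <- chi_square_proportions(counts)
  expect_equal(r$statistic, 0.71, tolerance = 0.01)
  expect_identical(r$df, 2L)
  expect_gt(r$p, 0.05)
  # brute-force oracle on a 2x2 table
  c2 <- data.frame(group = c("a", "b"), n_dopamine = c(10, 30),
                   n_total = c(100, 100))
  r2 <- chi_square_proportions(c2)
  expect_equal(r2$statistic,
               brute_chi2(cbind(c(10, 30), c(90, 70))), tolerance = 1e-12)
  # identical proportions give exactly zero
  c3 <- data.frame(group = c("a", "b"), n_dopamine = c(20, 40),
                   n_total = c(100, 200))
  expect_equal(chi_square_proportions(c3)$statistic, 0)
  expect_error(chi_square_proportions(
    data.frame(group = "a", n_dopamine = 1, n_total = 0)), "zero-total")
})

test_that("identity time course decays in controls and persists in OFCx", {
  sc <- simulate_phenotype_session("control", seed = 903, n_units = 15)
  so <- simulate_phenotype_session("OFCx", seed = 903, n_units = 15)
  resp_c <- screen_responses(sc)
  resp_o <- screen_responses(so)
  tc_c <- identity_shift_timecourse(sc, resp_c$unit_id[resp_c$reward_responsive])
  tc_o <- identity_shift_timecourse(so, resp_o$unit_id[resp_o$reward_responsive])
  lv_c <- timecourse_levels(tc_c)
  lv_o <- timecourse_levels(tc_o)
  expect_gt(lv_c[["early"]], lv_c[["late"]])   # control: transient
  expect_gt(lv_o[["post"]], lv_c[["late"]])    # OFCx: persists above control-late
  expect_gte(lv_o[["n_post"]], 30)
})
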