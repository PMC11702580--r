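test_that("odor sequences have the exact free-choice mix in every aligned window", {
  cfg <- task_config()
  set.seed(42)
  for (rep in 1:50) {
    o <- generate_odor_sequence(cfg, 200)
    for (w in seq_len(10)) {
      win <- o[(20 * (w - 1) + 1):(20 * w)]
      expect_identical(sum(win == "free"), 7L)
      expect_gte(sum(win == "forced_left"), 6L)
      expect_gte(sum(win == "forced_right"), 6L)
    }
  }
})

test_that("odor runs never exceed the maximum, including across window boundaries", {
  cfg <- task_config()
  set.seed(7)
  worst <- 0L
  for (rep in 1:200) {
    o <- generate_odor_sequence(cfg, 60)
    worst <- max(worst, max(rle(o)$lengths))
  }
  expect_lte(worst, cfg$max_consecutive_same_odor)
})

test_that("degenerate lengths and infeasible constraints are handled", {
  cfg <- task_config()
  set.seed(1)
  expect_length(generate_odor_sequence(cfg, 1), 1L)
  expect_error(generate_odor_sequence(cfg, 0), "length")
  expect_error(task_config(max_consecutive_same_odor = 0), "infeasible")
  expect_error(task_config(free_per_20 = 10, forced_per_20 = 6), "odor mix")
  expect_error(task_config(big_drops = 1, small_drops = 1), "drop counts")
  expect_error(task_config(switch_min_large = 11), "switch")
})

test_that("block plans follow the value/identity shift schedule", {
  cfg <- task_config()
  set.seed(3)
  for (rep in 1:25) {
    plan <- generate_block_plan(cfg)
    expect_identical(plan$shift_type,
                     c("initial", "value_shift", "identity_shift",
                       "value_shift", "identity_shift"))
    for (b in seq_len(nrow(plan))) {
      expect_true(xor(plan$left_drops[b] == cfg$big_drops,
                      plan$right_drops[b] == cfg$big_drops))
      expect_false(plan$left_flavor[b] == plan$right_flavor[b])
      if (b > 1) {
        if (plan$shift_type[b] == "value_shift") {
          expect_identical(plan$left_flavor[b], plan$left_flavor[b - 1])
          expect_identical(plan$left_drops[b], plan$right_drops[b - 1])
        } else {
          expect_identical(plan$left_drops[b], plan$left_drops[b - 1])
          expect_identical(plan$left_flavor[b], plan$right_flavor[b - 1])
        }
      }
    }
    expect_true(plan$length[1] >= 30 && plan$length[1] <= 50)
    expect_true(all(plan$length[-1] >= 60 & plan$length[-1] <= 100))
  }
})

test_that("initial big-well side is unbiased across plans", {
  cfg <- task_config()
  set.seed(9)
  left_big <- replicate(1000, {
    p <- generate_block_plan(cfg)
    p$left_drops[1] == cfg$big_drops
  })
  expect_gt(binom.test(sum(left_big), 1000, 0.5)$p.value, 0.01)
})

test_that("switch criterion requires 6 of the last 10 free choices to the large reward", {
  cfg <- task_config()
  expect_true(check_switch_criterion(rep(c("large", "small"), c(6, 4)), cfg))
  expect_false(check_switch_criterion(rep(c("large", "small"), c(5, 5)), cfg))
  expect_false(check_switch_criterion(rep("large", 9), cfg))
  # order within the window does not matter; earlier history does not count
  expect_true(check_switch_criterion(
    c(rep("small", 30), rep(c("small", "large", "large"), c(2, 4, 4))), cfg))
  expect_error(check_switch_criterion(c("big", "small")), "large")
})

test_that("greedy choice limit and no-learning limit behave as expected", {
  cfg <- task_config(n_blocks = 1L, block1_len_range = c(60L, 60L))
  set.seed(5)
  plan <- generate_block_plan(cfg)
  odors <- generate_odor_sequence(cfg, 600)
  big <- if (plan$left_drops[1] == cfg$big_drops) "left" else "right"
  greedy <- behavior_params(choice_sensitivity = Inf,
                            learning_rate_behavior = 0,
                            initial_value_belief =
                              if (big == "left") c(3, 1) else c(1, 3))
  tr <- simulate_behavior(plan, odors, greedy, cfg)
  expect_true(all(tr$chosen_well[tr$odor == "free"] == big))

  flat <- behavior_params(learning_rate_behavior = 0,
                          initial_value_belief = c(2, 2))
  picks <- unlist(lapply(1:15, function(i) {
    set.seed(100 + i)
    plan_i <- generate_block_plan(cfg)
    tr_i <- simulate_behavior(plan_i, generate_odor_sequence(cfg, 600),
                              flat, cfg)
    tr_i$chosen_well[tr_i$odor == "free"] == "left"
  }))
  expect_gt(length(picks), 300)
  expect_lt(abs(mean(picks) - 0.5), 0.08)
})

test_that("behavior learns to prefer the big well by the end of each block", {
  late_rates <- sapply(1:25, function(k) {
    task <- simulate_task(seed = 500 + k)
    tr <- task$trials
    sapply(1:5, function(b) {
      fb <- tr[tr$block_id == b & tr$odor == "free", ]
      mean(tail(fb$correct, 10))
    })
  })
  expect_gt(mean(late_rates), 0.6)
})

test_that("blocks end only once length and switch criterion are both met", {
  task <- simulate_task(seed = 77)
  tr <- task$trials
  cfg <- task$config
  for (b in 1:5) {
    tb <- tr[tr$block_id == b, ]
    expect_gte(nrow(tb), task$blocks$length[b])
    free <- tb[tb$odor == "free", ]
    choices <- ifelse(free$correct, "large", "small")
    expect_true(check_switch_criterion(choices, cfg))
  }
  expect_gte(nrow(tr), sum(task$blocks$length))
})

test_that("trial event times are strictly increasing with fixed drop spacing", {
  task <- simulate_task(seed = 21)
  tr <- task$trials
  ev <- as.matrix(tr[, c("trial_light_on", "odor_on", "odor_off",
                         "well_entry", "drop_1", "drop_2", "drop_3")])
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, !is.na(ev[i, ])]
    expect_true(all(diff(e) > 0))
  }
  d2 <- tr$drop_2 - tr$drop_1
  expect_equal(d2[!is.na(d2)],
               rep(task$config$inter_drop_interval, sum(!is.na(d2))))
  # forced errors deliver nothing
  err <- tr[!tr$correct & tr$odor != "free", ]
  expect_true(all(err$outcome_drops == 0))
  expect_true(all(is.na(err$drop_1)))
  # delivered drop counts match the block plan for the chosen well
  for (i in which(tr$rewarded)) {
    col <- paste0(tr$chosen_well[i], "_drops")
    expect_identical(tr$outcome_drops[i],
                     task$blocks[[col]][tr$block_id[i]])
  }
})

test_that("identical config and seed give byte-identical trial tables", {
  t1 <- simulate_task(seed = 13)
  t2 <- simulate_task(seed = 13)
  expect_identical(t1$trials, t2$trials)
  expect_identical(t1$blocks, t2$blocks)
  t3 <- simulate_task(seed = 14)
  expect_false(identical(t1$trials, t3$trials))
})
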