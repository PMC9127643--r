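test_that("the outlier rule removes latencies strictly above 30 seconds", {
  set.seed(20)
  s <- make_figid_session(rep(2000, 60))
  expect_equal(remove_outlier_trials(s)$n_removed, 0L)
  expect_equal(nrow(remove_outlier_trials(s)$trials), 60L)

  s$latency_ms[10] <- 31000
  out <- remove_outlier_trials(s)
  expect_equal(out$n_removed, 1L)
  expect_false(10L %in% out$trials$trial_index)

  s$latency_ms[10] <- 30000            # boundary: exactly 30 s is retained
  expect_equal(remove_outlier_trials(s)$n_removed, 0L)
})

test_that("posterior time limit boundary is inclusive at 90.000 s per set", {
  all3 <- make_figid_session(rep(3000, 60))       # 30 x 3.0 s = 90.0 s exactly
  expect_equal(score_figid_session(all3)$score, 60L)

  all31 <- make_figid_session(rep(3100, 60))      # 29 x 3.1 = 89.9; 30th over
  expect_equal(score_figid_session(all31)$score, 58L)
})

test_that("outlier trials contribute neither clock time nor credit", {
  lat <- rep(3000, 60)
  lat[5] <- 31000                                  # correct but removed
  correct <- c(rep(TRUE, 30), rep(FALSE, 30))      # set 2 earns nothing
  sc <- score_figid_session(make_figid_session(lat, correct))
  # set 1: 29 retained items, cumulative 87.0 s, all correct
  expect_equal(sc$score, 29L)
  expect_equal(sc$n_outliers_removed, 1L)
  # secondary measures use the 59 non-outlier figures
  expect_equal(sc$accuracy, 29 / 59)
  expect_equal(sc$pct_incorrect, 100 * 30 / 59)
})

test_that("secondary measures ignore the time limit and the 70% gate splits at 42/60", {
  lat <- rep(2000, 60)
  ok41 <- score_figid_session(make_figid_session(lat, rep(c(TRUE, FALSE),
                                                          c(41, 19))))
  expect_false(ok41$scored)             # 41/60 = 0.6833
  ok42 <- score_figid_session(make_figid_session(lat, rep(c(TRUE, FALSE),
                                                          c(42, 18))))
  expect_true(ok42$scored)              # 42/60 = 0.70 exactly

  perfect <- score_figid_session(make_figid_session(rep(2000, 60)))
  expect_equal(perfect$score, 60L)
  expect_equal(perfect$pct_incorrect, 0)
  expect_equal(perfect$median_rt_correct_s, 2.0)

  # median over ALL correct non-outlier figures, not just those in time
  slow <- make_figid_session(rep(8000, 60))        # only 11 fit per set
  sc <- score_figid_session(slow)
  expect_equal(sc$score, 22L)
  expect_equal(sc$median_rt_correct_s, 8.0)
})

test_that("scores match the cumulative-clock oracle and are monotone in the limit", {
  set.seed(21)
  for (i in 1:300) {
    s <- random_figid_session()
    sc90 <- score_figid_session(s)
    expect_identical(sc90$score, oracle_figid_score(s))
    sc120 <- score_figid_session(s, scoring_limits(set_limit_s = 120))
    expect_gte(sc120$score, sc90$score)
    kept <- remove_outlier_trials(s)$trials
    sc_inf <- score_figid_session(s, scoring_limits(set_limit_s = 1e9))
    expect_identical(sc_inf$score, as.integer(sum(kept$correct)))
  }
})

test_that("block design respects the rank-group constraint and optimizes its objective", {
  set.seed(22)
  bank <- data.frame(item_id = 1:60,
                     median_rt = runif(60, 3, 7),
                     iqr_rt = runif(60, 0.5, 2))
  des <- design_item_blocks(bank, n_blocks = 6, n_iter = 100, seed = 5,
                            keep_iterations = TRUE)
  expect_equal(as.vector(table(des$assignment$block_id)), rep(10L, 6))
  # one item per block within every rank group, in every sampled iteration
  ord <- order(bank$median_rt, bank$item_id)
  groups <- split(ord, rep(1:10, each = 6))
  for (it in des$iterations)
    for (g in groups)
      expect_setequal(it$block_id[g], 1:6)
  objs <- vapply(des$iterations, `[[`, numeric(1), "objective")
  expect_true(all(des$objective_value <= objs))
  expect_equal(des$objective_value, objs[des$chosen_iteration])
  # reproducibility
  des2 <- design_item_blocks(bank, n_blocks = 6, n_iter = 100, seed = 5)
  expect_equal(des2$assignment, des$assignment)
})

test_that("identical item statistics make every assignment optimal at iteration 1", {
  bank <- data.frame(item_id = 1:12, median_rt = rep(4, 12),
                     iqr_rt = rep(1, 12))
  des <- design_item_blocks(bank, n_blocks = 2, n_iter = 50, seed = 3)
  expect_equal(des$objective_value, 0)
  expect_equal(des$chosen_iteration, 1L)
})

test_that("block design rejects non-divisible item counts", {
  bank <- data.frame(item_id = 1:10, median_rt = 1:10, iqr_rt = rep(1, 10))
  expect_error(design_item_blocks(bank, n_blocks = 3),
               class = "speedcog_config_error")
})
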