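test_that("trial logs round-trip through CSV and JSON-lines unchanged", {
  set.seed(42)
  cohort <- simulate_cohort(sim_config(n_respondents = 4, seed = 99))
  trials <- cohort$trials
  ord <- order(trials$respondent_id, trials$test, trials$session_index,
               trials$trial_index)
  expected <- trials[ord, ]
  rownames(expected) <- NULL
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trial_log(trials, path, format = fmt)
    back <- read_trial_log(path, format = fmt, quiet = TRUE)
    expect_equal(back, expected, info = fmt)
  }
})

test_that("an empty file with a valid header reads as an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(c("respondent_id", "test", "session_index", "device_type",
                     "trial_index", "trial_type", "item_id", "block_id",
                     "latency_ms", "correct"), collapse = ","), path)
  out <- read_trial_log(path, quiet = TRUE)
  expect_equal(nrow(out), 0L)
})

test_that("reading rejects bad rows with typed errors naming the problem", {
  set.seed(1)
  s <- random_sgst_session()
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- s; bad$latency_ms[3] <- -5
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(read_trial_log(path, quiet = TRUE),
               class = "speedcog_integrity_error")

  # malformed numeric cell: parse error carries the line number
  txt <- readLines(path)
  txt[4] <- sub("-5", "oops", txt[4], fixed = TRUE)
  writeLines(txt, path)
  err <- expect_error(read_trial_log(path, quiet = TRUE),
                      class = "speedcog_parse_error")
  expect_match(conditionMessage(err), "line 4")

  # header not matching the documented schema
  write.csv(setNames(s, c("id", names(s)[-1])), path, row.names = FALSE)
  expect_error(read_trial_log(path, quiet = TRUE),
               class = "speedcog_format_error")

  # duplicated trial_index within a session
  dup <- s; dup$trial_index[2] <- 1L
  write.csv(dup, path, row.names = FALSE, na = "")
  expect_error(read_trial_log(path, quiet = TRUE),
               class = "speedcog_integrity_error")
})

test_that("writing validates before touching the disk", {
  set.seed(2)
  s <- random_sgst_session()
  path <- withr::local_tempfile(fileext = ".csv")
  # 48 trials violate the fixed inventory
  expect_error(write_trial_log(s[-1, ], path),
               class = "speedcog_integrity_error")
  expect_false(file.exists(path))
  # interleaved respondents come back sorted by key
  set.seed(3)
  two <- rbind(random_sgst_session("B"), random_sgst_session("A"))
  write_trial_log(two, path)
  back <- read_trial_log(path, quiet = TRUE)
  expect_equal(unique(back$respondent_id), c("A", "B"))
})

test_that("validate_session checks the fixed trial inventories", {
  set.seed(4)
  fig <- random_figid_session()
  expect_true(validate_session(fig)$valid)

  missing_item <- validate_session(fig[-60, ])
  expect_false(missing_item$valid)
  expect_match(paste(missing_item$problems, collapse = " "), "60 item")

  sg <- random_sgst_session()
  sg$trial_type[sg$trial_type == "nonswitch"][1] <- "switch"  # 7 switch trials
  rep <- validate_session(sg)
  expect_false(rep$valid)
  expect_match(paste(rep$problems, collapse = " "), "switch")

  expect_error(validate_session(rbind(sg, fig)),
               class = "speedcog_integrity_error")
})

test_that("extreme latencies are flagged but not removed at validation", {
  set.seed(5)
  fig <- random_figid_session(p_outlier = 0)
  fig$latency_ms[7] <- 31000
  rep <- validate_session(fig)
  expect_true(rep$valid)
  expect_equal(rep$latency_flags, 7L)
})

test_that("respondent and environment tables round-trip with validation", {
  cohort <- simulate_cohort(sim_config(n_respondents = 3, seed = 8))
  rp <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  write_respondents(cohort$respondents, rp)
  write_environment(cohort$environment, ep)
  expect_equal(read_respondents(rp), cohort$respondents)
  env <- cohort$environment
  ord <- order(env$respondent_id, env$test, env$session_index)
  env <- env[ord, ]; rownames(env) <- NULL
  expect_equal(read_environment(ep), env)

  bad <- cohort$respondents; bad$weight[1] <- -1
  expect_error(write_respondents(bad, rp), class = "speedcog_integrity_error")
  bade <- cohort$environment; bade$interrupted[1] <- 2L
  expect_error(write_environment(bade, ep), class = "speedcog_integrity_error")
})
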