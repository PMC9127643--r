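# Session builders and independent oracles used across the suite. The
# oracles deliberately re-derive each quantity by the most literal route
# (sorting, walking a clock, exhaustive enumeration, large-n simulation)
# and share no code with the package implementation.

SGST_TYPES <- c("normal", "reverse", "nonswitch", "switch")

# A valid 49-trial switching-task session. latencies: named list with one
# numeric vector per trial type (ms); correct: logical vector in
# administration order (normal, reverse, then the mixed block).
make_sgst_session <- function(latencies, correct = rep(TRUE, 49),
                              rid = "P1", session = 1L,
                              device = "keyboard") {
  stopifnot(lengths(latencies[SGST_TYPES]) == c(10, 10, 23, 6))
  mixed <- rep("nonswitch", 29)
  mixed[c(5, 10, 15, 20, 24, 28)] <- "switch"
  types <- c(rep("normal", 10), rep("reverse", 10), mixed)
  lat <- numeric(49)
  for (tt in SGST_TYPES) lat[types == tt] <- latencies[[tt]]
  data.frame(respondent_id = rid, test = "SGST", session_index = session,
             device_type = device, trial_index = 1:49, trial_type = types,
             item_id = NA_integer_, block_id = NA_integer_,
             latency_ms = lat, correct = correct, stringsAsFactors = FALSE)
}

random_sgst_session <- function(rid = "P1") {
  make_sgst_session(
    latencies = list(normal = round(stats::rlnorm(10, log(1000), 0.5)),
                     reverse = round(stats::rlnorm(10, log(1100), 0.5)),
                     nonswitch = round(stats::rlnorm(23, log(950), 0.5)),
                     switch = round(stats::rlnorm(6, log(1500), 0.5))),
    correct = stats::runif(49) < 0.8, rid = rid)
}

# A valid 60-item figure-identification session; items administered in id
# order, blocks of 10 consecutive items.
make_figid_session <- function(latency_ms, correct = rep(TRUE, 60),
                               rid = "P1", session = 1L,
                               device = "keyboard") {
  stopifnot(length(latency_ms) == 60, length(correct) == 60)
  data.frame(respondent_id = rid, test = "FIGID", session_index = session,
             device_type = device, trial_index = 1:60,
             trial_type = NA_character_, item_id = 1:60,
             block_id = rep(1:6, each = 10), latency_ms = latency_ms,
             correct = correct, stringsAsFactors = FALSE)
}

random_figid_session <- function(rid = "P1", p_outlier = 0.01) {
  lat <- round(stats::rlnorm(60, log(4000), 0.6))
  out <- stats::runif(60) < p_outlier
  lat[out] <- round(stats::runif(sum(out), 25000, 45000))
  make_figid_session(lat, correct = stats::runif(60) < 0.85, rid = rid)
}

# --- sort-and-index oracle for the switching-task medians ----------------
oracle_sgst_medians <- function(session, include_incorrect = FALSE) {
  out <- numeric(0)
  for (tt in SGST_TYPES) {
    keep <- session$trial_type == tt
    if (!include_incorrect) keep <- keep & session$correct
    v <- sort(session$latency_ms[keep])       # work in ms; convert once
    n <- length(v)
    m <- if (n == 0) NA_real_
         else if (n %% 2 == 1) v[(n + 1) / 2]
         else (v[n / 2] + v[n / 2 + 1]) / 2
    out[tt] <- m / 1000
  }
  out
}

# --- cumulative-clock oracle for the posterior time limit ----------------
oracle_figid_score <- function(session, set_limit_s = 90, cut_s = 30) {
  clock <- c(0, 0)
  score <- 0L
  for (i in order(session$trial_index)) {
    set <- if (session$trial_index[i] <= 30) 1L else 2L
    if (session$latency_ms[i] > cut_s * 1000) next  # removed entirely
    clock[set] <- clock[set] + session$latency_ms[i]
    if (session$correct[i] && clock[set] <= set_limit_s * 1000)
      score <- score + 1L
  }
  score
}

# --- independent block-balance objective and exhaustive enumeration ------
oracle_block_objective <- function(items, block_id, n_blocks) {
  bm <- sapply(1:n_blocks, function(b) median(items$median_rt[block_id == b]))
  bi <- sapply(1:n_blocks, function(b)
    IQR(items$median_rt[block_id == b]))
  safe_ratio <- function(v, g) if (v < 1e-14) 0 else v / g
  safe_ratio(var(bm), var(items$median_rt)) +
    safe_ratio(var(bi), var(items$iqr_rt))
}

# all constrained assignments for a 2-block instance: each consecutive
# rank-pair is split one item per block, so each group has 2 choices
enumerate_block_assignments_2 <- function(items) {
  n <- nrow(items)
  ord <- order(items$median_rt, items$item_id)
  n_groups <- n / 2
  grids <- expand.grid(rep(list(1:2), n_groups))
  lapply(seq_len(nrow(grids)), function(i) {
    block_id <- integer(n)
    for (g in seq_len(n_groups)) {
      pair <- ord[c(2 * g - 1, 2 * g)]
      first <- grids[i, g]
      block_id[pair[1]] <- first
      block_id[pair[2]] <- 3 - first
    }
    block_id
  })
}

# --- brute-force generative-law oracle for the device effect -------------
# Simulates person-level nonswitch medians for attentive respondents under
# the stated law (lognormal trials; additive age, device, interruption and
# person effects on the log scale) and returns Cohen d touch vs keyboard.
oracle_device_d <- function(delta_device, n_per_group,
                            beta_age = 0.006, delta_interrupt = 0.08,
                            baseline_s = 0.95, sigma_person = 0.25,
                            sigma_trial = 0.20, p_interrupt = 0.125,
                            p_correct = 0.97, n_trials = 23) {
  person_scores <- function(device_shift, n) {
    ages <- sample(18:101, n, replace = TRUE, prob = dnorm(18:101, 50, 16))
    mu <- log(baseline_s) + beta_age * (ages - 50) + device_shift +
      delta_interrupt * (runif(n) < p_interrupt) +
      rnorm(n, 0, sigma_person)
    lat <- matrix(exp(rep(mu, each = n_trials) +
                      rnorm(n * n_trials, 0, sigma_trial)), nrow = n_trials)
    lat[runif(n_trials * n) >= p_correct] <- NA   # incorrect trials dropped
    apply(lat, 2, median, na.rm = TRUE)
  }
  kb <- person_scores(0, n_per_group)
  ts <- person_scores(delta_device, n_per_group)
  sp <- sqrt(((length(kb) - 1) * var(kb) + (length(ts) - 1) * var(ts)) /
             (length(kb) + length(ts) - 2))
  (mean(ts) - mean(kb)) / sp
}
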