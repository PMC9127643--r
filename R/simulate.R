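# Synthetic-cohort generator. Trial latencies are lognormal with additive
# effects on the log scale (age, device, interruption, person); a small
# careless subpopulation answers at chance-like accuracy with rushed
# latencies. Weights are two-way (age band x education) inverse-inclusion
# weights normalized to mean 1.

AGE_BAND_BREAKS <- c(18, 35, 45, 55, 65, 75, Inf)
AGE_BAND_LABELS <- c("18-34", "35-44", "45-54", "55-64", "65-74", ">=75")
EDU_LEVELS <- c("hs_or_less", "some_college", "bachelor_plus")

#' Configuration of the synthetic cohort
#'
#' Returns a validated list of generative parameters. Defaults are
#' calibrated so that a mid-panel (age 50) attentive keyboard respondent has
#' median trial latencies near 1.0/1.1/0.95/1.5 s for the four switching-task
#' trial types and figure-matching item medians spanning roughly 3-7 s, a
#' ~12.5% session interruption rate, ~90% at-home testing, and a 5%
#' careless subpopulation answering at 55% accuracy.
#'
#' @param n_respondents number of panel members to draw.
#' @param seed integer master seed; every respondent gets a derived
#'   substream so earlier respondents are unchanged when `n_respondents`
#'   grows.
#' @param tests which tests to administer (`"SGST"`, `"FIGID"` or both).
#' @param n_sessions sessions per test per respondent (2 emulates the
#'   repeated, device-crossed design).
#' @param age_range,age_mean,age_sd integer age support and the (truncated,
#'   discretized) normal law ages are drawn from.
#' @param beta_age additive effect on log-latency per year of age, centered
#'   at age 50.
#' @param delta_device additive log-latency effect of a touch-screen device.
#' @param delta_interrupt additive log-latency effect of an interrupted
#'   session (applied to all trials of that session).
#' @param trial_type_baselines named median latencies (seconds) of the four
#'   SGST trial types at age 50 on a keyboard.
#' @param figid_item_baselines 60 per-item median latencies in seconds.
#' @param sigma_person,sigma_trial between-person and within-person SDs of
#'   log-latency.
#' @param p_correct_attentive,p_correct_careless per-trial correctness
#'   probabilities for attentive and careless respondents.
#' @param careless_fraction fraction of respondents answering carelessly
#'   (their latencies are drawn at 0.6x the attentive scale).
#' @param p_outlier probability a figure-matching latency is replaced by an
#'   extreme Uniform(30, 60) s response.
#' @param prevalence named Bernoulli probabilities of the binary
#'   environment fields.
#' @param p_own_both,p_own_keyboard_only device-ownership mix; the
#'   remainder owns only a touch-screen device. Ownership is drawn
#'   independently of age.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 1000L,
                       seed = 20260101L,
                       tests = c("SGST", "FIGID"),
                       n_sessions = 2L,
                       age_range = c(18L, 101L),
                       age_mean = 50, age_sd = 16,
                       beta_age = 0.006,
                       delta_device = 0.05,
                       delta_interrupt = 0.08,
                       trial_type_baselines = c(normal = 1.00, reverse = 1.10,
                                                nonswitch = 0.95, switch = 1.50),
                       figid_item_baselines = exp(seq(log(3), log(7),
                                                      length.out = 60)),
                       sigma_person = 0.25,
                       sigma_trial = 0.20,
                       p_correct_attentive = 0.97,
                       p_correct_careless = 0.55,
                       careless_fraction = 0.05,
                       p_outlier = 0.002,
                       prevalence = c(interrupted = 0.125, at_home = 0.896,
                                      watching_tv = 0.15, listening_music = 0.085,
                                      talking = 0.07, texting_email = 0.007,
                                      internet_content = 0.007,
                                      playing_game = 0.0015),
                       p_own_both = 0.52,
                       p_own_keyboard_only = 0.16) {
  if (!is_count(n_respondents))
    sc_config_error("n_respondents must be a positive integer")
  if (!is_count(n_sessions) || n_sessions > 2)
    sc_config_error("n_sessions must be 1 or 2")
  tests <- match.arg(tests, TESTS, several.ok = TRUE)
  if (!all(sort(names(trial_type_baselines)) == sort(TRIAL_TYPES)) ||
      any(trial_type_baselines <= 0))
    sc_config_error("trial_type_baselines must name positive medians for the four trial types")
  if (length(figid_item_baselines) != 60 || any(figid_item_baselines <= 0))
    sc_config_error("figid_item_baselines must be 60 positive medians")
  if (sigma_person <= 0 || sigma_trial <= 0)
    sc_config_error("sigma_person and sigma_trial must be positive")
  probs <- c(p_correct_attentive, p_correct_careless, careless_fraction,
             p_outlier, prevalence, p_own_both, p_own_keyboard_only)
  if (!all(vapply(probs, is_prob, logical(1))))
    sc_config_error("all probabilities must lie in [0, 1]")
  if (p_own_both + p_own_keyboard_only > 1)
    sc_config_error("device ownership probabilities exceed 1")
  if (!setequal(names(prevalence), ENV_COLUMNS[4:11]))
    sc_config_error("prevalence must name the eight environment fields")
  structure(list(
    n_respondents = as.integer(n_respondents), seed = as.integer(seed),
    tests = tests, n_sessions = as.integer(n_sessions),
    age_range = as.integer(age_range), age_mean = age_mean, age_sd = age_sd,
    beta_age = beta_age, delta_device = delta_device,
    delta_interrupt = delta_interrupt,
    trial_type_baselines = trial_type_baselines[TRIAL_TYPES],
    figid_item_baselines = figid_item_baselines,
    sigma_person = sigma_person, sigma_trial = sigma_trial,
    p_correct_attentive = p_correct_attentive,
    p_correct_careless = p_correct_careless,
    careless_fraction = careless_fraction, p_outlier = p_outlier,
    prevalence = prevalence[ENV_COLUMNS[4:11]],
    p_own_both = p_own_both, p_own_keyboard_only = p_own_keyboard_only),
    class = "sim_config")
}

# deterministic 32-bit substream seed per (master seed, unit index, tag)
substream_seed <- function(seed, index, tag = 0L) {
  as.integer((as.double(seed) %% 2147483647 * 69069 +
              as.double(index) * 7907 + as.double(tag) * 104729) %% 2147483647)
}

age_distribution <- function(config) {
  ages <- seq(config$age_range[1L], config$age_range[2L])
  p <- stats::dnorm(ages, config$age_mean, config$age_sd)
  list(ages = ages, p = p / sum(p))
}

# US-adult-flavored population shares used for the inverse-inclusion weights
POP_BAND_SHARE <- c(`18-34` = 0.30, `35-44` = 0.16, `45-54` = 0.16,
                    `55-64` = 0.16, `65-74` = 0.13, `>=75` = 0.09)
POP_EDU_SHARE  <- c(hs_or_less = 0.38, some_college = 0.30, bachelor_plus = 0.32)
# relative inclusion rate of education groups in the (internet) panel
EDU_INCLUSION  <- c(hs_or_less = 0.70, some_college = 1.00, bachelor_plus = 1.35)

edu_sampling_probs <- function() {
  q <- POP_EDU_SHARE * EDU_INCLUSION
  q / sum(q)
}

band_of_age <- function(age) {
  as.character(cut(age, AGE_BAND_BREAKS, labels = AGE_BAND_LABELS,
                   right = FALSE, include.lowest = TRUE))
}

# weight mapping is analytic (population share / sampling share), so it is a
# deterministic function of (band, education) and not of the realized sample
respondent_weight <- function(band, edu, config) {
  dist <- age_distribution(config)
  samp_band <- tapply(dist$p, band_of_age(dist$ages), sum)[AGE_BAND_LABELS]
  w_band <- POP_BAND_SHARE[band] / samp_band[band]
  w_edu <- (POP_EDU_SHARE / edu_sampling_probs())[edu]
  unname(w_band * w_edu)
}

rbern <- function(n, p) stats::runif(n) < p

sgst_trial_sequence <- function() {
  mixed <- sample(c(rep("nonswitch", 23L), rep("switch", 6L)))
  c(rep("normal", 10L), rep("reverse", 10L), mixed)
}

# fixed default item->block map: items ranked by baseline latency; each
# consecutive rank-sextet contributes one item per block
default_block_of_item <- function(config) {
  rank <- order(order(config$figid_item_baselines, seq_len(60)))
  ((rank - 1L) %% 6L) + 1L
}

figid_item_order <- function(block_of_item) {
  order_blocks <- sample(1:6)
  unlist(lapply(order_blocks, function(b) sample(which(block_of_item == b))),
         use.names = FALSE)
}

trial_log_latencies <- function(mu_log, shift, sigma_trial) {
  pmax(1, round(exp(mu_log + shift + stats::rnorm(length(mu_log), 0, sigma_trial)) * 1000))
}

#' Simulate a synthetic survey cohort
#'
#' Draws respondents, their trial logs and post-test environment reports
#' under the generative law described in the package vignette: per-trial
#' log-latency is a trial-type (or item) baseline plus additive age, device
#' and interruption effects, a person effect and trial noise; correctness is
#' Bernoulli at the attentive or careless rate; figure-matching latencies
#' are occasionally replaced by extreme (>30 s) responses. Sampling weights
#' are inverse-inclusion weights over age band x education, normalized to
#' mean 1. Fully reproducible from `config$seed`; each respondent has a
#' dedicated random substream.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `speedcog_cohort` with data frames
#'   `respondents`, `trials` and `environment`, plus the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_respondents = 5, seed = 7))
#' table(cohort$trials$test)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    sc_config_error("config must come from sim_config()")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  dist <- age_distribution(config)
  edu_q <- edu_sampling_probs()
  block_of_item <- default_block_of_item(config)
  mu_type <- log(config$trial_type_baselines)       # median -> log-scale mean
  mu_item <- log(config$figid_item_baselines)

  resp_rows <- vector("list", config$n_respondents)
  trial_rows <- vector("list", config$n_respondents)
  env_rows <- vector("list", config$n_respondents)

  for (i in seq_len(config$n_respondents)) {
    set.seed(substream_seed(config$seed, i))
    rid <- sprintf("R%05d", i)
    age <- sample(dist$ages, 1L, prob = dist$p)
    edu <- sample(EDU_LEVELS, 1L, prob = edu_q)
    sex <- sample(c("female", "male"), 1L, prob = c(0.59, 0.41))
    race <- sample(c("white", "black", "hispanic", "other"), 1L,
                   prob = c(0.65, 0.07, 0.16, 0.12))
    income <- sample(c("lt25k", "25-49k", "50-99k", "ge100k"), 1L,
                     prob = c(0.15, 0.20, 0.34, 0.31))
    careless <- rbern(1L, config$careless_fraction)
    u <- stats::rnorm(1L, 0, config$sigma_person)

    own_draw <- stats::runif(1L)
    owned <- if (own_draw < config$p_own_both) DEVICES
             else if (own_draw < config$p_own_both + config$p_own_keyboard_only)
               "keyboard" else "touchscreen"
    session_devices <- if (length(owned) == 2L) sample(owned) else
      rep(owned, 2L)

    p_correct <- if (careless) config$p_correct_careless else
      config$p_correct_attentive
    careless_shift <- if (careless) log(0.6) else 0
    base_shift <- config$beta_age * (age - 50) + u + careless_shift

    t_acc <- list(); e_acc <- list()
    for (test in config$tests) {
      for (s in seq_len(config$n_sessions)) {
        device <- session_devices[s]
        env <- as.integer(rbern(8L, config$prevalence))
        names(env) <- names(config$prevalence)
        shift <- base_shift + config$delta_device * (device == "touchscreen") +
          config$delta_interrupt * env[["interrupted"]]
        if (test == "SGST") {
          types <- sgst_trial_sequence()
          n_t <- length(types)
          chunk <- list(
            respondent_id = rep(rid, n_t), test = rep(test, n_t),
            session_index = rep(s, n_t), device_type = rep(device, n_t),
            trial_index = seq_len(n_t), trial_type = types,
            item_id = rep(NA_integer_, n_t), block_id = rep(NA_integer_, n_t),
            latency_ms = trial_log_latencies(mu_type[types], shift,
                                             config$sigma_trial),
            correct = rbern(n_t, p_correct))
        } else {
          items <- figid_item_order(block_of_item)
          n_t <- length(items)
          lat <- trial_log_latencies(mu_item[items], shift, config$sigma_trial)
          is_out <- rbern(n_t, config$p_outlier)
          lat[is_out] <- round(stats::runif(sum(is_out), 30, 60) * 1000)
          chunk <- list(
            respondent_id = rep(rid, n_t), test = rep(test, n_t),
            session_index = rep(s, n_t), device_type = rep(device, n_t),
            trial_index = seq_len(n_t), trial_type = rep(NA_character_, n_t),
            item_id = items, block_id = block_of_item[items],
            latency_ms = lat, correct = rbern(n_t, p_correct))
        }
        t_acc[[length(t_acc) + 1L]] <- chunk
        e_acc[[length(e_acc) + 1L]] <-
          c(list(respondent_id = rid, test = test, session_index = s),
            as.list(env))
      }
    }
    band <- band_of_age(age)
    resp_rows[[i]] <- list(
      respondent_id = rid, age = as.integer(age), sex = sex, race = race,
      education = edu, income = income,
      weight = respondent_weight(band, edu, config),
      devices_owned = paste(owned, collapse = "|"))
    trial_rows[[i]] <- t_acc
    env_rows[[i]] <- e_acc
  }
  bind_chunks <- function(rows, columns) {
    out <- lapply(columns, function(col)
      unlist(lapply(rows, `[[`, col), use.names = FALSE))
    names(out) <- columns
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  respondents <- bind_chunks(resp_rows, RESPONDENT_COLUMNS)
  respondents$weight <- respondents$weight / mean(respondents$weight)
  trial_chunks <- unlist(trial_rows, recursive = FALSE)
  trials <- bind_chunks(trial_chunks, TRIAL_COLUMNS)
  env_chunks <- unlist(env_rows, recursive = FALSE)
  environment <- bind_chunks(env_chunks, ENV_COLUMNS)
  validate_trials(trials)
  structure(list(respondents = respondents, trials = trials,
                 environment = environment, config = config),
            class = "speedcog_cohort")
}

#' @export
print.speedcog_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$respondents), "respondents,",
      nrow(x$trials), "trials,", nrow(x$environment), "environment reports\n")
  cat("  tests:", paste(x$config$tests, collapse = ", "),
      "| sessions per test:", x$config$n_sessions,
      "| seed:", x$config$seed, "\n")
  invisible(x)
}

#' Simulate a pilot item bank for the figure-matching test
#'
#' Emulates the pilot study used to characterize item difficulty: a panel of
#' pilot respondents answers all 60 items once, and the per-item median and
#' IQR of the pooled item-level response times (seconds) are returned. These
#' statistics feed the block-balancing randomization
#' ([design_item_blocks()]).
#'
#' @param config a [sim_config()]; item baselines and variance components
#'   are taken from it.
#' @param n_pilot pilot sample size (default 900, the scale of the study's
#'   pilot).
#' @param seed seed for the pilot simulation (defaults to `config$seed`).
#' @return Data frame with columns `item_id`, `median_rt`, `iqr_rt`.
#' @export
generate_item_bank <- function(config, n_pilot = 900L, seed = config$seed) {
  if (!inherits(config, "sim_config"))
    sc_config_error("config must come from sim_config()")
  if (!is_count(n_pilot)) sc_config_error("n_pilot must be a positive integer")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, 0L, tag = 17L))

  dist <- age_distribution(config)
  ages <- sample(dist$ages, n_pilot, replace = TRUE, prob = dist$p)
  u <- stats::rnorm(n_pilot, 0, config$sigma_person)
  shift <- config$beta_age * (ages - 50) + u      # keyboard, uninterrupted pilot
  mu_item <- log(config$figid_item_baselines)
  lat <- matrix(exp(rep(mu_item, each = n_pilot) + shift +
                    stats::rnorm(60L * n_pilot, 0, config$sigma_trial)),
                nrow = n_pilot)
  data.frame(item_id = 1:60,
             median_rt = apply(lat, 2L, stats::median),
             iqr_rt = apply(lat, 2L, stats::IQR))
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
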