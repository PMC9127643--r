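# End-to-end study pipeline: simulate -> write -> validate -> score ->
# filter -> analyze -> norms, with a reproducible run manifest.

#' Configuration of a full study run
#'
#' @param sim a [sim_config()] for the synthetic cohort.
#' @param limits a [scoring_limits()] for the figure test.
#' @param include_incorrect_trials passed to the switching-task scorer.
#' @param age_breaks,age_labels age-group edges and labels for the norms
#'   (defaults: 18-34, 35-44, 45-54, 55-64, 65-74, >=75).
#' @param alpha nominal significance level recorded in the manifest.
#' @param within_person also run the paired within-person device
#'   comparison on both-device respondents.
#' @param seed optional integer overriding `sim$seed`.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), limits = scoring_limits(),
                       include_incorrect_trials = FALSE,
                       age_breaks = AGE_BAND_BREAKS,
                       age_labels = AGE_BAND_LABELS,
                       alpha = 0.05, within_person = TRUE, seed = NULL) {
  if (!inherits(sim, "sim_config")) sc_config_error("sim must be a sim_config")
  if (!inherits(limits, "scoring_limits"))
    sc_config_error("limits must come from scoring_limits()")
  if (any(diff(age_breaks) <= 0) || age_breaks[1L] > 18)
    sc_config_error("age-group edges must increase and cover ages 18+")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, limits = limits,
                 include_incorrect_trials = include_incorrect_trials,
                 age_breaks = age_breaks, age_labels = age_labels,
                 alpha = alpha, within_person = within_person),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Fields mirror the arguments of [sim_config()], [scoring_limits()] and
#' [run_config()] under keys `sim`, `limits` and top-level analysis
#' options.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) sc_format_error(paste0("no such file: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  sim_args <- raw$sim
  if (!is.null(sim_args$prevalence))
    sim_args$prevalence <- unlist(sim_args$prevalence)
  if (!is.null(sim_args$trial_type_baselines))
    sim_args$trial_type_baselines <- unlist(sim_args$trial_type_baselines)
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  limits <- do.call(scoring_limits,
                    if (is.null(raw$limits)) list() else raw$limits)
  extra <- raw[setdiff(names(raw), c("sim", "limits"))]
  do.call(run_config, c(list(sim = sim, limits = limits), extra))
}

env_first_session <- function(environment, test) {
  env <- environment[environment$test == test & environment$session_index == 1L, ]
  rownames(env) <- NULL
  env
}

# environment indicators with no variation in the analysis sample cannot be
# estimated; they are dropped from the model rather than failing the run
nondegenerate_env <- function(dat) {
  keep <- vapply(ENV_COLUMNS[4:11], function(col)
    length(unique(dat[[col]][!is.na(dat[[col]])])) > 1L, logical(1))
  ENV_COLUMNS[4:11][keep]
}

run_regressions <- function(retained, respondents, env, score_cols) {
  dat <- merge(retained, respondents[, c("respondent_id", "age")],
               by = "respondent_id")
  dat <- merge(dat, env[, c("respondent_id", ENV_COLUMNS[4:11])],
               by = "respondent_id")
  env_cols <- nondegenerate_env(dat)
  lapply(stats::setNames(score_cols, score_cols), function(col)
    ols_regression(dat[[col]], dat[, c("age", env_cols)]))
}

regression_table <- function(fits) {
  do.call(rbind, lapply(names(fits), function(outcome) {
    cf <- fits[[outcome]]$coefficients
    cbind(data.frame(outcome = outcome), cf, n = fits[[outcome]]$n)
  }))
}

run_norms <- function(retained, respondents, score_cols, config) {
  dat <- merge(retained, respondents[, c("respondent_id", "age", "weight")],
               by = "respondent_id")
  lapply(stats::setNames(score_cols, score_cols), function(col)
    weighted_group_norms(dat[[col]], dat$weight, dat$age,
                         breaks = config$age_breaks,
                         labels = config$age_labels))
}

norm_csv <- function(norms) {
  do.call(rbind, lapply(names(norms), function(score)
    cbind(data.frame(score_name = score), as.data.frame(norms[[score]]))))
}

SGST_SCORE_COLS <- c("median_normal_s", "median_reverse_s",
                     "median_nonswitch_s", "median_switch_s")
FIGID_SCORE_COLS <- c("score", "pct_incorrect", "median_rt_correct_s")

#' Run the full study pipeline
#'
#' Simulates a cohort, writes the three interchange CSVs, validates every
#' session, scores both tests, applies the 70% validity filter, and runs
#' the analyses: device-type effect sizes on first sessions, distraction
#' regressions with an age covariate, partial correlations of age and
#' score controlling for the environment indicators, survey-weighted
#' age-group norms, and (optionally) the paired within-person device
#' comparison. All stage outputs are written to `out_dir` together with a
#' JSON run manifest recording counts at each stage, the seed, a config
#' hash and per-file checksums; an identical config and seed reproduces an
#' identical manifest.
#'
#' @param config a [run_config()] object.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The manifest, an object of class `speedcog_run`, invisibly.
#' @export
run_study <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "run_config"))
    sc_config_error("config must come from run_config()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  stage <- "simulate"
  manifest <- list(seed = config$sim$seed, config_hash = config_hash(config),
                   alpha = config$alpha, stages = list(), files = list())
  result <- tryCatch({
    cohort <- simulate_cohort(config$sim)
    say(sprintf("simulated %d respondents", nrow(cohort$respondents)))
    write_respondents(cohort$respondents, file.path(out_dir, "respondents.csv"))
    write_trial_log(cohort$trials, file.path(out_dir, "trials.csv"))
    write_environment(cohort$environment, file.path(out_dir, "environment.csv"))

    stage <- "validate"
    keys <- unique(session_key(cohort$trials))
    check_session_inventories(cohort$trials)
    manifest$stages$n_respondents <- nrow(cohort$respondents)
    manifest$stages$n_sessions <- length(keys)

    analyses <- list()
    for (test in config$sim$tests) {
      stage <- paste0("score-", test)
      scores <- if (test == "SGST")
        score_sgst(cohort$trials, config$include_incorrect_trials, check = FALSE)
      else score_figid(cohort$trials, config$limits, check = FALSE)
      score_cols <- if (test == "SGST") SGST_SCORE_COLS else FIGID_SCORE_COLS
      first <- scores[scores$session_index == 1L, , drop = FALSE]
      parts <- filter_scored(first, quiet = quiet)
      manifest$stages[[paste0(tolower(test), "_completed")]] <- nrow(first)
      manifest$stages[[paste0(tolower(test), "_scored")]] <-
        unname(parts$counts[["retained"]])
      manifest$stages[[paste0(tolower(test), "_excluded")]] <-
        unname(parts$counts[["excluded"]])
      fname <- file.path(out_dir, paste0(tolower(test), "_scores.csv"))
      write_table(scores, fname)

      stage <- paste0("analyze-", test)
      retained <- parts$retained
      env <- env_first_session(cohort$environment, test)
      effects <- device_comparison(retained, cohort$respondents, score_cols)
      fits <- run_regressions(retained, cohort$respondents, env, score_cols)
      norms <- run_norms(retained, cohort$respondents, score_cols, config)
      pc <- partial_correlations_vs_age(retained, cohort$respondents, env,
                                        score_cols)
      write_table(as.data.frame(effects),
                  file.path(out_dir, paste0(tolower(test), "_effects.csv")))
      write_table(regression_table(fits),
                  file.path(out_dir, paste0(tolower(test), "_regression.csv")))
      write_table(norm_csv(norms),
                  file.path(out_dir, paste0(tolower(test), "_norms.csv")))
      wp <- NULL
      if (config$within_person && config$sim$n_sessions >= 2L) {
        stage <- paste0("within-person-", test)
        wp <- within_person_table(scores, score_cols)
      }
      analyses[[test]] <- list(scores = scores, effects = effects,
                               regressions = fits, norms = norms,
                               partial_correlations = pc, within_person = wp)
    }
    stage <- "manifest"
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$files <- data.frame(file = basename(files),
                                 md5 = unname(tools::md5sum(files)),
                                 row.names = NULL)
    manifest_out <- manifest
    jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    structure(c(manifest, list(analyses = analyses, out_dir = out_dir)),
              class = "speedcog_run")
  }, speedcog_error = function(e) {
    sc_abort(paste0("pipeline failed at stage '", stage, "': ",
                    conditionMessage(e)), class(e)[1L])
  })
  invisible(result)
}

# paired device comparison per score over respondents with a session on
# each device type (uses both sessions; both must pass the filter)
within_person_table <- function(scores, score_cols) {
  both <- scores[isTRUE_vec(scores$scored), , drop = FALSE]
  rows <- lapply(score_cols, function(col) {
    sub <- data.frame(respondent_id = both$respondent_id,
                      device_type = both$device_type, value = both[[col]])
    sub <- sub[!duplicated(paste(sub$respondent_id, sub$device_type)), ]
    res <- tryCatch(within_person_device_comparison(sub),
                    speedcog_error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(score_name = col, mean_diff = res$mean_diff,
               paired_d = res$paired_d, r_cross_device = res$r_cross_device,
               n_pairs = res$n_pairs)
  })
  do.call(rbind, rows)
}

partial_correlations_vs_age <- function(retained, respondents, env,
                                        score_cols) {
  dat <- merge(retained, respondents[, c("respondent_id", "age")],
               by = "respondent_id")
  dat <- merge(dat, env[, c("respondent_id", ENV_COLUMNS[4:11])],
               by = "respondent_id")
  env_cols <- nondegenerate_env(dat)
  do.call(rbind, lapply(score_cols, function(col) {
    ok <- stats::complete.cases(dat[[col]], dat$age)
    data.frame(score_name = col,
               r_zero_order = pearson_r(dat$age[ok], dat[[col]][ok]),
               r_partial = partial_correlation(dat$age[ok], dat[[col]][ok],
                                               dat[ok, env_cols, drop = FALSE]))
  }))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.speedcog_run <- function(x, ...) {
  cat("Study run (seed", x$seed, ", config", substr(x$config_hash, 1, 8), ")\n")
  st <- x$stages
  cat("  respondents:", st$n_respondents, "| sessions:", st$n_sessions, "\n")
  for (test in names(x$analyses)) {
    lt <- tolower(test)
    cat(sprintf("  %s: %d completed first sessions, %d scored, %d excluded\n",
                test, st[[paste0(lt, "_completed")]],
                st[[paste0(lt, "_scored")]], st[[paste0(lt, "_excluded")]]))
  }
  cat("  outputs in", x$out_dir, "\n")
  invisible(x)
}
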