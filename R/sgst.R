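# Switching-task scoring: median response time per trial type, gated by the
# 70% overall-accuracy validity filter.

#' Score one switching-task session
#'
#' Computes the four person-level scores of the switching task: median
#' response time (seconds) over the normal, reverse, nonswitch and switch
#' trials. A session is only scored when overall accuracy over its 49
#' trials is at least 70% (inclusive); below that the respondent is flagged
#' unscored and no medians are reported, since low accuracy indicates
#' careless or inattentive responding that invalidates the latencies.
#'
#' By default medians are taken over correct trials only; incorrect
#' responses do not measure the intended process, and the accuracy gate
#' bounds the resulting trial loss. Set `include_incorrect_trials = TRUE`
#' to take medians over all trials of each type. Even-count medians are the
#' mean of the two central order statistics. No latency trimming is applied
#' to this test.
#'
#' @param trials validated trial records of exactly one SGST session
#'   (10 normal, 10 reverse, 23 nonswitch, 6 switch trials).
#' @param include_incorrect_trials include incorrect trials in the medians.
#' @param check run [validate_session()] first (disable only for inputs
#'   already validated upstream).
#' @return One-row data frame: `respondent_id`, `session_index`,
#'   `device_type`, `median_normal_s`, `median_reverse_s`,
#'   `median_nonswitch_s`, `median_switch_s`, `accuracy`, `scored`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_respondents = 1, seed = 2))
#' s <- subset(cohort$trials, test == "SGST" & session_index == 1)
#' score_sgst_session(s)
#' @export
score_sgst_session <- function(trials, include_incorrect_trials = FALSE,
                               check = TRUE) {
  if (check) {
    if (!is.data.frame(trials) || !nrow(trials) || any(trials$test != "SGST"))
      sc_integrity_error("score_sgst_session expects records of one SGST session")
    rep <- validate_session(trials)
    if (!rep$valid)
      sc_integrity_error(paste0("session fails validation: ",
                                paste(rep$problems, collapse = "; ")))
  }
  n <- nrow(trials)
  accuracy <- sum(trials$correct) / n
  scored <- accuracy >= 0.70
  med <- rep(NA_real_, 4L)
  names(med) <- TRIAL_TYPES
  if (scored) {
    use <- if (include_incorrect_trials) rep(TRUE, n) else trials$correct
    for (tt in TRIAL_TYPES) {
      lat <- trials$latency_ms[use & trials$trial_type == tt]
      if (length(lat)) med[[tt]] <- stats::median(lat) / 1000
    }
  }
  data.frame(respondent_id = trials$respondent_id[1L],
             session_index = trials$session_index[1L],
             device_type = trials$device_type[1L],
             median_normal_s = med[["normal"]],
             median_reverse_s = med[["reverse"]],
             median_nonswitch_s = med[["nonswitch"]],
             median_switch_s = med[["switch"]],
             accuracy = accuracy, scored = scored,
             stringsAsFactors = FALSE)
}

#' Score every switching-task session in a trial log
#'
#' Splits a trial log into (respondent, session) groups and applies
#' [score_sgst_session()] to each.
#'
#' @param trials trial-log data frame (other tests' rows are ignored).
#' @inheritParams score_sgst_session
#' @return Data frame with one row per session.
#' @export
score_sgst <- function(trials, include_incorrect_trials = FALSE, check = TRUE) {
  trials <- trials[trials$test == "SGST", , drop = FALSE]
  if (!nrow(trials)) sc_integrity_error("no SGST trials to score")
  groups <- split(seq_len(nrow(trials)), session_key(trials))
  out <- do.call(rbind, lapply(groups, function(idx)
    score_sgst_session(trials[idx, , drop = FALSE],
                       include_incorrect_trials, check)))
  out <- out[order(out$respondent_id, out$session_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition scores by the validity filter
#'
#' Splits a score table (switching task or figure identification) into the
#' sessions retained by the 70% accuracy filter and those excluded by it.
#'
#' @param scores score data frame with a logical `scored` column.
#' @param quiet suppress the count message.
#' @return List with `retained`, `excluded` (data frames) and `counts`
#'   (named integer vector `retained`/`excluded`/`total`).
#' @export
filter_scored <- function(scores, quiet = FALSE) {
  if (!is.data.frame(scores) || is.null(scores$scored))
    sc_format_error("filter_scored expects a score table with a 'scored' column")
  keep <- isTRUE_vec(scores$scored)
  out <- list(retained = scores[keep, , drop = FALSE],
              excluded = scores[!keep, , drop = FALSE],
              counts = c(retained = sum(keep), excluded = sum(!keep),
                         total = nrow(scores)))
  if (!quiet)
    message(sprintf("validity filter: %d retained, %d excluded of %d",
                    out$counts[["retained"]], out$counts[["excluded"]],
                    out$counts[["total"]]))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
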