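# Figure-identification scoring: extreme-outlier removal, posterior time
# limit accumulation, the 70% accuracy filter, and the secondary
# accuracy/latency measures.

#' Scoring limits of the figure identification test
#'
#' The test is administered without a live time limit; scoring imposes a
#' *posterior* limit by accumulating recorded latencies. Defaults: 90
#' seconds per 30-item set, 2 sets, and removal of extreme outlier
#' latencies above 30 seconds.
#'
#' @param set_limit_s posterior time limit per 30-item set, seconds.
#' @param n_sets number of item sets (positions 1-30 and 31-60).
#' @param outlier_cut_s latencies strictly above this many seconds are
#'   removed from the data entirely.
#' @return List of class `scoring_limits`.
#' @export
scoring_limits <- function(set_limit_s = 90, n_sets = 2L, outlier_cut_s = 30) {
  if (set_limit_s <= 0 || outlier_cut_s <= 0 || !is_count(n_sets))
    sc_config_error("scoring limits must all be positive")
  structure(list(set_limit_s = set_limit_s, n_sets = as.integer(n_sets),
                 outlier_cut_s = outlier_cut_s), class = "scoring_limits")
}

#' Remove extreme outlier trials
#'
#' Drops trials whose latency exceeds the outlier cut (strictly greater
#' than 30 s by default, i.e. 30000 ms; the comparison is done in
#' milliseconds so a latency of exactly 30 s is retained). Removed trials
#' contribute neither time to the posterior clock nor correctness credit
#' nor an accuracy-denominator slot downstream. Administration order of the
#' remainder is preserved.
#'
#' @param trials validated figure-identification session.
#' @param limits a [scoring_limits()] object.
#' @return List with `trials` (retained rows) and `n_removed`.
#' @export
remove_outlier_trials <- function(trials, limits = scoring_limits()) {
  cut_ms <- limits$outlier_cut_s * 1000
  keep <- trials$latency_ms <= cut_ms
  list(trials = trials[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Apply the posterior time limit
#'
#' Within each administered 30-item set (set membership is by administered
#' position 1-30 / 31-60, fixed before outlier removal), retained latencies
#' are accumulated in administration order; a figure counts toward the
#' score iff it was answered correctly and the cumulative time through its
#' own response is at most the set limit (the boundary is inclusive:
#' "within 90 seconds" includes exactly 90.000 s). The score is the sum
#' over both sets.
#'
#' @param trials outlier-free session rows, carrying their original
#'   `trial_index`.
#' @param limits a [scoring_limits()] object.
#' @return Integer score (number of correctly identified figures within the
#'   time limits).
#' @examples
#' # 60 correct figures at exactly 3 s each: the clock reaches 90.000 s at
#' # item 30 of each set, so all 60 count.
#' @export
apply_posterior_time_limit <- function(trials, limits = scoring_limits()) {
  if (!nrow(trials)) return(0L)
  set_size <- FIGID_N_ITEMS / limits$n_sets
  set_of <- ceiling(trials$trial_index / set_size)
  limit_ms <- limits$set_limit_s * 1000
  score <- 0L
  for (s in sort(unique(set_of))) {
    rows <- which(set_of == s)
    rows <- rows[order(trials$trial_index[rows])]
    clock <- cumsum(trials$latency_ms[rows])
    score <- score + sum(trials$correct[rows] & clock <= limit_ms)
  }
  as.integer(score)
}

#' Score one figure-identification session
#'
#' Primary score: number of figures correctly identified within the
#' posterior time limits, after removal of extreme (>30 s) outlier trials.
#' Secondary measures ignore the time limit: `pct_incorrect` is the
#' percentage of non-outlier figures answered incorrectly and
#' `median_rt_correct_s` the median latency (seconds) over all correct
#' non-outlier figures. A session is scored only when accuracy over the
#' non-outlier figures is at least 70% (inclusive); outlier-removed figures
#' are excluded from the accuracy denominator.
#'
#' @param trials validated trial records of one FIGID session (60 items).
#' @param limits a [scoring_limits()] object.
#' @param check run [validate_session()] first.
#' @return One-row data frame: `respondent_id`, `session_index`,
#'   `device_type`, `score` (0-60), `pct_incorrect`, `median_rt_correct_s`,
#'   `accuracy`, `n_outliers_removed`, `scored`.
#' @export
score_figid_session <- function(trials, limits = scoring_limits(),
                                check = TRUE) {
  if (check) {
    if (!is.data.frame(trials) || !nrow(trials) || any(trials$test != "FIGID"))
      sc_integrity_error("score_figid_session expects records of one FIGID session")
    rep <- validate_session(trials)
    if (!rep$valid)
      sc_integrity_error(paste0("session fails validation: ",
                                paste(rep$problems, collapse = "; ")))
  }
  kept <- remove_outlier_trials(trials, limits)
  k <- kept$trials
  n_kept <- nrow(k)
  accuracy <- if (n_kept) sum(k$correct) / n_kept else NA_real_
  scored <- !is.na(accuracy) && accuracy >= 0.70
  score <- apply_posterior_time_limit(k, limits)
  med <- if (any(k$correct)) stats::median(k$latency_ms[k$correct]) / 1000
         else NA_real_
  data.frame(respondent_id = trials$respondent_id[1L],
             session_index = trials$session_index[1L],
             device_type = trials$device_type[1L],
             score = score,
             pct_incorrect = if (is.na(accuracy)) NA_real_ else 100 * (1 - accuracy),
             median_rt_correct_s = med,
             accuracy = accuracy,
             n_outliers_removed = kept$n_removed,
             scored = scored, stringsAsFactors = FALSE)
}

#' Score every figure-identification session in a trial log
#'
#' @param trials trial-log data frame (other tests' rows are ignored).
#' @inheritParams score_figid_session
#' @return Data frame with one row per session.
#' @export
score_figid <- function(trials, limits = scoring_limits(), check = TRUE) {
  trials <- trials[trials$test == "FIGID", , drop = FALSE]
  if (!nrow(trials)) sc_integrity_error("no FIGID trials to score")
  groups <- split(seq_len(nrow(trials)), session_key(trials))
  out <- do.call(rbind, lapply(groups, function(idx)
    score_figid_session(trials[idx, , drop = FALSE], limits, check)))
  out <- out[order(out$respondent_id, out$session_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
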