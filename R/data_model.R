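# Trial-log and respondent data model: the tabular interchange layer every
# other module consumes. Latencies are stored in milliseconds; all derived
# scores downstream are reported in seconds.

#' @name trial-log-schema
#' @title Trial-log data model
#'
#' @description
#' A trial log is a data frame with one row per stimulus-response event and
#' columns `respondent_id` (character), `test` (`"SGST"` or `"FIGID"`),
#' `session_index` (integer, 1-based), `device_type` (`"keyboard"` or
#' `"touchscreen"`), `trial_index` (integer, 1-based administration order
#' within a session), `trial_type` (`"normal"`, `"reverse"`, `"nonswitch"`,
#' `"switch"`; SGST only, `NA` for FIGID), `item_id` (integer 1-60, FIGID
#' only), `block_id` (integer 1-6, FIGID only), `latency_ms` (positive
#' number) and `correct` (logical).
#'
#' A conforming SGST session holds exactly 10 normal, 10 reverse, 23
#' nonswitch and 6 switch trials (49 in total); a conforming figure
#' identification session holds exactly 60 item trials, 10 per block.
#' Administration order is the row order and must agree with `trial_index`.
NULL

TRIAL_COLUMNS <- c("respondent_id", "test", "session_index", "device_type",
                   "trial_index", "trial_type", "item_id", "block_id",
                   "latency_ms", "correct")

RESPONDENT_COLUMNS <- c("respondent_id", "age", "sex", "race", "education",
                        "income", "weight", "devices_owned")

ENV_COLUMNS <- c("respondent_id", "test", "session_index", "interrupted",
                 "at_home", "watching_tv", "listening_music", "talking",
                 "texting_email", "internet_content", "playing_game")

TESTS        <- c("SGST", "FIGID")
DEVICES      <- c("keyboard", "touchscreen")
TRIAL_TYPES  <- c("normal", "reverse", "nonswitch", "switch")
SGST_INVENTORY <- c(normal = 10L, reverse = 10L, nonswitch = 23L, switch = 6L)
FIGID_N_ITEMS  <- 60L
FIGID_N_BLOCKS <- 6L

session_key <- function(df) {
  paste(df$respondent_id, df$test, df$session_index, sep = "\r")
}

#' Validate a collection of trial records
#'
#' Row-level validation of a trial log: enum membership, positive latencies,
#' population of exactly one of `trial_type` / `item_id` matching the test,
#' and uniqueness of `trial_index` within each (respondent, test, session).
#' Raises a typed `speedcog_integrity_error` on the first violation; never
#' silently coerces a field.
#'
#' @param trials data frame following the trial-log schema.
#' @return The validated data frame, invisibly.
#' @keywords internal
validate_trials <- function(trials) {
  if (!is.data.frame(trials))
    sc_format_error("trial log must be a data frame")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols))
    sc_format_error(paste0("trial log is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (nrow(trials) == 0L) return(invisible(trials))

  req <- c("respondent_id", "test", "session_index", "device_type",
           "trial_index", "latency_ms", "correct")
  for (col in req) {
    bad <- which(is.na(trials[[col]]))
    if (length(bad))
      sc_integrity_error(sprintf("missing %s in trial row %d", col, bad[1L]))
  }
  bad <- which(!(trials$test %in% TESTS))
  if (length(bad))
    sc_integrity_error(sprintf("unknown test '%s' in trial row %d",
                               trials$test[bad[1L]], bad[1L]))
  bad <- which(!(trials$device_type %in% DEVICES))
  if (length(bad))
    sc_integrity_error(sprintf("unknown device_type '%s' in trial row %d",
                               trials$device_type[bad[1L]], bad[1L]))
  bad <- which(trials$latency_ms <= 0)
  if (length(bad))
    sc_integrity_error(sprintf("non-positive latency_ms (%s) in trial row %d",
                               format(trials$latency_ms[bad[1L]]), bad[1L]))
  bad <- which(trials$trial_index < 1 | trials$session_index < 1)
  if (length(bad))
    sc_integrity_error(sprintf("trial_index/session_index below 1 in trial row %d",
                               bad[1L]))

  is_sgst <- trials$test == "SGST"
  bad <- which(is_sgst & (is.na(trials$trial_type) |
                          !(trials$trial_type %in% TRIAL_TYPES)))
  if (length(bad))
    sc_integrity_error(sprintf("SGST trial row %d lacks a valid trial_type", bad[1L]))
  bad <- which(is_sgst & (!is.na(trials$item_id) | !is.na(trials$block_id)))
  if (length(bad))
    sc_integrity_error(sprintf("SGST trial row %d must not carry item_id/block_id", bad[1L]))
  bad <- which(!is_sgst & !is.na(trials$trial_type))
  if (length(bad))
    sc_integrity_error(sprintf("FIGID trial row %d must not carry trial_type", bad[1L]))
  bad <- which(!is_sgst & (is.na(trials$item_id) | trials$item_id < 1 |
                           trials$item_id > FIGID_N_ITEMS))
  if (length(bad))
    sc_integrity_error(sprintf("FIGID trial row %d lacks a valid item_id (1-60)", bad[1L]))
  bad <- which(!is_sgst & (is.na(trials$block_id) | trials$block_id < 1 |
                           trials$block_id > FIGID_N_BLOCKS))
  if (length(bad))
    sc_integrity_error(sprintf("FIGID trial row %d lacks a valid block_id (1-6)", bad[1L]))

  key <- paste(session_key(trials), trials$trial_index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    sc_integrity_error(sprintf(
      "duplicate trial_index %d within (%s, %s, session %s)",
      trials$trial_index[dup[1L]], trials$respondent_id[dup[1L]],
      trials$test[dup[1L]], trials$session_index[dup[1L]]))
  invisible(trials)
}

check_session_inventories <- function(trials) {
  for (idx in split(seq_len(nrow(trials)), session_key(trials))) {
    s <- trials[idx, , drop = FALSE]
    rep <- validate_session(s)
    if (!rep$valid)
      sc_integrity_error(paste0("session (", s$respondent_id[1L], ", ",
                                s$test[1L], ", ", s$session_index[1L],
                                ") fails validation: ",
                                paste(rep$problems, collapse = "; ")))
  }
  invisible(trials)
}

#' Validate one test session
#'
#' Checks a single (respondent, test, session) record set against the fixed
#' trial inventory of its test: 10/10/23/6 trials per SGST trial type, or 60
#' figure items with 10 per block. Also reports duplicate trial indices and
#' flags (without removing) extreme latencies above 30 seconds.
#'
#' @param trials data frame of trial records for exactly one session.
#' @return A list of class `speedcog_validation` with elements `valid`
#'   (logical), `problems` (character vector, empty when valid), `n_trials`,
#'   `counts` (named trial-type or block tally) and `latency_flags`
#'   (trial indices with latency above 30 s; informational only).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_respondents = 1, seed = 1))
#' s <- subset(cohort$trials, test == "SGST" & session_index == 1)
#' validate_session(s)$valid
#' @export
validate_session <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    sc_integrity_error("validate_session needs a non-empty record set")
  if (length(unique(trials$test)) != 1L)
    sc_integrity_error("mixed tests in one session")
  if (length(unique(paste(trials$respondent_id, trials$session_index))) != 1L)
    sc_integrity_error("records from more than one (respondent, session)")

  problems <- character(0)
  test <- trials$test[1L]
  if (anyDuplicated(trials$trial_index))
    problems <- c(problems, "duplicate trial_index")
  if (test == "SGST") {
    counts <- table(factor(trials$trial_type, levels = TRIAL_TYPES))
    for (tt in TRIAL_TYPES)
      if (counts[[tt]] != SGST_INVENTORY[[tt]])
        problems <- c(problems, sprintf("expected %d %s trials, found %d",
                                        SGST_INVENTORY[[tt]], tt, counts[[tt]]))
  } else {
    if (nrow(trials) != FIGID_N_ITEMS)
      problems <- c(problems, sprintf("expected %d item trials, found %d",
                                      FIGID_N_ITEMS, nrow(trials)))
    if (anyDuplicated(trials$item_id))
      problems <- c(problems, "duplicate item_id")
    counts <- table(factor(trials$block_id, levels = 1:FIGID_N_BLOCKS))
    if (any(counts != FIGID_N_ITEMS / FIGID_N_BLOCKS))
      problems <- c(problems, "blocks do not contain 10 items each")
  }
  structure(list(valid = length(problems) == 0L,
                 problems = problems,
                 n_trials = nrow(trials),
                 counts = counts,
                 latency_flags = trials$trial_index[trials$latency_ms > 30000]),
            class = "speedcog_validation")
}

#' @export
print.speedcog_validation <- function(x, ...) {
  cat("Session validation:", if (x$valid) "VALID" else "INVALID", "\n")
  cat("  trials:", x$n_trials, "\n")
  if (length(x$problems)) cat("  problems:", paste(x$problems, collapse = "; "), "\n")
  if (length(x$latency_flags))
    cat("  latencies > 30 s at trial_index:",
        paste(x$latency_flags, collapse = ", "), "\n")
  invisible(x)
}

# -- reading / writing ------------------------------------------------------

coerce_column <- function(x, what, type, path) {
  x[!nzchar(trimws(x))] <- NA_character_
  if (type == "character") return(x)
  if (type == "logical") {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "1")]  <- TRUE
    out[tolower(x) %in% c("false", "0")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
  } else {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (type == "integer") out <- as.integer(round(out))
  }
  if (length(bad))
    sc_parse_error(sprintf("cannot parse %s value '%s' at line %d of %s",
                           what, x[bad[1L]], bad[1L] + 1L, path))
  out
}

TRIAL_COLUMN_TYPES <- c(respondent_id = "character", test = "character",
                        session_index = "integer", device_type = "character",
                        trial_index = "integer", trial_type = "character",
                        item_id = "integer", block_id = "integer",
                        latency_ms = "numeric", correct = "logical")

read_delimited <- function(path, columns, types, format) {
  if (!file.exists(path)) sc_format_error(paste0("no such file: ", path))
  if (format == "jsonl") {
    raw <- readLines(path, warn = FALSE)
    raw <- raw[nzchar(trimws(raw))]
    if (!length(raw))
      return(empty_frame(columns, types))
    rows <- lapply(seq_along(raw), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(raw[i]),
                      error = function(e) sc_parse_error(
                        sprintf("malformed JSON at line %d of %s", i, path)))
      rec[vapply(rec, is.null, logical(1))] <- NA
      rec
    })
    nm <- names(rows[[1L]])
    if (!setequal(nm, columns))
      sc_format_error(paste0("JSON-lines fields do not match schema in ", path))
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[columns], stringsAsFactors = FALSE)))
  } else {
    df <- utils::read.csv(path, colClasses = "character",
                          check.names = FALSE, na.strings = character(0))
    if (!identical(names(df), columns))
      sc_format_error(paste0("header of ", path,
                             " does not match the documented schema"))
  }
  for (col in columns)
    df[[col]] <- coerce_column(as.character(df[[col]]), col, types[[col]], path)
  df
}

empty_frame <- function(columns, types) {
  out <- lapply(types[columns], function(t) vector(t, 0L))
  structure(as.data.frame(out, stringsAsFactors = FALSE), names = columns)
}

#' Read a trial log
#'
#' Reads a CSV or JSON-lines trial log, coerces and validates every field,
#' and preserves administration (file row) order. Malformed values raise a
#' `speedcog_parse_error` naming the offending line; a wrong header raises a
#' `speedcog_format_error`; invariant violations (negative latency,
#' duplicate trial index, ...) raise a `speedcog_integrity_error`.
#'
#' @param path file to read.
#' @param test optional `"SGST"` or `"FIGID"`; when given, the log is
#'   filtered to that test.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @param quiet suppress the record-count message.
#' @return A validated trial-log data frame (see [trial-log-schema]).
#' @seealso [write_trial_log()], [validate_session()]
#' @export
read_trial_log <- function(path, test = NULL, format = c("csv", "jsonl"),
                           quiet = FALSE) {
  format <- match.arg(format)
  df <- read_delimited(path, TRIAL_COLUMNS, TRIAL_COLUMN_TYPES, format)
  if (!is.null(test)) {
    test <- match.arg(test, TESTS)
    df <- df[df$test == test, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_trials(df)
  if (!quiet) message(sprintf("read %d trial record(s) from %s", nrow(df), path))
  df
}

#' Write a trial log
#'
#' Validates the records (including, by default, the fixed per-session trial
#' inventories) and writes them in deterministic column and row order:
#' sorted by respondent, test, session and trial index, so administration
#' order equals file order. The output is re-readable by [read_trial_log()].
#'
#' @param trials trial-log data frame.
#' @param path destination file.
#' @param format `"csv"` (default) or `"jsonl"`.
#' @param check_sessions also enforce per-session trial inventories
#'   (10/10/23/6 for SGST, 60 items for FIGID) before writing.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path, format = c("csv", "jsonl"),
                            check_sessions = TRUE) {
  format <- match.arg(format)
  validate_trials(trials)
  if (check_sessions && nrow(trials)) check_session_inventories(trials)
  ord <- order(trials$respondent_id, trials$test, trials$session_index,
               trials$trial_index)
  out <- trials[ord, TRIAL_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  write_table(out, path, format)
}

write_table <- function(df, path, format = "csv") {
  ok <- tryCatch(suppressWarnings({
    if (format == "jsonl") {
      con <- file(path, "w")
      on.exit(close(con))
      for (i in seq_len(nrow(df)))
        writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                    auto_unbox = TRUE, na = "null",
                                    digits = NA), con)
    } else {
      utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
    }
    TRUE
  }), error = function(e) FALSE)
  if (!ok) sc_abort(paste0("cannot write ", path), "speedcog_io_error")
  invisible(path)
}

RESPONDENT_COLUMN_TYPES <- c(respondent_id = "character", age = "integer",
                             sex = "character", race = "character",
                             education = "character", income = "character",
                             weight = "numeric", devices_owned = "character")

validate_respondents <- function(df) {
  if (!is.data.frame(df) || !identical(names(df), RESPONDENT_COLUMNS))
    sc_format_error("respondent table does not match the documented schema")
  if (!nrow(df)) return(invisible(df))
  if (anyDuplicated(df$respondent_id))
    sc_integrity_error("duplicate respondent_id in respondent table")
  bad <- which(is.na(df$age) | df$age < 18 | df$age > 102)
  if (length(bad))
    sc_integrity_error(sprintf("age out of bounds (18-102) in respondent row %d", bad[1L]))
  bad <- which(is.na(df$weight) | df$weight < 0)
  if (length(bad))
    sc_integrity_error(sprintf("negative or missing weight in respondent row %d", bad[1L]))
  owned <- strsplit(df$devices_owned, "|", fixed = TRUE)
  bad <- which(!vapply(owned, function(d) length(d) >= 1 && all(d %in% DEVICES),
                       logical(1)))
  if (length(bad))
    sc_integrity_error(sprintf("unparseable devices_owned in respondent row %d", bad[1L]))
  invisible(df)
}

#' Read / write respondent profiles
#'
#' Respondent tables carry `respondent_id`, integer `age` (18-102),
#' categorical `sex`, `race`, `education`, `income`, a non-negative sampling
#' `weight`, and `devices_owned` (pipe-separated subset of
#' `keyboard|touchscreen`).
#'
#' @param path file location.
#' @param respondents respondent data frame.
#' @return `read_respondents` returns the validated data frame;
#'   `write_respondents` returns `path` invisibly.
#' @export
read_respondents <- function(path) {
  df <- read_delimited(path, RESPONDENT_COLUMNS, RESPONDENT_COLUMN_TYPES, "csv")
  validate_respondents(df)
  df
}

#' @rdname read_respondents
#' @export
write_respondents <- function(respondents, path) {
  validate_respondents(respondents)
  out <- respondents[order(respondents$respondent_id), RESPONDENT_COLUMNS,
                     drop = FALSE]
  rownames(out) <- NULL
  write_table(out, path)
}

ENV_COLUMN_TYPES <- c(respondent_id = "character", test = "character",
                      session_index = "integer",
                      stats::setNames(rep("integer", 8),
                                      ENV_COLUMNS[4:11]))

validate_environment <- function(df) {
  if (!is.data.frame(df) || !identical(names(df), ENV_COLUMNS))
    sc_format_error("environment table does not match the documented schema")
  if (!nrow(df)) return(invisible(df))
  for (col in ENV_COLUMNS[4:11]) {
    bad <- which(!(df[[col]] %in% c(0L, 1L)))
    if (length(bad))
      sc_integrity_error(sprintf("%s must be 0/1; offending row %d", col, bad[1L]))
  }
  key <- paste(df$respondent_id, df$test, df$session_index)
  if (anyDuplicated(key))
    sc_integrity_error("duplicate (respondent, test, session) in environment table")
  invisible(df)
}

#' Read / write post-test environment reports
#'
#' One row per (respondent, test, session) with binary self-reports:
#' interrupted, at home, and six concurrent-activity distractors (watching
#' TV, music, talking, texting/email, internet content, playing a game).
#'
#' @param path file location.
#' @param environment environment-report data frame.
#' @export
read_environment <- function(path) {
  df <- read_delimited(path, ENV_COLUMNS, ENV_COLUMN_TYPES, "csv")
  validate_environment(df)
  df
}

#' @rdname read_environment
#' @export
write_environment <- function(environment, path) {
  validate_environment(environment)
  out <- environment[order(environment$respondent_id, environment$test,
                           environment$session_index), ENV_COLUMNS, drop = FALSE]
  rownames(out) <- NULL
  write_table(out, path)
}
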