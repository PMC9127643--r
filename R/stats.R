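# Comparison statistics: Cohen d with normal-approximation CI, Pearson and
# partial correlations, Cohen q (Fisher-z difference), OLS distraction
# regression, survey-weighted age-group norms, and the paired within-person
# device comparison.

#' Cohen's d from summary statistics
#'
#' Standardized mean difference `d = (m2 - m1) / s_p` with the pooled SD
#' `s_p^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`, and a
#' normal-approximation 95% CI `d +/- 1.96 * SE` with
#' `SE = sqrt((n1+n2)/(n1*n2) + d^2 / (2 (n1+n2)))`. In the device
#' comparison, group 1 is keyboard and group 2 touch screen, so positive
#' `d` means higher scores on touch screens. Benchmarks: 0.20 small,
#' 0.50 medium, 0.80 large.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1 (keyboard).
#' @param m2,sd2,n2 mean, SD and size of group 2 (touch screen).
#' @param conf_level confidence level of the interval.
#' @return List with `d`, `ci_low`, `ci_high`, `se`.
#' @examples
#' cohen_d(1.04, 0.56, 2820, 1.09, 0.80, 3309)  # d ~ 0.07, CI 0.02-0.12
#' @export
cohen_d <- function(m1, sd1, n1, m2, sd2, n2, conf_level = 0.95) {
  if (any(c(sd1, sd2) <= 0)) sc_domain_error("SDs must be positive")
  if (any(c(n1, n2) < 2)) sc_domain_error("group sizes must be at least 2")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  d <- (m2 - m1) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(d = d, ci_low = d - z * se, ci_high = d + z * se, se = se)
}

#' @rdname cohen_d
#' @param x,y raw samples of groups 1 and 2.
#' @export
cohen_d_from_samples <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  cohen_d(mean(x), stats::sd(x), length(x),
          mean(y), stats::sd(y), length(y), conf_level)
}

#' Pearson correlation with input validation
#'
#' Sample product-moment correlation; raises a typed domain error on
#' unequal lengths, fewer than 3 complete pairs, or degenerate (constant)
#' input rather than returning `NA`.
#'
#' @param x,y numeric vectors.
#' @return Scalar correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) sc_domain_error("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) sc_domain_error("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    sc_domain_error("degenerate (constant) input to pearson_r")
  stats::cor(x, y)
}

#' Cohen's q: difference of Fisher-z transformed correlations
#'
#' `q = atanh(r1) - atanh(r2)`, used to compare the magnitude of the age
#' correlation across device types; by the package's sign convention `r1`
#' is the keyboard-group and `r2` the touch-screen-group correlation.
#' Benchmarks: 0.10 small, 0.30 medium, 0.50 large.
#'
#' @param r1,r2 correlations with absolute value strictly below 1.
#' @return Scalar q.
#' @examples
#' cohen_q(0.38, 0.32)  # ~ 0.07
#' @export
cohen_q <- function(r1, r2) {
  if (any(abs(c(r1, r2)) >= 1))
    sc_domain_error("correlations must lie strictly inside (-1, 1)")
  atanh(r1) - atanh(r2)
}

#' Multivariable OLS regression
#'
#' Ordinary least squares of a score on age plus binary
#' environment/distraction indicators, with conventional standard errors
#' and two-sided p-values from the t distribution on the residual degrees
#' of freedom. Only complete cases are used; a rank-deficient design
#' raises a collinearity error naming the offending column.
#'
#' @param outcome numeric response vector.
#' @param predictors data frame of predictors (same row count as
#'   `outcome`).
#' @return Object of class `speedcog_regression`: data frame
#'   `coefficients` (`term`, `b`, `se`, `p`) and `n` used.
#' @export
ols_regression <- function(outcome, predictors) {
  if (!is.data.frame(predictors) || nrow(predictors) != length(outcome))
    sc_format_error("predictors must be a data frame matching outcome length")
  dat <- cbind(data.frame(.outcome = outcome), predictors)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= ncol(predictors) + 1)
    sc_domain_error("not enough complete cases for the requested model")
  X <- stats::model.matrix(.outcome ~ ., data = dat)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    sc_domain_error(paste0("collinear predictor(s): ",
                           paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm(.outcome ~ ., data = dat)
  cf <- summary(fit)$coefficients
  structure(list(coefficients = data.frame(term = rownames(cf),
                                           b = cf[, 1], se = cf[, 2],
                                           p = cf[, 4], row.names = NULL),
                 n = nrow(dat)),
            class = "speedcog_regression")
}

#' @export
print.speedcog_regression <- function(x, digits = 3, ...) {
  cat("OLS regression (n =", x$n, ")\n")
  cf <- x$coefficients
  cf$b <- signif(cf$b, digits); cf$se <- signif(cf$se, digits)
  cf$p <- signif(cf$p, digits)
  print(cf, row.names = FALSE)
  invisible(x)
}

#' @export
coef.speedcog_regression <- function(object, ...) {
  stats::setNames(object$coefficients$b, object$coefficients$term)
}

#' Partial correlation
#'
#' Correlation between the OLS residuals of `x` and of `y` after
#' regressing each on the control variables. With an empty control set
#' this is the zero-order Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param controls data frame of control variables, or `NULL`.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  if (is.null(controls) || NCOL(controls) == 0L) return(pearson_r(x, y))
  controls <- as.data.frame(controls)
  if (nrow(controls) != length(x) || length(x) != length(y))
    sc_format_error("x, y and controls must have matching lengths")
  ok <- stats::complete.cases(x, y, controls)
  x <- x[ok]; y <- y[ok]; controls <- controls[ok, , drop = FALSE]
  if (length(x) < ncol(controls) + 3)
    sc_domain_error("not enough complete cases for partial correlation")
  X <- stats::model.matrix(~ ., data = controls)
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    sc_domain_error("degenerate residuals in partial correlation")
  stats::cor(rx, ry)
}

#' Survey-weighted age-group norms
#'
#' Weighted mean scores by age group with large-sample 95% CIs. The
#' weighted mean is `sum(w x) / sum(w)`; its standard error uses the
#' weight-squared (linearization-style) form
#' `SE^2 = sum(w^2 (x - xbar_w)^2) / (sum w)^2`. Groups of size 1 report
#' the mean with an unavailable (NA) interval.
#'
#' @param scores numeric score vector.
#' @param weights non-negative sampling weights.
#' @param age ages in years.
#' @param breaks increasing age-group edges (default the six panel groups
#'   18-34, 35-44, 45-54, 55-64, 65-74, >=75).
#' @param labels group labels.
#' @param conf_level confidence level.
#' @return Data frame of class `norm_table`: `age_group`, `weighted_mean`,
#'   `ci_low`, `ci_high`, `n_unweighted`, `sum_weights`.
#' @export
weighted_group_norms <- function(scores, weights, age,
                                 breaks = AGE_BAND_BREAKS,
                                 labels = AGE_BAND_LABELS,
                                 conf_level = 0.95) {
  if (length(scores) != length(weights) || length(scores) != length(age))
    sc_format_error("scores, weights and age must have equal length")
  if (any(weights < 0, na.rm = TRUE))
    sc_domain_error("weights must be non-negative")
  if (any(diff(breaks) <= 0)) sc_config_error("age-group edges must increase")
  ok <- stats::complete.cases(scores, weights, age)
  scores <- scores[ok]; weights <- weights[ok]; age <- age[ok]
  grp <- cut(age, breaks, labels = labels, right = FALSE, include.lowest = TRUE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(levels(grp), function(g) {
    idx <- which(grp == g)
    if (!length(idx))
      return(data.frame(age_group = g, weighted_mean = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_unweighted = 0L, sum_weights = 0))
    w <- weights[idx]; x <- scores[idx]
    if (sum(w) <= 0)
      sc_domain_error(paste0("all-zero weights in age group ", g))
    wm <- sum(w * x) / sum(w)
    if (length(idx) < 2) {
      ci <- c(NA_real_, NA_real_)
    } else {
      se <- sqrt(sum(w^2 * (x - wm)^2) / sum(w)^2)
      ci <- wm + c(-1, 1) * z * se
    }
    data.frame(age_group = g, weighted_mean = wm, ci_low = ci[1],
               ci_high = ci[2], n_unweighted = length(idx),
               sum_weights = sum(w))
  })
  structure(do.call(rbind, rows), class = c("norm_table", "data.frame"))
}

#' @export
print.norm_table <- function(x, digits = 3, ...) {
  cat("Weighted age-group norms\n")
  y <- as.data.frame(x)
  for (col in c("weighted_mean", "ci_low", "ci_high", "sum_weights"))
    y[[col]] <- signif(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
plot.norm_table <- function(x, ylab = "weighted mean score", ...) {
  n <- nrow(x)
  plot(seq_len(n), x$weighted_mean, xaxt = "n", xlab = "age group",
       ylab = ylab, pch = 19,
       ylim = range(c(x$ci_low, x$ci_high, x$weighted_mean), na.rm = TRUE), ...)
  graphics::axis(1, at = seq_len(n), labels = x$age_group)
  graphics::segments(seq_len(n), x$ci_low, seq_len(n), x$ci_high)
  invisible(x)
}

#' Within-person device comparison
#'
#' Paired comparison over respondents who completed the test on both
#' device types: mean score difference (touch screen minus keyboard),
#' paired standardized difference (mean difference divided by the SD of
#' the differences), and the cross-device Pearson correlation.
#' Respondents missing either device are excluded (count reported);
#' duplicate device entries per respondent raise an integrity error.
#'
#' @param scores data frame with columns `respondent_id`, `device_type`
#'   and `value` (one score per respondent per device).
#' @return List: `mean_diff`, `paired_d` (`NA` with a flag when the
#'   differences are constant at 0), `r_cross_device`, `n_pairs`,
#'   `n_excluded`.
#' @export
within_person_device_comparison <- function(scores) {
  need <- c("respondent_id", "device_type", "value")
  if (!is.data.frame(scores) || !all(need %in% names(scores)))
    sc_format_error("scores must carry respondent_id, device_type, value")
  if (anyDuplicated(paste(scores$respondent_id, scores$device_type)))
    sc_integrity_error("duplicate device entries for a respondent")
  kb <- scores[scores$device_type == "keyboard", c("respondent_id", "value")]
  ts <- scores[scores$device_type == "touchscreen", c("respondent_id", "value")]
  m <- merge(kb, ts, by = "respondent_id", suffixes = c("_kb", "_ts"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n_excluded <- length(unique(scores$respondent_id)) - nrow(m)
  if (nrow(m) < 3) sc_domain_error("need at least 3 complete pairs")
  diffs <- m$value_ts - m$value_kb
  sd_d <- stats::sd(diffs)
  list(mean_diff = mean(diffs),
       paired_d = if (sd_d == 0) NA_real_ else mean(diffs) / sd_d,
       paired_d_defined = sd_d > 0,
       r_cross_device = pearson_r(m$value_kb, m$value_ts),
       n_pairs = nrow(m), n_excluded = n_excluded)
}

#' Device-type effect-size table
#'
#' For each score column, compares first-session keyboard vs touch-screen
#' respondents: group means/SDs/ns, Cohen d (touch minus keyboard) with
#' 95% CI, per-group Pearson correlations with age, and Cohen q for the
#' difference in age correlations (keyboard minus touch).
#'
#' @param scores score data frame (one row per respondent; already
#'   filtered to scored sessions) with a `device_type` column.
#' @param respondents respondent table supplying `age`.
#' @param score_cols character vector of score column names.
#' @return Data frame of class `effect_table`, one row per score.
#' @export
device_comparison <- function(scores, respondents, score_cols) {
  dat <- merge(scores, respondents[, c("respondent_id", "age")],
               by = "respondent_id")
  rows <- lapply(score_cols, function(col) {
    kb <- dat[dat$device_type == "keyboard", ]
    ts <- dat[dat$device_type == "touchscreen", ]
    d <- cohen_d_from_samples(kb[[col]], ts[[col]])
    r_kb <- pearson_r(kb$age, kb[[col]])
    r_ts <- pearson_r(ts$age, ts[[col]])
    data.frame(score_name = col,
               mean_keyboard = mean(kb[[col]], na.rm = TRUE),
               sd_keyboard = stats::sd(kb[[col]], na.rm = TRUE),
               n_keyboard = sum(!is.na(kb[[col]])),
               mean_touch = mean(ts[[col]], na.rm = TRUE),
               sd_touch = stats::sd(ts[[col]], na.rm = TRUE),
               n_touch = sum(!is.na(ts[[col]])),
               d = d$d, d_ci_low = d$ci_low, d_ci_high = d$ci_high,
               r_keyboard = r_kb, r_touch = r_ts,
               q = cohen_q(r_kb, r_ts))
  })
  structure(do.call(rbind, rows), class = c("effect_table", "data.frame"))
}

#' @export
print.effect_table <- function(x, digits = 2, ...) {
  cat("Device-type comparison (touch screen minus keyboard)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
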