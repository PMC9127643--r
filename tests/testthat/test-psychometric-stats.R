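test_that("cohen_d matches hand-computed pooled-SD examples", {
  # groups {1,2,3} and {3,4,5}: means 2 and 4, both SDs 1, pooled SD 1
  res <- cohen_d_from_samples(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$d, 2.0)

  same <- cohen_d(1.5, 0.5, 100, 1.5, 0.5, 100)
  expect_equal(same$d, 0)
  expect_equal(same$ci_low, -same$ci_high)

  # published worked example: keyboard (1.04, 0.56, 2820) vs touch
  # (1.09, 0.80, 3309) gives d = 0.07 with CI 0.02 to 0.12
  tab <- cohen_d(1.04, 0.56, 2820, 1.09, 0.80, 3309)
  expect_equal(round(tab$d, 2), 0.07)
  expect_equal(round(c(tab$ci_low, tab$ci_high), 2), c(0.02, 0.12))
})

test_that("cohen_d is antisymmetric, scale invariant and validates input", {
  a <- cohen_d(1.0, 0.4, 50, 1.3, 0.6, 70)
  b <- cohen_d(1.3, 0.6, 70, 1.0, 0.4, 50)
  expect_equal(a$d, -b$d)
  scaled <- cohen_d(3 * 1.0, 3 * 0.4, 50, 3 * 1.3, 3 * 0.6, 70)
  expect_equal(scaled$d, a$d)
  expect_error(cohen_d(1, 0, 50, 2, 1, 50), class = "speedcog_domain_error")
  expect_error(cohen_d(1, 1, 1, 2, 1, 50), class = "speedcog_domain_error")
})

test_that("pearson_r matches hand computation and rejects degenerate input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:5, rep(2, 5)), class = "speedcog_domain_error")
  expect_error(pearson_r(1:4, 1:5), class = "speedcog_domain_error")
  expect_error(pearson_r(1:2, 2:1), class = "speedcog_domain_error")
})

test_that("cohen_q is the Fisher-z difference with its symmetries", {
  expect_equal(cohen_q(0.38, 0.32), atanh(0.38) - atanh(0.32))
  expect_equal(cohen_q(0.5, 0.5), 0)
  for (r in c(-0.9, -0.3, 0, 0.4, 0.85))
    expect_equal(cohen_q(r, 0.1), -cohen_q(0.1, r))
  expect_error(cohen_q(1, 0.5), class = "speedcog_domain_error")
})

test_that("OLS coefficients equal the normal-equations solution", {
  set.seed(30)
  n <- 50
  X <- data.frame(age = runif(n, 18, 101),
                  tv = rbinom(n, 1, 0.3),
                  music = rbinom(n, 1, 0.2))
  y <- 0.5 + 0.01 * X$age + 0.2 * X$tv - 0.1 * X$music + rnorm(n, 0, 0.3)
  fit <- ols_regression(y, X)
  M <- cbind(1, as.matrix(X))
  beta <- solve(t(M) %*% M) %*% t(M) %*% y      # brute-force normal equations
  expect_equal(unname(coef(fit)), as.vector(beta), tolerance = 1e-10)
  # conventional SEs from the residual variance
  res <- y - M %*% beta
  s2 <- sum(res^2) / (n - ncol(M))
  expect_equal(unname(fit$coefficients$se),
               unname(sqrt(diag(s2 * solve(t(M) %*% M)))), tolerance = 1e-10)

  # intercept-only model recovers the sample mean
  m0 <- ols_regression(y, data.frame(row.names = seq_len(n)))
  expect_equal(unname(coef(m0)), mean(y))

  # noiseless outcome is recovered exactly (summary warns about the
  # perfect fit, which is the point here)
  fit2 <- suppressWarnings(ols_regression(2 * X$age - 1, X["age"]))
  expect_equal(unname(coef(fit2)), c(-1, 2))

  # collinearity is reported with the offending column
  X$age2 <- 2 * X$age
  err <- expect_error(ols_regression(y, X), class = "speedcog_domain_error")
  expect_match(conditionMessage(err), "age2")
})

test_that("partial correlation removes only what the controls explain", {
  set.seed(31)
  n <- 10000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  r0 <- pearson_r(x, y)
  expect_equal(partial_correlation(x, y, NULL), r0)

  # controls independent of both variables leave r essentially unchanged
  ctl <- data.frame(a = rbinom(n, 1, 0.2), b = rnorm(n))
  se_r <- (1 - r0^2) / sqrt(n)
  expect_lt(abs(partial_correlation(x, y, ctl) - r0), 3 * se_r)

  # y an exact function of the control: only numeric noise is left, whose
  # correlation with anything is O(1/sqrt(n))
  z <- rnorm(n)
  expect_lt(abs(partial_correlation(x, 3 * z + 1, data.frame(z = z))), 0.05)
})

test_that("weighted norms match hand computation and handle edge groups", {
  # scores {40, 44} with weights {1, 3}: (40 + 132) / 4 = 43
  nr <- weighted_group_norms(c(40, 44), c(1, 3), c(20, 25),
                             breaks = c(18, 35), labels = "18-34")
  expect_equal(nr$weighted_mean, 43.0)

  single <- weighted_group_norms(5, 2, 40, breaks = c(35, 45),
                                 labels = "35-44")
  expect_equal(single$weighted_mean, 5)
  expect_true(is.na(single$ci_low))

  expect_error(weighted_group_norms(c(1, 2), c(0, 0), c(20, 21),
                                    breaks = c(18, 35), labels = "18-34"),
               class = "speedcog_domain_error")
  expect_error(weighted_group_norms(1:3, c(1, 1, -1), c(20, 30, 40)),
               class = "speedcog_domain_error")
})

test_that("unit weights reproduce the unweighted mean and large-sample CI", {
  set.seed(32)
  x <- rnorm(200, 50, 10)
  age <- sample(18:101, 200, replace = TRUE)
  nr <- weighted_group_norms(x, rep(1, 200), age)
  grp <- cut(age, c(18, 35, 45, 55, 65, 75, Inf), right = FALSE,
             include.lowest = TRUE)
  for (g in seq_along(levels(grp))) {
    xi <- x[as.integer(grp) == g]
    if (length(xi) < 2) next
    m <- mean(xi)
    se <- sqrt(sum((xi - m)^2)) / length(xi)   # large-sample (1/n) variance
    expect_equal(nr$weighted_mean[g], m, tolerance = 1e-12)
    expect_equal(nr$ci_low[g], m - qnorm(0.975) * se, tolerance = 1e-12)
    expect_equal(nr$ci_high[g], m + qnorm(0.975) * se, tolerance = 1e-12)
  }
})

test_that("within-person comparison handles offsets, ties and duplicates", {
  ids <- sprintf("P%02d", 1:20)
  set.seed(33)
  base <- rnorm(20, 1, 0.2)
  paired <- data.frame(respondent_id = rep(ids, 2),
                       device_type = rep(c("keyboard", "touchscreen"),
                                         each = 20),
                       value = c(base, base + 0.1))
  res <- within_person_device_comparison(paired)
  expect_equal(res$mean_diff, 0.1)
  expect_equal(res$r_cross_device, 1)
  expect_equal(res$n_pairs, 20L)

  tied <- paired; tied$value <- rep(base, 2)
  tres <- within_person_device_comparison(tied)
  expect_equal(tres$mean_diff, 0)
  expect_true(is.na(tres$paired_d))
  expect_false(tres$paired_d_defined)

  dup <- rbind(paired, paired[1, ])
  expect_error(within_person_device_comparison(dup),
               class = "speedcog_integrity_error")

  # respondents missing one device are excluded and counted
  missing <- paired[-1, ]
  expect_equal(within_person_device_comparison(missing)$n_excluded, 1L)
})
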