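make_outcomes <- function(values, masses = NULL, subject = "S1") {
  if (is.null(masses)) masses <- cbind(thigh = 0, shank = 0, foot = 0)
  data.frame(subject_id = subject, condition = paste0("c", seq_along(values)),
             thigh = masses[, 1], shank = masses[, 2], foot = masses[, 3],
             outcome = "early_peak", value = values)
}

test_that("percent change uses the mean of the two unloaded trials", {
  tab <- make_outcomes(c(2.9, 3.1, 3.3),
                       rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 2)))
  pc <- percent_change(tab)
  expect_equal(pc$value[3], 10)        # mean baseline 3.0, condition 3.3
  expect_equal(pc$value[1:2], c(-10 / 3, 10 / 3), tolerance = 1e-12)
  # first-only rule
  pc1 <- percent_change(tab, baseline_rule = "first")
  expect_equal(pc1$value[3], 100 * (3.3 - 2.9) / 2.9)
  # condition equal to baseline gives zero
  tab2 <- make_outcomes(c(3, 3.3), rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_equal(percent_change(tab2)$value, c(0, 10))
  # missing baseline names the subject
  tab3 <- make_outcomes(3.3, cbind(1, 0, 0), subject = "S9")
  expect_error(percent_change(tab3), "S9")
})

test_that("through-origin regression is exact on noiseless linear outcomes", {
  sc <- study_conditions()
  X <- sc[, c("thigh", "shank", "foot")]
  y <- 1.5 * X$thigh + 2.1 * X$shank + 5.9 * X$foot
  fit <- fit_origin_regression(y, X)
  expect_equal(unname(coef(fit)), c(1.5, 2.1, 5.9), tolerance = 1e-10)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-10)
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
})

test_that("through-origin regression matches the normal-equations oracle", {
  for (k in 1:100) {
    set.seed(k)
    n <- sample(6:30, 1)
    X <- data.frame(thigh = runif(n, 0, 4), shank = runif(n, 0, 3),
                    foot = runif(n, 0, 2))
    y <- rnorm(n)
    fit <- fit_origin_regression(y, X)
    M <- as.matrix(X)
    beta <- solve(crossprod(M), crossprod(M, y))
    expect_lt(max(abs(coef(fit) - drop(beta))), 1e-8)
  }
  bad <- data.frame(thigh = 1:5, shank = 2 * (1:5), foot = 3 * (1:5))
  expect_error(fit_origin_regression(rnorm(5), bad), "rank")
})

test_that("coefficient-wise interval propagation matches the bound construction", {
  sc <- study_conditions()
  X <- sc[, c("thigh", "shank", "foot")]
  y <- 1.5 * X$thigh + 2.1 * X$shank + 5.9 * X$foot
  fit <- fit_origin_regression(y, X)
  pred0 <- predict_with_ci(fit, data.frame(thigh = 0, shank = 0, foot = 0))
  expect_equal(unlist(pred0), c(point = 0, lower = 0, upper = 0))
  pred <- predict_with_ci(fit, data.frame(thigh = 4, shank = 3, foot = 2))
  expect_equal(pred$point, 1.5 * 4 + 2.1 * 3 + 5.9 * 2, tolerance = 1e-8)
  expect_equal(pred$point, 24.1, tolerance = 1e-8)
  expect_true(pred$lower <= pred$point && pred$point <= pred$upper)
  expect_error(predict_with_ci(fit, data.frame(thigh = -1, shank = 0, foot = 0)),
               "nonnegative")
})

test_that("the mixed model collapses to OLS without subject structure", {
  # balanced design (every subject sees the same conditions): generalized
  # least squares with a compound-symmetric error equals OLS exactly, so
  # the fixed effects must match whatever the variance split
  set.seed(1)
  base <- data.frame(thigh = c(0, 2, 4, 0, 0), shank = c(0, 0, 0, 1.5, 3),
                     foot = c(0, 1, 2, 0, 1))
  X <- base[rep(1:5, times = 8), ]
  ids <- rep(paste0("S", 1:8), each = 5)
  y <- 1.5 * X$thigh + 0.9 * X$foot + rnorm(40, 0, 0.5)
  lmm <- fit_random_intercept_lmm(y, X, ids)
  ols <- coef(lm(y ~ 0 + thigh + shank + foot, data = cbind(y = y, X)))
  expect_lt(max(abs(lmm$fixed$estimate - ols)), 1e-6)
})

test_that("the mixed model recovers known variance components", {
  set.seed(7)
  est_b <- est_e <- numeric(200)
  for (r in 1:200) {
    ids <- rep(1:10, each = 6)
    b <- rnorm(10, 0, 2)[ids]
    X <- data.frame(x = rep(seq(0, 5, length.out = 6), 10))
    y <- 1.2 * X$x + b + rnorm(60, 0, 1)
    f <- fit_random_intercept_lmm(y, X, ids, intercept = TRUE)
    est_b[r] <- f$var_subject
    est_e[r] <- f$var_resid
  }
  expect_equal(median(est_b), 4, tolerance = 0.15)
  expect_equal(median(est_e), 1, tolerance = 0.15)
})

test_that("a constant shift of one subject moves its intercept, not the slopes", {
  set.seed(3)
  ids <- rep(1:6, each = 8)
  X <- data.frame(x = rep(seq(0, 7, length.out = 8), 6))
  y <- 2 * X$x + rnorm(48, 0, 0.3)
  f1 <- fit_random_intercept_lmm(y, X, ids, intercept = TRUE)
  y2 <- y + 5 * (ids == 3)
  f2 <- fit_random_intercept_lmm(y2, X, ids, intercept = TRUE)
  expect_equal(f2$fixed$estimate[2], f1$fixed$estimate[2], tolerance = 0.02)
})

test_that("minimum detectable R-squared is monotone and verified by simulation", {
  r2 <- min_detectable_r2(60, 3, 0.05, 0.8)
  expect_lt(min_detectable_r2(120, 3, 0.05, 0.8), r2)
  expect_gt(min_detectable_r2(60, 3, 0.05, 0.9), r2)
  expect_error(min_detectable_r2(4, 3), "n > p")
  # Monte-Carlo check of the power function at the returned effect size:
  # draw the F statistic from its defining chi-square ratio under the
  # noncentrality convention lambda = f2 * (n - p - 1)
  set.seed(42)
  n <- 60; p <- 3; df2 <- n - p - 1
  lam <- r2 / (1 - r2) * df2
  fstat <- (rchisq(10000, p, ncp = lam) / p) / (rchisq(10000, df2) / df2)
  rej <- mean(fstat > qf(0.95, p, df2))
  expect_equal(rej, 0.80, tolerance = 0.0125)
})

test_that("temporal outcomes report stride metrics and respond to normalization", {
  tr <- generate_stride(fix_subject(), study_conditions()[1, ],
                        noise_free_response(), seed = 6, n_strides = 2)
  out <- temporal_outcomes(tr)
  expect_setequal(unique(out$outcome),
                  c("stride_time", "duty_factor", "peak_knee_flexion_angle",
                    "peak_knee_extension_angle", "peak_knee_flexion_moment",
                    "peak_knee_extension_moment"))
  expect_equal(out$value[out$outcome == "stride_time"], 1.10,
               tolerance = 2 / 1250)
  expect_equal(out$value[out$outcome == "duty_factor"], 0.59, tolerance = 0.02)

  # worn-mass normalization removes a pure mass-proportional effect exactly
  worn <- c(1, 2, 4)
  vals <- 3.0 * worn
  norm <- vals / worn
  expect_equal(norm, rep(3.0, 3))
})
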