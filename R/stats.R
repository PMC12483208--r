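# Statistical layer: percent-change outcomes, through-origin multiple
# regression of outcome change on added segment mass, random-intercept
# mixed models, coefficient-wise confidence-interval propagation for the
# additivity (interaction) check, and the a priori noncentral-F power
# analysis.

#' Percent change from each subject's unloaded baseline
#'
#' Converts outcome values to percent change relative to the subject's
#' no-mass baseline, taken as the mean of the initial and final unloaded
#' trials (configurable to first-only). Baseline rows are retained with
#' value 0.
#'
#' @param outcomes data frame with columns `subject_id`, `condition`,
#'   `thigh`, `shank`, `foot`, `outcome`, `value`
#' @param baseline_rule `"mean"` (default) or `"first"`
#' @return the table with `value` replaced by percent change
#' @export
percent_change <- function(outcomes, baseline_rule = c("mean", "first")) {
  baseline_rule <- match.arg(baseline_rule)
  out <- outcomes
  is_base <- outcomes$thigh + outcomes$shank + outcomes$foot == 0
  for (sid in unique(outcomes$subject_id)) {
    for (oc in unique(outcomes$outcome[outcomes$subject_id == sid])) {
      sel <- outcomes$subject_id == sid & outcomes$outcome == oc
      bvals <- outcomes$value[sel & is_base]
      if (length(bvals) == 0)
        stop("missing no-mass baseline for subject ", sid, ", outcome ", oc)
      b <- if (baseline_rule == "mean") mean(bvals) else bvals[1]
      out$value[sel] <- 100 * (outcomes$value[sel] - b) / b
    }
  }
  out
}

#' Through-origin regression of percent change on added segment masses
#'
#' Fits `y = a_thigh*m_thigh + a_shank*m_shank + a_foot*m_foot` (no
#' intercept) by least squares, with 95% confidence intervals and p-values
#' from the t-distribution on `n - 3` degrees of freedom, and Pearson's r
#' between observed and model-predicted outcomes.
#'
#' @param y percent-change outcomes
#' @param X data frame or matrix with columns `thigh`, `shank`, `foot`
#'   (% BW per leg)
#' @param level confidence level (default 0.95)
#' @return object of class `origin_fit`
#' @export
fit_origin_regression <- function(y, X, level = 0.95) {
  X <- as.data.frame(X)[, c("thigh", "shank", "foot")]
  if (length(y) < 4) stop("need at least 4 observations")
  if (qr(as.matrix(X))$rank < ncol(X))
    stop("rank-deficient design: the three mass predictors are collinear")
  dat <- cbind(y = y, X)
  fit <- stats::lm(y ~ 0 + thigh + shank + foot, data = dat)
  # noiseless recovery tests fit exactly; silence the perfect-fit warning
  ci <- suppressWarnings(stats::confint(fit, level = level))
  sm <- suppressWarnings(summary(fit))
  pred <- stats::fitted(fit)
  structure(list(
    coefficients = stats::coef(fit),
    ci = ci,
    p_values = sm$coefficients[, "Pr(>|t|)"],
    pearson_r = stats::cor(y, pred),
    n = length(y), level = level, lm = fit
  ), class = "origin_fit")
}

#' @export
coef.origin_fit <- function(object, ...) object$coefficients

#' @export
confint.origin_fit <- function(object, ...) object$ci

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("Through-origin regression (n = %d): %%change = a.m_thigh + a.m_shank + a.m_foot\n", x$n))
  tab <- cbind(coefficient = x$coefficients, x$ci, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("Pearson r (observed vs predicted) = %.2f\n", x$pearson_r))
  invisible(x)
}

#' @export
summary.origin_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Predict percent change with coefficient-wise interval propagation
#'
#' Point prediction `sum(a_i * m_i)` with lower/upper bounds formed from the
#' coefficient confidence-interval endpoints multiplied by the (nonnegative)
#' masses - the bound construction used for the additivity check on the
#' all-segment loading conditions, not a proper prediction interval.
#'
#' @param fit an `origin_fit`
#' @param new_masses data frame/matrix with `thigh`, `shank`, `foot` columns
#' @return data frame with `point`, `lower`, `upper` (percent)
#' @export
predict_with_ci <- function(fit, new_masses) {
  M <- as.matrix(as.data.frame(new_masses)[, c("thigh", "shank", "foot")])
  if (any(M < 0)) stop("masses must be nonnegative")
  data.frame(point = drop(M %*% fit$coefficients),
             lower = drop(M %*% fit$ci[, 1]),
             upper = drop(M %*% fit$ci[, 2]))
}

#' @export
predict.origin_fit <- function(object, newdata, ...) predict_with_ci(object, newdata)

#' @export
residuals.origin_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
simulate.origin_fit <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$lm, nsim = nsim, seed = seed, ...)

#' Random-intercept linear mixed model
#'
#' Fits `y = X beta + b_subject + e` with `b ~ N(0, sigma_b^2)` by restricted
#' maximum likelihood, with Wald p-values for the fixed effects.
#'
#' @param y outcome vector
#' @param X fixed-effects design (data frame/matrix; no intercept added)
#' @param subject_ids grouping factor
#' @param intercept add a fixed intercept column (default FALSE)
#' @return object of class `lmm_fit`: `fixed` (estimate, se, z, p),
#'   `var_subject`, `var_resid`, `logLik`, and the underlying `lmer` fit
#' @export
fit_random_intercept_lmm <- function(y, X, subject_ids, intercept = FALSE) {
  X <- as.data.frame(X)
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  dat <- cbind(y = y, X, .subject = factor(subject_ids))
  rhs <- paste(c(if (intercept) "1" else "0", colnames(X)), collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs, "+ (1 | .subject)"))
  fit <- lme4::lmer(form, data = dat, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- beta / se
  vc <- lme4::VarCorr(fit)
  structure(list(
    fixed = data.frame(estimate = beta, se = se, z = z,
                       p = 2 * stats::pnorm(-abs(z))),
    var_subject = as.numeric(vc$.subject[1, 1]),
    var_resid = attr(vc, "sc")^2,
    logLik = as.numeric(stats::logLik(fit)),
    lmer = fit
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Random-intercept mixed model (REML)\n")
  print(round(x$fixed, 4))
  cat(sprintf("  subject variance %.4g, residual variance %.4g\n",
              x$var_subject, x$var_resid))
  invisible(x)
}

#' Minimum detectable R-squared of a p-predictor linear model
#'
#' Smallest population R-squared for which the overall F-test of a linear
#' model with `p` predictors and `n` independent observations attains the
#' requested power at level `alpha`. Uses the noncentral-F power function
#' with Cohen's effect-size convention `lambda = f2 * nu_error`
#' (`f2 = R2/(1-R2)`, error degrees of freedom `n - p - 1`), solved by
#' bisection to 1e-6.
#'
#' @param n number of observations (> p + 1)
#' @param p number of predictors
#' @param alpha significance level
#' @param power requested power
#' @return minimum detectable R-squared
#' @export
min_detectable_r2 <- function(n, p, alpha = 0.05, power = 0.8) {
  if (n <= p + 1) stop("need n > p + 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  df2 <- n - p - 1
  fcrit <- stats::qf(1 - alpha, p, df2)
  pow <- function(R2) {
    f2 <- R2 / (1 - R2)
    stats::pf(fcrit, p, df2, ncp = f2 * df2, lower.tail = FALSE)
  }
  if (pow(0.999999) < power) stop("requested power unattainable at this n")
  lo <- 0; hi <- 0.999999
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (pow(mid) < power) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Temporal and knee kinematic/kinetic outcomes of a trial
#'
#' Stride time and duty factor from the force-plate segmentation, and peak
#' knee angles/moments over the first stance: peak knee flexion angle in
#' early stance, peak extension (minimum flexion) angle in late stance, and
#' peak knee extension/flexion moments. Optional covariate normalization by
#' stride time and/or total worn mass.
#'
#' @param trial a `gait_trial`
#' @param segmentation a `stance_segmentation` (default: detected from the
#'   trial's vertical GRF)
#' @param normalize one of `"none"`, `"stride_time"`, `"worn_mass"`
#' @return data frame of outcome rows (`subject_id`, `condition`, `thigh`,
#'   `shank`, `foot`, `outcome`, `value`, `unit`)
#' @export
temporal_outcomes <- function(trial, segmentation = NULL,
                              normalize = c("none", "stride_time", "worn_mass")) {
  normalize <- match.arg(normalize)
  if (is.null(segmentation)) {
    segmentation <- detect_stance(pmax(trial$grf_hi$fy, 0), trial$fs_grf)
  }
  if (nrow(segmentation$events) < 2) stop("need at least 2 heel strikes")
  ev <- trial$events[1, ]
  i <- trial$time >= ev$heel_strike & trial$time <= ev$toe_off
  pct <- (trial$time[i] - ev$heel_strike) / (ev$toe_off - ev$heel_strike) * 100
  knee <- trial$q[i, "knee_r"]
  model <- apply_added_mass(
    scale_muscle_strength(build_default_model(trial$subject)), trial$condition)
  id <- inverse_dynamics(model, list(time = trial$time, q = trial$q), trial$grf)
  km <- id$moments[i, "knee_r"]
  early <- pct <= 50; late <- pct > 40
  rows <- data.frame(
    outcome = c("stride_time", "duty_factor", "peak_knee_flexion_angle",
                "peak_knee_extension_angle", "peak_knee_flexion_moment",
                "peak_knee_extension_moment"),
    value = c(segmentation$stride_time, segmentation$duty_factor,
              max(knee[early]), min(knee[late]), max(km), -min(km)),
    unit = c("s", "ratio", "rad", "rad", "N.m", "N.m"),
    stringsAsFactors = FALSE
  )
  if (normalize == "stride_time") {
    sel <- !(rows$outcome %in% c("stride_time", "duty_factor"))
    rows$value[sel] <- rows$value[sel] / segmentation$stride_time
    rows$unit[sel] <- paste0(rows$unit[sel], "/s")
  } else if (normalize == "worn_mass") {
    worn <- 2 * (trial$condition$thigh + trial$condition$shank + trial$condition$foot) / 100 *
      trial$subject$mass
    if (worn > 0) {
      rows$value <- rows$value / worn
      rows$unit <- paste0(rows$unit, "/kg")
    }
  }
  cbind(data.frame(subject_id = trial$subject$subject_id,
                   condition = trial$condition$name,
                   thigh = trial$condition$thigh, shank = trial$condition$shank,
                   foot = trial$condition$foot, stringsAsFactors = FALSE),
        rows)
}
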