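test_that("cohort sampling is seeded, bounded and centered", {
  c1 <- generate_cohort(10, seed = 1)
  c2 <- generate_cohort(10, seed = 1)
  expect_identical(c1, c2)
  expect_true(all(c1$mass >= 57 & c1$mass <= 81))
  expect_true(all(c1$height >= 1.63 & c1$height <= 1.78))
  big <- generate_cohort(10000, seed = 2)
  expect_equal(mean(big$mass), 69, tolerance = 0.5 / 69)
  expect_error(generate_cohort(0, 1), "at least 1")
})

test_that("trial generation is byte-identical for a fixed seed", {
  s <- fix_subject()
  resp <- noise_free_response()
  t1 <- generate_stride(s, study_conditions()[6, ], resp, seed = 11, n_strides = 1)
  t2 <- generate_stride(s, study_conditions()[6, ], resp, seed = 11, n_strides = 1)
  expect_identical(t1$q, t2$q)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$truth$peaks, t2$truth$peaks)
})

test_that("stride-time effects follow the response model exactly", {
  s <- fix_subject()
  resp <- noise_free_response()
  tr0 <- fix_trial()
  tr_foot <- generate_stride(s, loading_condition("f1", foot = 1), resp,
                             seed = 3, n_strides = 1,
                             baseline = tr0$truth$baseline)
  expect_equal(tr_foot$truth$stride_time / tr0$truth$stride_time, 1.025)
  # detected stride time agrees with the generator within one sample
  tr2 <- generate_stride(s, study_conditions()[1, ], resp, seed = 4, n_strides = 3)
  expect_equal(tr2$stride_time, tr2$truth$stride_time, tolerance = 1 / 1250 / 1.1)
  # detected duty factor is consistent with the detected events to one
  # sample, and near the template's stance fraction (threshold crossings
  # shave the ramps)
  ev <- tr2$events
  duty_ev <- mean((ev$toe_off - ev$heel_strike)[1:2]) / tr2$stride_time
  expect_equal(tr2$duty_factor, duty_ev, tolerance = 1e-6)
  expect_equal(tr2$duty_factor, tr2$truth$duty_factor, tolerance = 0.04)
})

test_that("the unloaded condition reproduces the baseline targets", {
  tr <- fix_trial()
  base_pk <- extract_peaks(data.frame(pct = tr$truth$baseline$pct,
                                      total = tr$truth$baseline$total))
  expect_equal(tr$truth$peaks_target$early, base_pk$early)
  expect_equal(tr$truth$peaks_target$late, base_pk$late)
  expect_equal(unname(tr$truth$delta_injected), c(0, 0))
})

test_that("synthetic EMG encodes the submaximal inflation and the delay", {
  s <- fix_subject()
  resp <- noise_free_response()
  submax <- setNames(rep(1, 9), default_model_config()$emg$measured)
  tr <- generate_stride(s, study_conditions()[1, ], resp, seed = 5,
                        n_strides = 1, submax = submax)
  # with submax = 1 and no noise, each channel is the advanced excitation
  ch <- tr$emg$soleus
  shifted <- kneeload:::interp1(tr$time, tr$truth$excitations[, "soleus"],
                                tr$emg$time + 66 / 1250)
  expect_equal(ch, shifted, tolerance = 1e-9)
  expect_true(all(vapply(default_model_config()$emg$measured,
                         function(nm) max(tr$emg[[nm]]) <= 1, logical(1))))
  expect_error(emulate_emg(tr$truth$excitations, tr$time,
                           setNames(rep(3, 9), names(submax))),
               "submax")
  # implied recoverable scale factor is the reciprocal of the inflation
  tr2 <- fix_trial()
  expect_true(all(tr2$truth$scale_factors >= 0.5 & tr2$truth$scale_factors <= 1))
})

test_that("inverse dynamics reproduces the generating net joint moments", {
  tr <- fix_trial()
  model <- apply_added_mass(fix_model(), tr$condition)
  id <- inverse_dynamics(model, list(time = tr$time, q = tr$q), tr$grf)
  expect_lt(max(abs(id$moments[, c("hip_r", "knee_r", "ankle_r")] -
                      tr$truth$moments[, c("hip_r", "knee_r", "ankle_r")])), 1e-6)
})

test_that("noise-free truth regression returns the response coefficients exactly", {
  resp <- noise_free_response()
  cohort <- generate_cohort(2, seed = 5)
  tp <- generate_truth_peaks(cohort, resp, seed = 5)
  pc <- percent_change(tp)
  for (oc in c("early_peak", "late_peak", "stride_time")) {
    d <- pc[pc$outcome == oc, ]
    d <- d[(d$thigh > 0) + (d$shank > 0) + (d$foot > 0) <= 1, ]
    fit <- fit_origin_regression(d$value, d[, c("thigh", "shank", "foot")])
    truth <- switch(oc, early_peak = resp$peak_effect_early,
                    late_peak = resp$peak_effect_late,
                    stride_time = resp$stride_time_effect)
    expect_equal(unname(coef(fit)), unname(truth[c("thigh", "shank", "foot")]),
                 tolerance = 1e-8)
    expect_equal(fit$pearson_r, 1, tolerance = 1e-6)
  }
})

test_that("the light truth generator matches the full generator's target channel", {
  resp <- response_model()  # with noise and offsets
  cohort <- generate_cohort(1, seed = 9)
  tp <- generate_truth_peaks(cohort, resp, seed = 9)
  sess <- generate_session(cohort, resp, seed = 9, n_strides = 1)
  for (nm in c("none_initial", "shank_high", "all_low")) {
    expect_equal(tp$value[tp$condition == nm & tp$outcome == "early_peak"],
                 sess[[1]][[nm]]$truth$peaks_target$early, tolerance = 1e-12)
  }
})

test_that("realized truth traces stay close to their injection targets at the peaks", {
  tr0 <- fix_trial()
  trf <- fix_trial_loaded()
  for (tr in list(tr0, trf)) {
    expect_equal(tr$truth$peaks$early, tr$truth$peaks_target$early, tolerance = 0.02)
    expect_equal(tr$truth$peaks$late, tr$truth$peaks_target$late, tolerance = 0.02)
  }
  # injected foot-loading response appears in the realized percent change
  d_early <- 100 * (trf$truth$peaks$early / tr0$truth$peaks$early - 1)
  expect_equal(d_early, 2 * 5.9, tolerance = 1.2)
})
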