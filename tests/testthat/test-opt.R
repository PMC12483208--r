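test_that("transcription metadata matches the closed-form counting formula", {
  fx <- fix_execution()
  pr <- fx$problem
  N <- pr$n_nodes
  expect_equal(pr$n_variables, N * (2 * 12 + 3))
  expect_equal(pr$n_constraints, 12 * N + 3 * N)
  cal <- assemble_ocp(fx$trial, fix_model(), fx$ref,
                      default_model_config()$weights$calibration,
                      stage = "calibration")
  expect_equal(cal$n_variables, N * (2 * 12 + 3) + 9)
})

test_that("reported objective equals the weighted sum of its four terms", {
  sol <- fix_execution()$solution
  ob <- sol$objective
  w <- ob$weights
  expect_equal(ob$total,
               w$w1 * ob$J_excitation + w$w2 * ob$J_knee_ankle +
                 w$w3 * ob$J_reserve + w$w4 * ob$J_EMG,
               tolerance = 1e-10)
  expect_true(all(unlist(ob[c("J_excitation", "J_knee_ankle", "J_reserve", "J_EMG")]) >= 0))
})

test_that("solutions are invariant to uniform weight rescaling", {
  fx <- fix_execution()
  w <- default_model_config()$weights$execution
  w10 <- lapply(w, function(x) 10 * x)
  sol10 <- suppressWarnings(solve_execution(fx$problem, fx$trial$truth$scale_factors, w10))
  expect_lt(max(abs(sol10$e - fx$solution$e)), 1e-5)
})

test_that("raising the knee/ankle reserve weight cannot increase that term", {
  fx <- fix_execution()
  w <- default_model_config()$weights$execution
  w2x <- w; w2x$w2 <- 2 * w$w2
  sol2 <- suppressWarnings(solve_execution(fx$problem, fx$trial$truth$scale_factors, w2x))
  expect_lte(sol2$objective$J_knee_ankle, fx$solution$objective$J_knee_ankle + 1e-8)
})

test_that("dropping the tracking term reduces to minimum-effort optimization", {
  fx <- fix_execution()
  w <- list(w1 = 1, w2 = 1000, w3 = 0, w4 = 0)
  pr <- assemble_ocp(fx$trial, fix_model(), NULL, w, stage = "execution")
  sol <- kneeload:::solve_qp_stage(pr, NULL)
  expect_equal(sol$objective$J_EMG, 0)
  # its optimum beats the (co-contracting) truth excitations under the same
  # effort-only objective, evaluated at the truth point
  tr <- fx$trial
  et <- sapply(pr$muscles, function(nm)
    kneeload:::interp1(tr$time, tr$truth$excitations[, nm], pr$times))
  A <- sapply(seq_along(pr$muscles), function(m)
    kneeload:::act_integrate(et[, m], pr$dt, 0.015, 0.060)$a)
  r_k <- pr$tau[, "knee"] - rowSums(pr$gains$K * pr$gains$arms$knee * A) -
    rowSums(pr$gains$P * pr$gains$arms$knee)
  r_a <- pr$tau[, "ankle"] - rowSums(pr$gains$K * pr$gains$arms$ankle * A) -
    rowSums(pr$gains$P * pr$gains$arms$ankle)
  J_truth <- w$w1 * sum(pr$wq * rowSums(et^2)) +
    w$w2 * sum(pr$wq * (r_k^2 + r_a^2))
  expect_lte(sol$objective$total, J_truth)
})

test_that("noiseless execution recovers the truth channel", {
  fx <- fix_execution()
  sol <- fx$solution
  tr <- fx$trial
  et <- sapply(fx$problem$muscles, function(nm)
    kneeload:::interp1(tr$time, tr$truth$excitations[, nm], sol$times))
  pct <- (sol$times - sol$times[1]) / diff(range(sol$times)) * 100
  i <- pct >= 10 & pct <= 90
  expect_lt(sqrt(mean((sol$e[i, ] - et[i, ])^2)), 0.05)
  expect_lt(tracking_rmse(sol), 0.05)
  # feasibility: activation dynamics satisfied to tolerance; reserves close
  # the moment equations by construction
  expect_lt(sol$diagnostics$dynamics_residual, 1e-8)
  expect_equal(sol$diagnostics$moment_residual, 0)
  expect_true(all(sol$e >= 0 & sol$e <= 1))
  expect_true(all(sol$a >= 0 & sol$a <= 1))
})

test_that("tracking RMSE follows its closed form", {
  fx <- fix_execution()
  sol <- fx$solution
  expect_equal(tracking_rmse(sol, reference = sol$e), 0)
  expect_equal(tracking_rmse(sol, reference = sol$e + 0.02), 0.02, tolerance = 1e-12)
  expect_error(tracking_rmse(sol, roi = c(99.2, 99.9)), "region of interest")
})

test_that("calibration recovers known scale factors on a noiseless stride", {
  cfg <- default_model_config()
  tr <- fix_trial()
  ref <- process_emg(tr, cfg)
  pr <- assemble_ocp(tr, fix_model(), ref, cfg$weights$calibration,
                     stage = "calibration", config = cfg)
  sc <- solve_calibration(list(pr), cfg$weights$calibration, cfg)
  s_true <- tr$truth$scale_factors[names(sc$s)]
  expect_lt(mean(abs(sc$s - s_true)), 0.05)
  expect_true(all(sc$s >= 0.5 & sc$s <= 1))
})

test_that("scale factors pin at their bounds under extreme inflation", {
  cfg <- default_model_config()
  s <- fix_subject()
  submax1 <- setNames(rep(1, 9), cfg$emg$measured)
  tr <- generate_stride(s, study_conditions()[1, ], noise_free_response(),
                        seed = 5, n_strides = 1, submax = submax1)
  ref <- process_emg(tr, cfg)
  pr <- assemble_ocp(tr, fix_model(), ref, cfg$weights$calibration,
                     stage = "calibration", config = cfg)
  sc1 <- solve_calibration(list(pr), cfg$weights$calibration, cfg)
  expect_gte(min(sc1$s), 0.93)  # uninflated EMG pins at the upper bound

  # strong inflation: reference far above any moment-consistent excitation
  ref_hi <- kneeload:::clamp(2.4 * sapply(colnames(tr$truth$excitations), function(nm)
    tr$truth$excitations[, nm]), 0, 1)
  pr_hi <- assemble_ocp(tr, fix_model(), ref_hi, cfg$weights$calibration,
                        stage = "calibration", config = cfg)
  sc_hi <- solve_calibration(list(pr_hi), cfg$weights$calibration, cfg)
  expect_lte(max(sc_hi$s), 0.52)  # pinned at the lower bound
})
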