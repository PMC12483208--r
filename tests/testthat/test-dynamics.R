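test_that("zero-phase low-pass keeps DC and the passband, kills the stopband", {
  fs <- 1250
  t <- seq(0, 4, by = 1 / fs)
  expect_equal(lowpass_filter(rep(2.5, length(t)), 8, fs),
               rep(2.5, length(t)), tolerance = 1e-4)
  mid <- (fs):(3 * fs)
  y1 <- lowpass_filter(sin(2 * pi * 1 * t), 8, fs)
  expect_gte(max(abs(y1[mid])), 0.99)
  y100 <- lowpass_filter(sin(2 * pi * 100 * t), 8, fs)
  expect_lte(max(abs(y100[mid])), 1e-3)
})

test_that("static single support satisfies the ankle moment balance", {
  model <- fix_model()
  sp0 <- static_pose_kin(model, cop_offset = 0)
  id0 <- inverse_dynamics(model, sp0$kin, sp0$grf)
  mid <- 11
  # with COP under the ankle, only the foot's own weight loads the joint
  expect_lt(abs(id0$moments[mid, "ankle_r"]), 2.5)
  sp5 <- static_pose_kin(model, cop_offset = 0.05)
  id5 <- inverse_dynamics(model, sp5$kin, sp5$grf)
  lever_term <- unname(id5$moments[mid, "ankle_r"] - id0$moments[mid, "ankle_r"])
  expect_equal(abs(lever_term), 0.05 * 70 * model$gravity, tolerance = 0.1)
  expect_equal(abs(unname(id5$moments[mid, "ankle_r"])), 34.3, tolerance = 2.5 / 34.3)
  expect_error(inverse_dynamics(model, list(time = sp0$kin$time,
                                            q = sp0$kin$q * NA), sp0$grf), "NaN")
})

test_that("static intersegmental axial force matches the free-body oracle", {
  model <- fix_model()
  sp <- static_pose_kin(model)
  inter <- intersegmental_reaction(model, sp$kin, sp$grf)
  seg <- model$segments
  m_sf <- sum(seg$mass[seg$name %in% c("shank_r", "foot_r")])
  expected <- 70 * model$gravity - m_sf * model$gravity
  expect_equal(inter$axial[11], expected, tolerance = 1e-6)
  expect_equal(inter$axial[11] / (70 * model$gravity), 0.94, tolerance = 0.01)

  # hanging limb (zero GRF): purely tensile support of shank+foot weight
  grf0 <- sp$grf; grf0[, c("fx", "fy")] <- 0
  hang <- intersegmental_reaction(model, sp$kin, grf0)
  expect_equal(hang$axial[11], -m_sf * model$gravity, tolerance = 1e-6)
})

test_that("mass below the knee only subtracts its weight from the static axial force", {
  model <- fix_model()
  cond <- loading_condition("foot2", foot = 2)
  model2 <- apply_added_mass(model, cond)
  sp <- static_pose_kin(model)   # same pose and same (unchanged) GRF
  a1 <- intersegmental_reaction(model, sp$kin, sp$grf)$axial[11]
  a2 <- intersegmental_reaction(model2, sp$kin, sp$grf)$axial[11]
  expect_equal(a2 - a1, -1.4 * model$gravity, tolerance = 1e-6)
})

test_that("intersegmental reaction is invariant to muscle parameters", {
  model <- fix_model()
  stronger <- model
  for (nm in names(stronger$muscles)) stronger$muscles[[nm]]$f_max <- 2 * stronger$muscles[[nm]]$f_max
  tr <- fix_trial()
  kin <- list(time = tr$time, q = tr$q)
  expect_identical(intersegmental_reaction(model, kin, tr$grf)$axial,
                   intersegmental_reaction(stronger, kin, tr$grf)$axial)
})

test_that("forward simulation and inverse dynamics are mutually consistent", {
  model <- fix_model()
  tau_fun <- function(t) c(5 * sin(2 * pi * t), -2 * cos(2 * pi * t), 0.5 * sin(4 * pi * t))
  sim <- kneeload:::simulate_leg(model, tau_fun, q0 = c(0.3, 0.4, 0), qd0 = c(0, 0, 0),
                                 t_end = 0.4, dt = 1e-3)
  worst <- 0
  for (k in seq(1, nrow(sim$q), by = 20)) {
    tau_rec <- kneeload:::id_leg_state(model, sim$q[k, ], sim$qd[k, ], sim$qdd[k, ])
    worst <- max(worst, max(abs(tau_rec - tau_fun(sim$time[k]))))
  }
  expect_lt(worst, 1e-6)
})

test_that("synthetic trials are whole-body force consistent to machine precision", {
  tr <- fix_trial()
  model <- apply_added_mass(fix_model(), tr$condition)
  wb <- kneeload:::whole_body_wrench(model, tr$q, 1 / tr$fs)
  total <- tr$grf[, c("fx", "fy")] + tr$grf_left[, c("fx", "fy")]
  expect_lt(max(abs(wb$force - total)), 1e-6)
})
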