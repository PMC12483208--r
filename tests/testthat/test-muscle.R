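test_that("activation dynamics reproduce first-order step responses", {
  dt <- 2e-4
  n <- round(0.12 / dt)
  # activation step: a(tau_act) = 1 - 1/e
  a <- suppressWarnings(activation_dynamics(rep(1, n), a0 = 0, dt = dt))
  k15 <- round(0.015 / dt) + 1
  expect_equal(a[k15], 1 - exp(-1), tolerance = 1e-3)
  # deactivation step: a(tau_deact) = 1/e
  a2 <- suppressWarnings(activation_dynamics(rep(0, n * 4), a0 = 1, dt = dt))
  k60 <- round(0.060 / dt) + 1
  expect_equal(a2[k60], exp(-1), tolerance = 1e-3)
  # fixed point
  a3 <- suppressWarnings(activation_dynamics(rep(0.4, 50), a0 = 0.4, dt = dt))
  expect_equal(a3, rep(0.4, 50))
  expect_warning(activation_dynamics(rep(0.5, 10), dt = 0.01),
                 "trapezoidal")
})

test_that("activation trajectories stay within [0, 1] for random excitations", {
  dt <- 0.002
  for (k in 1:20) {
    set.seed(k)
    e <- runif(300)
    a <- suppressWarnings(activation_dynamics(e, a0 = runif(1), dt = dt))
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("excitation inversion round-trips smooth activation trajectories", {
  dt <- 0.01
  t <- seq(0, 0.6, by = dt)
  a <- 0.2 + 0.15 * sin(2 * pi * t / 0.6)
  e <- kneeload:::excitation_from_activation(a, dt)
  a2 <- kneeload:::act_integrate(e, dt, 0.015, 0.060, a0 = a[1])$a
  expect_equal(a2, a, tolerance = 2e-3)
})

test_that("rigid-tendon force honors its defining identities", {
  curves <- default_model_config()$curves
  mtu <- list(name = "toy", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
              pen_opt = 0, arms = list(knee = c(0.05)),
              lmt_ref = 0.3, q_ref = list(knee = 0.2))
  q <- list(knee = 0.2); qd0 <- list(knee = 0)
  # zero activation, optimal length: no active or passive force
  expect_equal(rigid_tendon_force(mtu, q, qd0, a = 0, curves), 0)
  # full activation at optimal length, zero velocity: peak isometric force
  expect_equal(rigid_tendon_force(mtu, q, qd0, a = 1, curves), 1000)
  # at maximum shortening velocity the force-velocity curve reaches zero
  qd_fast <- list(knee = curves$vmax * mtu$l_opt / 0.05)  # vtilde = -1
  expect_lt(rigid_tendon_force(mtu, q, qd_fast, a = 1, curves), 1e-6)
  # monotone non-decreasing in activation at fixed kinematics
  f <- vapply(seq(0, 1, by = 0.1),
              function(a) rigid_tendon_force(mtu, q, qd0, a, curves), numeric(1))
  expect_true(all(diff(f) >= 0))
})

test_that("the quasi-static elastic tendon tracks the rigid tendon in walking range", {
  model <- fix_model()
  curves <- default_model_config()$curves
  mu <- model$muscles$vas_lat
  q <- list(knee = seq(0.1, 0.6, by = 0.1))
  qd <- list(knee = rep(0.5, 6))
  fr <- rigid_tendon_force(mu, q, qd, a = 0.4, curves)
  fe <- elastic_tendon_force(mu, q, qd, a = 0.4, curves)
  expect_true(all(abs(fe - fr) / pmax(fr, 1) < 0.15))
  # compliance always relieves the fiber: elastic force <= rigid on stretch
  expect_true(all(fe <= fr + 1e-6))
})

test_that("moment arms equal the negative musculotendon length gradient", {
  model <- fix_model()
  h <- 1e-6
  for (nm in c("vas_lat", "semimem", "gas_med", "rec_fem", "soleus")) {
    mu <- model$muscles[[nm]]
    for (j in names(mu$arms)) {
      for (qv in seq(-0.2, 1.0, by = 0.3)) {
        qs <- lapply(mu$arms, function(x) 0.15)
        qs[[j]] <- qv
        qp <- qs; qp[[j]] <- qv + h
        qm <- qs; qm[[j]] <- qv - h
        dldq <- (kneeload:::mtu_length(mu, qp) - kneeload:::mtu_length(mu, qm)) / (2 * h)
        expect_equal(-dldq, moment_arm(mu, j, qv), tolerance = 1e-6)
      }
    }
  }
  expect_error(moment_arm(model$muscles$soleus, "knee", 0.1), "span")
})

test_that("compressive components follow the configured knee fraction", {
  model <- fix_model()
  vl <- model$muscles$vas_lat
  frac <- kneeload:::polyval_asc(vl$comp, 0.3)
  expect_equal(compressive_component(vl, 0.3, 1000), 1000 * frac)
  expect_equal(compressive_component(vl, 0.3, 0), 0)
  # ankle-only muscles contribute nothing at the knee
  expect_equal(compressive_component(model$muscles$soleus, 0.5, 1000), 0)
  # fractions stay within [0, 1] across the knee range of motion
  for (nm in names(model$muscles)) {
    comp <- model$muscles[[nm]]$comp
    if (is.null(comp)) next
    vals <- kneeload:::polyval_asc(comp, seq(0, 1.3, by = 0.01))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
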