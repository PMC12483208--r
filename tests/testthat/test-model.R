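test_that("default model conserves subject mass and is deterministic", {
  s <- subject_anthropometry("A", 70, 1.75)
  m1 <- build_default_model(s)
  m2 <- build_default_model(s)
  expect_equal(sum(m1$segments$mass), 70)
  expect_identical(m1$segments, m2$segments)
  expect_length(m1$muscles, 12)
})

test_that("segment masses scale by the body-mass ratio across subjects", {
  cfg <- default_model_config()
  a <- build_default_model(subject_anthropometry("A", 57, 1.63), cfg)
  b <- build_default_model(subject_anthropometry("B", 81, 1.78), cfg)
  expect_equal(b$segments$mass / a$segments$mass, rep(81 / 57, 7))
  # lengths scale by height, per the configured fraction table
  expect_equal(b$segments$length / a$segments$length, rep(1.78 / 1.63, 7))
})

test_that("muscle strength scaling follows mass*height and is monotone", {
  ref <- list(mass = 75, height = 1.70)
  m0 <- build_default_model(subject_anthropometry("A", 57, 1.63))
  m1 <- scale_muscle_strength(m0, ref$mass, ref$height)
  fac <- 57 * 1.63 / (75 * 1.70)
  expect_equal(m1$muscles$soleus$f_max / m0$muscles$soleus$f_max, fac,
               tolerance = 1e-12)
  # identity when subject equals the reference
  mref <- build_default_model(subject_anthropometry("R", 75, 1.70))
  expect_equal(scale_muscle_strength(mref)$muscles$vas_lat$f_max,
               mref$muscles$vas_lat$f_max)
  # strictly increasing in subject mass at fixed height
  heavier <- scale_muscle_strength(build_default_model(subject_anthropometry("C", 60, 1.63)))
  expect_gt(heavier$muscles$soleus$f_max, m1$muscles$soleus$f_max)
  expect_error(scale_muscle_strength(m0, -1, 1.7), "positive")
})

test_that("rod combinations minimize discrepancy with stated tie-breaks", {
  expect_equal(rod_combination(0)[c("n_large", "n_small", "discrepancy")],
               list(n_large = 0L, n_small = 0L, discrepancy = 0))
  r570 <- rod_combination(570)
  expect_equal(r570$total_mass, 600)
  expect_equal(r570$discrepancy, 30)
  # worst case: exactly half the 75 g granularity, tie broken to smaller mass
  r <- rod_combination(37.5)
  expect_equal(r$total_mass, 0)
  expect_equal(r$discrepancy, -37.5)
  expect_error(rod_combination(-5), "nonnegative")
})

test_that("rod discrepancy is bounded by 37.5 g over an exhaustive sweep", {
  targets <- seq(0, 10000, by = 1)
  disc <- vapply(targets, function(t) rod_combination(t)$discrepancy, numeric(1))
  expect_lte(max(abs(disc)), 37.5)
})

test_that("added mass updates mass, COM and inertia consistently", {
  s <- subject_anthropometry("A", 70, 1.75)
  model <- build_default_model(s)
  cond <- study_conditions()
  expect_identical(apply_added_mass(model, cond[1, ])$segments, model$segments)

  foot2 <- apply_added_mass(model, cond[cond$name == "foot_high", ])
  i <- match("foot_r", foot2$segments$name)
  expect_equal(foot2$segments$mass[i], model$segments$mass[i] + 1.4)
  expect_equal(sum(foot2$segments$mass), 72.8)
  # inertia never decreases under augmentation
  expect_true(all(foot2$segments$inertia_com >= model$segments$inertia_com))

  # point mass exactly at the current COM adds no parallel-axis term
  i_th <- match("thigh_r", model$segments$name)
  com_frac <- model$segments$com_offset[i_th] / model$segments$length[i_th]
  at_com <- apply_added_mass(model, cond[cond$name == "thigh_low", ],
                             attachment = com_frac)
  expect_equal(at_com$segments$inertia_com[i_th], model$segments$inertia_com[i_th])
  expect_error(apply_added_mass(model, cond[2, ], attachment = 1.2), "attachment")
})

test_that("strength scaling commutes with added mass", {
  s <- subject_anthropometry("A", 66, 1.7)
  cond <- study_conditions()[8, ]
  m1 <- apply_added_mass(scale_muscle_strength(build_default_model(s)), cond)
  m2 <- scale_muscle_strength(apply_added_mass(build_default_model(s), cond))
  expect_equal(m1$segments, m2$segments)
  expect_equal(m1$muscles$soleus$f_max, m2$muscles$soleus$f_max)
})

test_that("the nine study conditions carry the protocol magnitudes", {
  sc <- study_conditions()
  expect_equal(nrow(sc), 9)
  expect_equal(sc$thigh[sc$name == "all_high"], 4)
  expect_equal(sc$shank[sc$name == "all_low"], 1.5)
  expect_equal(sum(sc[sc$name == "all_low", c("thigh", "shank", "foot")]), 4.5)
  expect_equal(sum(sc[sc$name == "all_high", c("thigh", "shank", "foot")]), 9)
})

test_that("model configuration survives a YAML round trip", {
  cfg <- default_model_config()
  path <- tempfile(fileext = ".yml")
  write_model_config(cfg, path)
  cfg2 <- read_model_config(path)
  expect_equal(cfg2$segments, cfg$segments, tolerance = 0)
  expect_equal(cfg2$muscles$vas_lat$arms$knee, cfg$muscles$vas_lat$arms$knee,
               tolerance = 0)
  cfg_bad <- cfg
  cfg_bad$segments$thigh$mass_frac <- -0.1
  expect_error(kneeload:::validate_model_config(cfg_bad), "configuration error")
})
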