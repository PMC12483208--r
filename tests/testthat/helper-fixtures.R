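# Shared fixtures, built lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

noise_free_response <- function() response_model(subject_offset_sd = 0, noise_sd = 0)

fix_subject <- function() subject_anthropometry("T01", 70, 1.72)

fix_model <- function() {
  if (is.null(.fix$model)) {
    .fix$model <- scale_muscle_strength(build_default_model(fix_subject()))
  }
  .fix$model
}

# one noiseless unloaded trial (single stride)
fix_trial <- function() {
  if (is.null(.fix$trial)) {
    .fix$trial <- generate_stride(fix_subject(), study_conditions()[1, ],
                                  noise_free_response(), seed = 3, n_strides = 1)
  }
  .fix$trial
}

# one noiseless loaded trial sharing the subject's baseline
fix_trial_loaded <- function() {
  if (is.null(.fix$trial_loaded)) {
    .fix$trial_loaded <- generate_stride(
      fix_subject(), study_conditions()[study_conditions()$name == "foot_high", ],
      noise_free_response(), seed = 3, n_strides = 1,
      baseline = fix_trial()$truth$baseline)
  }
  .fix$trial_loaded
}

# an executed solution on the unloaded fixture trial, using true scales
fix_execution <- function() {
  if (is.null(.fix$execution)) {
    cfg <- default_model_config()
    tr <- fix_trial()
    ref <- process_emg(tr, cfg)
    prob <- assemble_ocp(tr, fix_model(), ref, cfg$weights$execution,
                         stage = "execution", config = cfg)
    sol <- suppressWarnings(solve_execution(prob, tr$truth$scale_factors,
                                            cfg$weights$execution))
    .fix$execution <- list(trial = tr, problem = prob, solution = sol, ref = ref)
  }
  .fix$execution
}

# static single-support pose: vertical tibia, trunk above the ankle
static_pose_kin <- function(model, n = 21, fs = 100, cop_offset = 0) {
  seg <- model$segments
  leg <- seg$length[seg$name == "thigh_r"] + seg$length[seg$name == "shank_r"]
  q <- matrix(rep(c(0, leg, 0, 0, 0, 0, 0, 0, 0), each = n), n, 9)
  colnames(q) <- kneeload:::coord_names
  kin <- list(time = (seq_len(n) - 1) / fs, q = q)
  fy <- model$subject$mass * model$gravity
  fk <- kneeload:::forward_kinematics(model, q)
  grf <- cbind(fx = rep(0, n), fy = rep(fy, n),
               cop = fk$joints$ankle_r[, 1] + cop_offset)
  list(kin = kin, grf = grf)
}
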