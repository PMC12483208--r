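# Default model configuration: anthropometric segment fractions, the
# twelve muscle-tendon parameter tables, angle conventions and processing
# settings. These defaults are editable configuration, not ground truth from
# any particular cadaver or imaging dataset; fractions follow standard
# anthropometric tables and muscle parameters are representative of generic
# lower-limb models, scaled to a 75 kg / 1.70 m reference.

#' Default planar model configuration
#'
#' Returns the full configuration used to construct a planar sagittal
#' musculoskeletal model: segment mass/length/COM/gyration fractions, the
#' twelve muscle-tendon unit parameter tables (peak isometric force, optimal
#' fiber length, tendon slack length, pennation, per-joint moment-arm
#' polynomials and knee compressive-fraction polynomials), activation time
#' constants, muscle curve constants and reference anthropometry.
#'
#' Sign conventions: hip flexion positive, knee flexion positive (zero at
#' full extension), ankle dorsiflexion positive. A positive moment arm
#' produces a moment in the positive direction of the joint coordinate.
#'
#' @return nested list of class `kneeload_config`
#' @export
default_model_config <- function() {
  mus <- function(f_max, l_opt, l_slack, pen, arms, comp = NULL)
    list(f_max = f_max, l_opt = l_opt, l_slack = l_slack, pen_opt = pen,
         arms = arms, comp = comp)
  cfg <- list(
    reference = list(mass = 75, height = 1.70),
    gravity = 9.80665,
    attachment_default = 0.43,
    segments = list(
      hat   = list(mass_frac = 0.678, length_frac = 0.300, com_frac = 0.626, gyr_frac = 0.496),
      thigh = list(mass_frac = 0.100, length_frac = 0.245, com_frac = 0.433, gyr_frac = 0.323),
      shank = list(mass_frac = 0.0465, length_frac = 0.246, com_frac = 0.433, gyr_frac = 0.302),
      foot  = list(mass_frac = 0.0145, length_frac = 0.152, com_frac = 0.500, gyr_frac = 0.475)
    ),
    activation = list(tau_act = 0.015, tau_deact = 0.060),
    curves = list(fl_width = 0.45, vmax = 10, fv_conc = 0.25, fv_ecc_max = 1.5,
                  fpass_strain = 0.6, tendon_strain = 0.04),
    # Reference posture (rad) at which each muscle-tendon unit operates at
    # optimal fiber length: mid-stance-like hip/knee/ankle angles.
    reference_pose = list(hip = 0.2, knee = 0.25, ankle = 0.05),
    muscles = list(
      soleus      = mus(10000, 0.044, 0.26, 0.44, list(ankle = c(-0.048, -0.004))),
      gas_med     = mus(3600, 0.051, 0.40, 0.30, list(ankle = c(-0.046, -0.004), knee = c(0.016, 0.004)),
                        comp = c(0.88, 0.03)),
      gas_lat     = mus(1600, 0.059, 0.38, 0.21, list(ankle = c(-0.044, -0.004), knee = c(0.014, 0.004)),
                        comp = c(0.88, 0.03)),
      tib_ant     = mus(4200, 0.068, 0.24, 0.17, list(ankle = c(0.037))),
      semiten     = mus(2600, 0.190, 0.25, 0.22, list(hip = c(-0.055), knee = c(0.032, 0.006, -0.012)),
                        comp = c(0.82, 0.05)),
      semimem     = mus(4400, 0.069, 0.35, 0.26, list(hip = c(-0.055), knee = c(0.030, 0.006, -0.012)),
                        comp = c(0.82, 0.05)),
      bifem_lh    = mus(3000, 0.098, 0.32, 0.20, list(hip = c(-0.052), knee = c(0.028, 0.006, -0.010)),
                        comp = c(0.82, 0.05)),
      bifem_sh    = mus(1800, 0.110, 0.11, 0.21, list(knee = c(0.028, 0.004)),
                        comp = c(0.82, 0.05)),
      vas_med     = mus(2750, 0.097, 0.11, 0.51, list(knee = c(-0.040, -0.012, 0.008)),
                        comp = c(0.92, -0.05)),
      vas_lat     = mus(5150, 0.099, 0.13, 0.32, list(knee = c(-0.042, -0.012, 0.008)),
                        comp = c(0.92, -0.05)),
      vas_int     = mus(3340, 0.099, 0.10, 0.08, list(knee = c(-0.041, -0.012, 0.008)),
                        comp = c(0.92, -0.05)),
      rec_fem     = mus(2200, 0.076, 0.34, 0.24, list(hip = c(0.045), knee = c(-0.042, -0.010, 0.007)),
                        comp = c(0.92, -0.05))
    ),
    emg = list(
      measured = c("soleus", "gas_med", "gas_lat", "tib_ant", "semiten",
                   "bifem_lh", "vas_med", "vas_lat", "rec_fem"),
      channel_map = c(vas_int = "vas_med", bifem_sh = "bifem_lh", semimem = "semiten"),
      delay = 0.053, highpass = 20, lowpass = 6, filter_order = 4,
      mvc_window = 0.250
    ),
    dynamics = list(grf_lowpass = 8, kin_lowpass = 8, filter_order = 4,
                    prefilter = FALSE),
    stance = list(threshold = 20, debounce = 0.050, roi = c(10, 90),
                  early_window = c(15, 40), late_window = c(60, 90), grid_n = 101L),
    # stage weights: calibration penalizes excitation effort and knee/ankle
    # reserve heavily; execution relaxes both; the EMG-tracking weight w4 is
    # common to both stages. w3 (reserve effort at the hip, which is only
    # partially muscle-actuated here) is zero: reserves are eliminated
    # analytically, so no effort weight is needed for convergence, and any
    # positive weight recruits the biarticular muscles as hip actuators
    # against their EMG (the hip reserve carries ~100 N m).
    weights = list(
      calibration = list(w1 = 0.5, w2 = 1000, w3 = 0, w4 = 1),
      execution   = list(w1 = 0.002, w2 = 100, w3 = 0, w4 = 1)
    ),
    ocp = list(multistart = c(0.5, 0.75, 1.0), maxit = 300L,
               s_bounds = c(0.5, 1), cd_tol = 1e-3, cd_maxit = 10L),
    # synthetic-gait study conditions: baseline stride time and duty factor
    # of the paced treadmill template, and the tonic antagonist
    # co-contraction floor of the truth channel (fraction of the
    # minimum-effort contact force; gives the injected added-mass responses
    # headroom below as well as above the minimum-effort mechanics)
    synth = list(stride_time = 1.10, duty = 0.60, cocontraction_floor = 0.03)
  )
  class(cfg) <- c("kneeload_config", "list")
  cfg
}

#' Write a model configuration to YAML
#' @param config a configuration list from [default_model_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Read a model configuration from YAML
#' @param path YAML path written by [write_model_config()]
#' @return configuration list of class `kneeload_config`
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_model_config(cfg)
  class(cfg) <- c("kneeload_config", "list")
  cfg
}

validate_model_config <- function(cfg) {
  for (nm in c("reference", "segments", "muscles", "activation", "curves")) {
    if (is.null(cfg[[nm]])) stop("configuration error: missing block '", nm, "'")
  }
  fr <- vapply(cfg$segments, function(s) s$mass_frac, numeric(1))
  if (any(!is.finite(fr)) || any(fr < 0))
    stop("configuration error: negative or missing segment mass fraction")
  invisible(TRUE)
}
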