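# Synthetic gait-trial generator. Produces dynamically consistent planar
# walking trials (joint angles at 100 Hz; ground reaction force and EMG at
# 1250 Hz) with a known ground-truth channel: true excitations, true EMG
# scale factors, and the true knee contact-force trace. Added-mass effects
# on the contact-force peaks and on stride time are injected through a
# configurable linear response model: peak effects enter as moment-neutral
# co-contraction of the uniarticular knee muscles, so the injected signal is
# recoverable by the EMG-informed pipeline, and stride-time effects enter by
# time-scaling the kinematic templates.

#' Linear added-mass response model
#'
#' Percent change per percent body weight added per leg, for the early- and
#' late-stance contact-force peaks and for stride time. The peak-effect
#' defaults are the study-condition values for thigh/shank/foot loading;
#' the between-subject offset and residual noise scales are synthetic
#' placeholders (no per-subject variance is published for the outcomes).
#'
#' @param peak_effect_early,peak_effect_late named vectors (thigh, shank,
#'   foot), percent change in peak contact force per % BW per leg
#' @param stride_time_effect named vector, percent change in stride time per
#'   % BW per leg
#' @param subject_offset_sd between-subject random-intercept SD, percent
#' @param noise_sd residual SD on injected peak effects, percent
#' @return list of class `response_model`
#' @export
response_model <- function(peak_effect_early = c(thigh = 1.5, shank = 2.1, foot = 5.9),
                           peak_effect_late = c(thigh = 1.6, shank = 0.9, foot = 3.0),
                           stride_time_effect = c(thigh = 0.26, shank = 0, foot = 2.5),
                           subject_offset_sd = 1.5,
                           noise_sd = 1.5) {
  stopifnot(noise_sd >= 0, subject_offset_sd >= 0,
            all(is.finite(c(peak_effect_early, peak_effect_late, stride_time_effect))))
  structure(list(peak_effect_early = peak_effect_early,
                 peak_effect_late = peak_effect_late,
                 stride_time_effect = stride_time_effect,
                 subject_offset_sd = subject_offset_sd,
                 noise_sd = noise_sd),
            class = "response_model")
}

#' Sample a synthetic cohort
#'
#' Body mass uniform on 57-81 kg and stature uniform on 1.63-1.78 m,
#' matching the study population ranges; reproducible for a fixed seed.
#'
#' @param n number of subjects (>= 1)
#' @param seed integer seed
#' @return data frame with `subject_id`, `mass` (kg), `height` (m)
#' @export
generate_cohort <- function(n, seed) {
  if (n < 1) stop("cohort size must be at least 1")
  with_seed(seed, {
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               mass = stats::runif(n, 57, 81),
               height = stats::runif(n, 1.63, 1.78),
               stringsAsFactors = FALSE)
  })
}

# wrapped (periodic) Gaussian bump on stride phase
phase_bump <- function(phi, center, width) {
  exp(-((phi - center) / width)^2) +
    exp(-((phi - center - 1) / width)^2) +
    exp(-((phi - center + 1) / width)^2)
}

# Joint-angle templates over stride phase (heel strike at phi = 0). The
# phase lag on the hip keeps the tibia progressing forward through
# mid-stance, which shapes a physiological biphasic knee moment.
# `load_frac` (total added mass / body mass) stiffens the loading-response
# knee flexion, a documented adaptation to carrying mass that keeps the
# purely mechanistic demand increase below the injected response targets.
gait_angles <- function(phi, load_frac = 0) {
  list(
    hip = 0.15 + 0.33 * cos(2 * pi * (phi - 0.05)),
    knee = 0.06 + 0.46 * (1 - 0.5 * load_frac) * phase_bump(phi, 0.18, 0.12) +
      1.05 * phase_bump(phi, 0.73, 0.13),
    ankle = 0.15 * phase_bump(phi, 0.42, 0.18) - 0.38 * phase_bump(phi, 0.63, 0.06)
  )
}

# Swing/tonic excitation template per muscle over stride phase; stance
# excitations are overwritten by the redundancy solution.
swing_excitation <- function(phi) {
  floor_e <- 0.015
  list(
    soleus = floor_e + 0.01 * phase_bump(phi, 0.45, 0.2),
    gas_med = floor_e + 0.01 * phase_bump(phi, 0.45, 0.2),
    gas_lat = floor_e + 0.01 * phase_bump(phi, 0.45, 0.2),
    tib_ant = floor_e + 0.12 * phase_bump(phi, 0.70, 0.10) + 0.10 * phase_bump(phi, 0.97, 0.06),
    semiten = floor_e + 0.10 * phase_bump(phi, 0.92, 0.06),
    semimem = floor_e + 0.10 * phase_bump(phi, 0.92, 0.06),
    bifem_lh = floor_e + 0.10 * phase_bump(phi, 0.92, 0.06),
    bifem_sh = floor_e + 0.06 * phase_bump(phi, 0.85, 0.08),
    vas_med = floor_e + 0.04 * phase_bump(phi, 0.98, 0.05),
    vas_lat = floor_e + 0.04 * phase_bump(phi, 0.98, 0.05),
    vas_int = floor_e + 0.04 * phase_bump(phi, 0.98, 0.05),
    rec_fem = floor_e + 0.05 * phase_bump(phi, 0.65, 0.06)
  )
}

# Build the 9-coordinate kinematic matrix for n_strides strides.
make_kinematics <- function(model, stride_time, duty = 0.60, n_strides = 3,
                            fs = 100, pad = 0.12, load_frac = 0) {
  seg <- model$segments
  leg_len <- seg$length[match("thigh_r", seg$name)] + seg$length[match("shank_r", seg$name)]
  # end the trial after the last full stance so no truncated stance is seen
  t_end <- pad + (n_strides - 1 + duty) * stride_time + 0.5 * pad
  time <- seq(0, t_end, by = 1 / fs)
  phi <- ((time - pad) / stride_time) %% 1
  phi_l <- (phi + 0.5) %% 1
  ar <- gait_angles(phi, load_frac)
  al <- gait_angles(phi_l, load_frac)
  q <- cbind(
    trunk_x = 0.010 * sin(4 * pi * (phi - 0.07)),
    trunk_y = 0.985 * leg_len - 0.013 * leg_len * cos(4 * pi * (phi - 0.07)),
    trunk_rot = 0.02 * sin(4 * pi * phi),
    hip_r = ar$hip, knee_r = ar$knee, ankle_r = ar$ankle,
    hip_l = al$hip, knee_l = al$knee, ankle_l = al$ankle
  )
  list(time = time, q = q, phi = phi, stride_time = stride_time, duty = duty,
       pad = pad, fs = fs, n_strides = n_strides, load_frac = load_frac)
}

# Force-share weight of the right foot over stride phase: cosine ramps over
# the double-support fractions at the edges of stance.
right_share <- function(phi, duty = 0.60, ds = 0.10) {
  w <- numeric(length(phi))
  w[phi < ds] <- 0.5 * (1 - cos(pi * phi[phi < ds] / ds))
  w[phi >= ds & phi < duty - ds] <- 1
  i <- phi >= duty - ds & phi < duty
  w[i] <- 0.5 * (1 + cos(pi * (phi[i] - (duty - ds)) / ds))
  w
}

smoothstep <- function(s) {
  s <- clamp(s, 0, 1)
  s^2 * (3 - 2 * s)
}

# Ground reaction forces for both feet from whole-body dynamic consistency,
# with smooth double-support force sharing and a heel-to-toe COP progression
# under each foot.
make_grf <- function(model, kin) {
  wb <- whole_body_wrench(model, kin$q, 1 / kin$fs)
  Ft <- wb$force
  duty <- kin$duty
  wr <- right_share(kin$phi, duty)
  wl <- right_share((kin$phi + 0.5) %% 1, duty)
  fk <- wb$kd$fk
  lf <- kin$load_frac %||% 0
  cop_for <- function(phi_side, ankle_x) {
    s <- clamp(phi_side / duty, 0, 1)
    # heel-to-toe progression weighted toward late stance: keeps the ground
    # reaction line near the knee through mid-stance; carried mass shortens
    # the push-off lever (gait adaptation), moderating the mechanistic rise
    # in late-stance demand
    ankle_x - 0.06 + 0.22 * (1 - lf) * smoothstep(s)^2
  }
  grf_r <- cbind(fx = wr * Ft[, 1], fy = wr * Ft[, 2],
                 cop = cop_for(kin$phi, fk$joints$ankle_r[, 1]))
  grf_l <- cbind(fx = wl * Ft[, 1], fy = wl * Ft[, 2],
                 cop = cop_for((kin$phi + 0.5) %% 1, fk$joints$ankle_l[, 1]))
  list(grf_r = grf_r, grf_l = grf_l, total = Ft, kd = wb$kd)
}

# Minimum-norm activations under per-node moment equality at the knee and
# ankle with box bounds: active-set clamping on the bounded least-norm
# problem min ||x||^2 s.t. Ax = b, 0 <= x <= u (vector upper allowed).
min_norm_bounded <- function(A, b, upper = 0.95) {
  p <- ncol(A)
  upper <- rep(upper, length.out = p)
  x <- numeric(p)
  free <- rep(TRUE, p)
  for (iter in seq_len(p)) {
    b_eff <- b - A[, !free, drop = FALSE] %*% x[!free]
    Af <- A[, free, drop = FALSE]
    G <- Af %*% t(Af)
    sol <- tryCatch(t(Af) %*% solve(G + 1e-10 * diag(nrow(G)), b_eff),
                    error = function(e) NULL)
    if (is.null(sol)) stop("truth redundancy solve failed: singular moment system")
    x[free] <- sol
    viol_lo <- x < -1e-10
    viol_hi <- x > upper + 1e-10
    if (!any(viol_lo | viol_hi)) break
    worst <- which.max(pmax(-x, x - upper))
    x[worst] <- clamp(x[worst], 0, upper[worst])
    free[worst] <- FALSE
    if (!any(free)) break
  }
  clamp(x, 0, upper)
}

# Shared-innervation ties: the three unmeasured muscles share the
# excitation of their EMG donor, matching the pipeline's channel mapping.
innervation_groups <- function(muscle_names, channel_map) {
  groups <- lapply(muscle_names, function(m) m)
  names(groups) <- muscle_names
  for (target in names(channel_map)) {
    src <- channel_map[[target]]
    groups[[src]] <- c(groups[[src]], target)
    groups[[target]] <- NULL
  }
  groups
}

# Bounded minimum-norm redundancy with tied activations: activations within
# a shared-innervation group are equal, so the system reduces to one
# variable per group (weighted by group size).
min_norm_tied <- function(A, b, groups, upper = 0.95) {
  n_g <- lengths(groups)
  Ag <- sapply(groups, function(g) rowSums(A[, g, drop = FALSE]))
  y <- min_norm_bounded(Ag %*% diag(1 / sqrt(n_g)), b, upper * sqrt(n_g))
  xg <- y / sqrt(n_g)
  x <- numeric(ncol(A))
  names(x) <- colnames(A)
  for (i in seq_along(groups)) x[groups[[i]]] <- xg[i]
  x
}

# Truth redundancy solution on one stance window: minimum-effort activations
# satisfying the knee and ankle net moments, the resulting contact trace and
# the per-node force gains. `idx` indexes the 100 Hz grid.
truth_solve <- function(model, kin, grf, idx, config) {
  dt <- 1 / kin$fs
  qfull <- kin$q
  qd <- central_diff(qfull, dt)
  qs <- list(hip = qfull[idx, "hip_r"], knee = qfull[idx, "knee_r"],
             ankle = qfull[idx, "ankle_r"])
  qds <- list(hip = qd[idx, "hip_r"], knee = qd[idx, "knee_r"],
              ankle = qd[idx, "ankle_r"])
  id <- inverse_dynamics(model, kin, grf)
  gains <- muscle_gains(model, qs, qds)
  n <- length(idx)
  nm <- colnames(gains$K)
  groups <- innervation_groups(nm, config$emg$channel_map)
  a0 <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  for (k in seq_len(n)) {
    A <- rbind(knee = gains$K[k, ] * gains$arms$knee[k, ],
               ankle = gains$K[k, ] * gains$arms$ankle[k, ])
    b <- c(id$moments[idx[k], "knee_r"] - sum(gains$P[k, ] * gains$arms$knee[k, ]),
           id$moments[idx[k], "ankle_r"] - sum(gains$P[k, ] * gains$arms$ankle[k, ]))
    a0[k, ] <- min_norm_tied(A, b, groups)
  }
  inter <- intersegmental_reaction(model, kin, grf)
  bw <- model$subject$mass * model$gravity
  tstance <- kin$time[idx]
  pct <- (tstance - tstance[1]) / (tstance[n] - tstance[1]) * 100
  inter_bw <- inter$axial[idx] / bw
  list(idx = idx, time = tstance, pct = pct, a0 = a0, gains = gains,
       tau = id$moments[idx, , drop = FALSE], inter_bw = inter_bw, bw = bw,
       moments_full = id$moments, dt = dt)
}

contact_from_activation <- function(ts, a) {
  F <- ts$gains$K * a + ts$gains$P
  muscle_bw <- rowSums(ts$gains$comp * F) / ts$bw
  total_bw <- ts$inter_bw + muscle_bw
  list(total = total_bw, muscle = muscle_bw, inter = ts$inter_bw, force = F)
}

# Forward sweep enforcing activation-rate feasibility on a desired
# activation trajectory: activations cannot fall faster than the
# deactivation time constant allows, so a muscle whose demand vanishes
# keeps producing moment while it decays. The sweep clamps each node to the
# reachable band and closes the resulting knee/ankle moment residuals with
# the joint's uniarticular antagonist group (raising activation is fast and
# always feasible). Knee corrections use the vasti/hamstrings, ankle
# corrections the soleus/tibialis anterior, so the two joints decouple; the
# hamstrings' hip byproduct goes to the hip reserve.
forward_feasible <- function(ts, a_des, tau_act, tau_deact, a_max = 0.95,
                             a_init = a_des[1, ]) {
  n <- nrow(a_des)
  dt <- ts$dt
  K <- ts$gains$K
  arms_k <- ts$gains$arms$knee
  arms_a <- ts$gains$arms$ankle
  b_knee <- ts$tau[, "knee_r"] - rowSums(ts$gains$P * arms_k)
  b_ankle <- ts$tau[, "ankle_r"] - rowSums(ts$gains$P * arms_a)
  grp <- list(knee_pos = c("semiten", "semimem", "bifem_lh", "bifem_sh"),
              knee_neg = c("vas_med", "vas_lat", "vas_int"),
              ankle_pos = "tib_ant", ankle_neg = "soleus")
  dec <- exp(-dt / tau_deact)
  ris <- exp(-dt / tau_act)
  a <- a_des
  for (k in seq_len(n)) {
    aprev <- if (k == 1) a_init else a[k - 1, ]
    lo <- aprev * dec
    hi <- 1 + (aprev - 1) * ris
    a[k, ] <- clamp(a_des[k, ], lo, hi)
    close_dof <- function(r, pos, neg, arms) {
      g <- if (r > 0) pos else neg
      gain <- sum(K[k, g] * arms[k, g])
      if (abs(gain) < 1e-9) return(invisible(NULL))
      d <- r / gain
      head <- pmin(a_max, hi[g]) - a[k, g]
      if (d > 0) d <- min(d, suppressWarnings(min(head)))
      if (d < 0) d <- max(d, -suppressWarnings(min(a[k, g] - lo[g])))
      a[k, g] <<- clamp(a[k, g] + d, lo[g], pmin(a_max, hi[g]))
    }
    r_k <- b_knee[k] - sum(K[k, ] * arms_k[k, ] * a[k, ])
    close_dof(r_k, grp$knee_pos, grp$knee_neg, arms_k)
    r_a <- b_ankle[k] - sum(K[k, ] * arms_a[k, ] * a[k, ])
    close_dof(r_a, grp$ankle_pos, grp$ankle_neg, arms_a)
  }
  a
}

# Moment-neutral co-contraction injection: per-node shared activation
# increments of the knee extensors (vasti) and knee flexors (hamstrings)
# that add `delta_c` newtons of tibia-axial compression with zero net knee
# moment change. The hamstrings' hip-extension byproduct is carried by the
# lightly penalized hip reserve. If a bound would be exceeded the node's
# increment pair is scaled down jointly (staying moment-neutral).
inject_cocontraction <- function(ts, a0, delta_c, a_max = 0.95) {
  vast <- c("vas_med", "vas_lat", "vas_int")
  flex <- c("semiten", "semimem", "bifem_lh", "bifem_sh")
  a <- a0
  K <- ts$gains$K; arms <- ts$gains$arms$knee; comp <- ts$gains$comp
  for (k in seq_along(delta_c)) {
    dc <- delta_c[k]
    if (dc <= 0) next
    M <- matrix(c(sum(K[k, vast] * arms[k, vast]), sum(K[k, flex] * arms[k, flex]),
                  sum(K[k, vast] * comp[k, vast]), sum(K[k, flex] * comp[k, flex])),
                2, 2, byrow = TRUE)
    d <- solve(M, c(0, dc))
    grp <- c(vast, flex)
    dd <- c(rep(d[1], length(vast)), rep(d[2], length(flex)))
    head <- pmax(a_max - a[k, grp], 0)
    scl <- suppressWarnings(min(1, head[dd > 0] / dd[dd > 0]))
    if (!is.finite(scl)) scl <- 0
    a[k, grp] <- a[k, grp] + scl * dd
  }
  clamp(a, 0, 1)
}

#' Synthesize raw-like EMG channels from true excitations
#'
#' Each measured channel is the true excitation multiplied by its
#' submaximal-MVC inflation factor (>= 1), plus Gaussian noise, clipped to
#' `[0, 1]`, and advanced in time so that the electromechanical-delay
#' compensation applied during processing re-aligns it. The implied
#' recoverable scale factor is `1/submax_factor`. The three unmeasured
#' muscles (vastus intermedius, biceps femoris short head, semimembranosus)
#' emit no channel.
#'
#' @param true_excitations matrix (time x 12 named muscles) on a uniform grid
#' @param time time vector of `true_excitations`, s
#' @param submax_factor named per-channel inflation factors in `[1, 2]`
#' @param noise_sd Gaussian noise SD on the normalized channel scale
#' @param delay electromechanical delay, s (default 0.053)
#' @param seed integer seed for the noise
#' @param fs_out output sampling rate, Hz (default 1250)
#' @param measured channel names (default the nine instrumented muscles)
#' @return data frame: `time` plus one column per measured channel
#' @export
emulate_emg <- function(true_excitations, time, submax_factor, noise_sd = 0,
                        delay = 0.053, seed = 1, fs_out = 1250,
                        measured = default_model_config()$emg$measured) {
  if (any(submax_factor < 1 - 1e-9 | submax_factor > 2 + 1e-9))
    stop("submax_factor must lie in [1, 2]")
  t_out <- seq(time[1], time[length(time)], by = 1 / fs_out)
  shift <- round(delay * fs_out) / fs_out
  out <- data.frame(time = t_out)
  with_seed(seed, {
    for (ch in measured) {
      e <- interp1(time, true_excitations[, ch], t_out + shift)
      v <- e * submax_factor[[ch]]
      if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
      out[[ch]] <- clamp(v, 0, 1)
    }
  })
  out
}

#' Generate one synthetic gait trial
#'
#' Builds the loaded planar model, time-scales the kinematic templates by
#' the response model's stride-time effect, derives both feet's ground
#' reaction forces from whole-body dynamic consistency, solves the
#' minimum-effort muscle redundancy problem on the stance phase for true
#' activations, injects the response model's contact-force peak effects as
#' moment-neutral knee co-contraction, and synthesizes EMG from the true
#' excitations. The returned trial carries a full ground-truth record.
#'
#' @param subject one row of [generate_cohort()] or a [subject_anthropometry()]
#' @param condition one row of [study_conditions()]
#' @param response a [response_model()]
#' @param seed integer seed
#' @param config model configuration
#' @param n_strides consecutive strides in the trial (default 3)
#' @param baseline optional cached baseline truth for this subject (from a
#'   previous `condition = none` call), avoids recomputation
#' @param submax named submaximal-MVC inflation factors; default drawn per
#'   subject with implied scale factors uniform in `[0.55, 0.95]`
#' @param subject_effects optional list with `offset_early`, `offset_late`
#'   (percent); default drawn from the subject-level seed
#' @param emg_noise_sd EMG noise SD (default 0)
#' @return list of class `gait_trial`
#' @export
generate_stride <- function(subject, condition, response = response_model(),
                            seed = 1, config = default_model_config(),
                            n_strides = 3, baseline = NULL, submax = NULL,
                            subject_effects = NULL, emg_noise_sd = 0) {
  if (inherits(subject, "data.frame")) {
    subject <- subject_anthropometry(subject$subject_id[1], subject$mass[1], subject$height[1])
  }
  sub_seed <- derive_seed(seed, sum(utf8ToInt(subject$subject_id)))
  measured <- config$emg$measured
  if (is.null(submax)) {
    submax <- with_seed(sub_seed, {
      s_true <- stats::runif(length(measured), 0.55, 0.95)
      stats::setNames(1 / s_true, measured)
    })
  }
  if (is.null(subject_effects)) {
    subject_effects <- with_seed(derive_seed(sub_seed, 7), list(
      offset_early = stats::rnorm(1, 0, response$subject_offset_sd),
      offset_late = stats::rnorm(1, 0, response$subject_offset_sd)))
  }
  m <- c(thigh = condition$thigh, shank = condition$shank, foot = condition$foot)
  loaded <- sum(m) > 0
  eff <- function(v) sum(v[c("thigh", "shank", "foot")] * m)
  # noise and the subject offset attach to the injected condition effect;
  # unloaded trials carry no injected effect and stay noise-free
  noise <- with_seed(derive_seed(seed, 13),
                     stats::rnorm(2, 0, response$noise_sd))
  delta_early <- if (loaded) eff(response$peak_effect_early) + subject_effects$offset_early +
    noise[1] else 0
  delta_late <- if (loaded) eff(response$peak_effect_late) + subject_effects$offset_late +
    noise[2] else 0
  stride_time0 <- config$synth$stride_time
  stride_time <- stride_time0 * (1 + eff(response$stride_time_effect) / 100)

  model0 <- scale_muscle_strength(build_default_model(subject, config))
  model <- apply_added_mass(model0, condition)

  load_frac <- 2 * sum(m) / 100
  kin <- make_kinematics(model, stride_time, duty = config$synth$duty,
                         n_strides = n_strides, load_frac = load_frac)
  grf <- make_grf(model, kin)

  # gait events from the high-rate force channel, as the pipeline will see them
  fs_hi <- 1250
  t_hi <- seq(kin$time[1], kin$time[length(kin$time)], by = 1 / fs_hi)
  grf_hi <- data.frame(time = t_hi,
                       fx = interp1(kin$time, grf$grf_r[, "fx"], t_hi),
                       fy = interp1(kin$time, grf$grf_r[, "fy"], t_hi),
                       cop = interp1(kin$time, grf$grf_r[, "cop"], t_hi))
  segm <- detect_stance(pmax(grf_hi$fy, 0), fs_hi,
                        threshold = config$stance$threshold,
                        debounce = config$stance$debounce)
  hs <- segm$events$heel_strike[1] + t_hi[1]
  to <- segm$events$toe_off[1] + t_hi[1]
  idx <- which(kin$time >= hs & kin$time <= to)

  # truth redundancy solution for this condition (minimum-effort floor)
  ts <- truth_solve(model, kin, grf$grf_r, idx, config)
  base_contact <- contact_from_activation(ts, ts$a0)
  grid101 <- stance_pct_grid()
  tmin101 <- resample_pct(ts$pct, base_contact$total)
  inter101 <- resample_pct(ts$pct, base_contact$inter)

  # baseline (no-mass) floored contact trace, the reference for this
  # subject's percent changes: minimum effort plus the tonic co-contraction
  # floor, always noise-free
  floor_frac <- config$synth$cocontraction_floor
  if (is.null(baseline)) {
    if (!loaded) {
      baseline <- list(pct = grid101, total = tmin101 * (1 + floor_frac))
    } else {
      kin0 <- make_kinematics(model0, stride_time0, duty = config$synth$duty, n_strides = 1)
      grf0 <- make_grf(model0, kin0)
      fy0 <- interp1(kin0$time, grf0$grf_r[, "fy"], seq(kin0$time[1], max(kin0$time), by = 1 / fs_hi))
      seg0 <- detect_stance(pmax(fy0, 0), fs_hi, config$stance$threshold, config$stance$debounce)
      idx0 <- which(kin0$time >= seg0$events$heel_strike[1] & kin0$time <= seg0$events$toe_off[1])
      ts0 <- truth_solve(model0, kin0, grf0$grf_r, idx0, config)
      c0 <- contact_from_activation(ts0, ts0$a0)
      baseline <- list(pct = grid101, total = resample_pct(ts0$pct, c0$total) * (1 + floor_frac))
    }
  }

  # smooth early/late blend of the injected percent change across stance
  blend <- function(pct) {
    wsm <- smoothstep(clamp((pct - 45) / 10, 0, 1))
    delta_early * (1 - wsm) + delta_late * wsm
  }
  # taper the injection to zero at the stance edges, where the muscle gains
  # vanish and the moment-neutral pair could not realize it anyway
  taper <- smoothstep(grid101 / 8) * smoothstep((100 - grid101) / 8)
  target101 <- baseline$total * (1 + blend(grid101) / 100)
  dc101 <- taper * pmax(0, target101 - tmin101) * ts$bw
  delta_c <- pmax(0, interp1(grid101, dc101, ts$pct))
  # short moving-average smoothing: the positive-part clamp leaves a kink at
  # the mid-stance valley that would ring through the excitation inversion
  delta_c <- stats::filter(delta_c, rep(1 / 3, 3), sides = 2)
  delta_c[is.na(delta_c)] <- 0
  a_des <- inject_cocontraction(ts, ts$a0, as.numeric(delta_c))

  # activation state carried into stance: integrate the late-swing/tonic
  # excitation template from trial start to heel strike
  nmus <- names(model$muscles)
  tau_a <- config$activation$tau_act
  tau_d <- config$activation$tau_deact
  sw <- swing_excitation(kin$phi)
  e_full <- sapply(nmus, function(nm) sw[[nm]])
  i_hs <- idx[1]
  a_init <- vapply(nmus, function(nm)
    act_integrate(e_full[1:i_hs, nm], 1 / kin$fs, tau_a, tau_d)$a[i_hs], numeric(1))

  a_star <- forward_feasible(ts, a_des, tau_a, tau_d, a_init = a_init)
  # excitations: invert activation dynamics on the stance grid; then
  # re-integrate (the inversion clamps e >= 0, so fast activation falls are
  # deactivation-limited) so the realized, dynamics-consistent activations
  # are what the trial's EMG and contact trace reflect
  e_st <- apply(a_star, 2, excitation_from_activation, dt = ts$dt,
                tau_act = tau_a, tau_deact = tau_d)
  a_star <- sapply(seq_along(nmus), function(j)
    act_integrate(e_st[, j], ts$dt, tau_a, tau_d, a0 = a_init[j])$a)
  colnames(a_star) <- colnames(e_st)
  achieved <- contact_from_activation(ts, a_star)
  # crossfade lives entirely OUTSIDE the stance window so the stance-phase
  # truth excitations are embedded exactly
  fade <- 0.04
  for (k in seq_len(n_strides)) {
    tshift <- (k - 1) * kin$stride_time
    tw <- kin$time - tshift
    t0 <- ts$time[1]; t1 <- ts$time[length(ts$time)]
    inwin <- tw >= t0 - fade & tw <= t1 + fade
    if (!any(inwin)) next
    wgt <- clamp(pmin((tw[inwin] - (t0 - fade)) / fade,
                      ((t1 + fade) - tw[inwin]) / fade), 0, 1)
    for (j in seq_along(nmus)) {
      ev <- interp1(ts$time, e_st[, j], tw[inwin])
      e_full[inwin, j] <- wgt * ev + (1 - wgt) * e_full[inwin, j]
    }
  }
  e_full <- clamp(e_full, 0, 1)
  colnames(e_full) <- nmus

  emg <- emulate_emg(e_full, kin$time, submax, noise_sd = emg_noise_sd,
                     delay = config$emg$delay, seed = derive_seed(seed, 29),
                     measured = measured)
  mvc <- stats::setNames(lapply(measured, function(ch) rep(1, 500)), measured)

  truth <- list(
    excitations = e_full,
    activations_stance = a_star,
    scale_factors = stats::setNames(1 / submax[measured], measured),
    # realized trace: what the trial's muscles actually produce (activation
    # dynamics limit how fast force can decay, so the valley between the
    # peaks sits above the injection target)
    contact = structure(data.frame(
      pct = grid101,
      total = resample_pct(ts$pct, achieved$total),
      muscle = resample_pct(ts$pct, achieved$muscle),
      inter = inter101), class = c("contact_trace", "data.frame")),
    # injection target: the response model's analytic construct; its peaks
    # carry the exact linear added-mass effects
    contact_target = {
      total101 <- ifelse(dc101 > 0, target101, tmin101)
      structure(data.frame(pct = grid101, total = total101,
                           muscle = total101 - inter101, inter = inter101),
                class = c("contact_trace", "data.frame"))
    },
    contact_nodes = data.frame(pct = ts$pct, total = achieved$total,
                               muscle = achieved$muscle, inter = achieved$inter),
    moments = ts$moments_full,
    stride_time = stride_time,
    duty_factor = kin$duty,
    delta_injected = c(early = delta_early, late = delta_late),
    baseline = baseline
  )
  truth$peaks <- extract_peaks(truth$contact, config = config)
  truth$peaks_target <- extract_peaks(truth$contact_target, config = config)

  structure(list(
    subject = subject, condition = condition,
    time = kin$time, q = kin$q, fs = kin$fs,
    grf = grf$grf_r, grf_left = grf$grf_l,
    grf_hi = grf_hi, fs_grf = 1250,
    emg = emg, fs_emg = 1250, mvc = mvc,
    events = data.frame(heel_strike = segm$events$heel_strike + t_hi[1],
                        toe_off = segm$events$toe_off + t_hi[1]),
    stride_time = segm$stride_time, duty_factor = segm$duty_factor,
    truth = truth, seed = seed, response = response
  ), class = "gait_trial")
}

#' Ground-truth outcome table without trial synthesis
#'
#' Computes, for every subject and protocol trial, the response model's
#' target contact-force peaks and stride time without synthesizing EMG or
#' solving the trial mechanics: one baseline redundancy solve per subject
#' defines the reference trace, and condition targets follow from the
#' injected linear effects. Uses the same seed streams as
#' [generate_session()], so the drawn offsets and noise match the full
#' generator.
#'
#' @inheritParams generate_session
#' @return outcome table (one row per subject x trial x outcome) with the
#'   target `early_peak`, `late_peak` (BW) and `stride_time` (s)
#' @export
generate_truth_peaks <- function(cohort, response = response_model(), seed = 1,
                                 config = default_model_config(),
                                 conditions = study_conditions()) {
  protocol <- rbind(
    transform(conditions[conditions$name == "none", ], name = "none_initial"),
    conditions[conditions$name != "none", ],
    transform(conditions[conditions$name == "none", ], name = "none_final"))
  fs_hi <- 1250
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    subj <- subject_anthropometry(cohort$subject_id[i], cohort$mass[i], cohort$height[i])
    eff_off <- with_seed(derive_seed(seed, 6007 + i), list(
      offset_early = stats::rnorm(1, 0, response$subject_offset_sd),
      offset_late = stats::rnorm(1, 0, response$subject_offset_sd)))
    model0 <- scale_muscle_strength(build_default_model(subj, config))
    kin0 <- make_kinematics(model0, config$synth$stride_time,
                            duty = config$synth$duty, n_strides = 1)
    grf0 <- make_grf(model0, kin0)
    t_hi <- seq(kin0$time[1], max(kin0$time), by = 1 / fs_hi)
    seg0 <- detect_stance(pmax(interp1(kin0$time, grf0$grf_r[, "fy"], t_hi), 0),
                          fs_hi, config$stance$threshold, config$stance$debounce)
    idx0 <- which(kin0$time >= seg0$events$heel_strike[1] &
                    kin0$time <= seg0$events$toe_off[1])
    ts0 <- truth_solve(model0, kin0, grf0$grf_r, idx0, config)
    c0 <- contact_from_activation(ts0, ts0$a0)
    base101 <- resample_pct(ts0$pct, c0$total) * (1 + config$synth$cocontraction_floor)
    grid101 <- stance_pct_grid()
    for (j in seq_len(nrow(protocol))) {
      cond <- protocol[j, ]
      tseed <- derive_seed(seed, i * 101 + j)
      m <- c(thigh = cond$thigh, shank = cond$shank, foot = cond$foot)
      loaded <- sum(m) > 0
      noise <- with_seed(derive_seed(tseed, 13), stats::rnorm(2, 0, response$noise_sd))
      de <- if (loaded) sum(response$peak_effect_early[names(m)] * m) +
        eff_off$offset_early + noise[1] else 0
      dl <- if (loaded) sum(response$peak_effect_late[names(m)] * m) +
        eff_off$offset_late + noise[2] else 0
      wsm <- smoothstep(clamp((grid101 - 45) / 10, 0, 1))
      target <- base101 * (1 + (de * (1 - wsm) + dl * wsm) / 100)
      pk <- extract_peaks(data.frame(pct = grid101, total = target), config)
      stride_time <- config$synth$stride_time *
        (1 + sum(response$stride_time_effect[names(m)] * m) / 100)
      base_row <- data.frame(subject_id = subj$subject_id, condition = cond$name,
                             thigh = cond$thigh, shank = cond$shank,
                             foot = cond$foot, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- rbind(
        cbind(base_row, data.frame(outcome = "early_peak", value = pk$early, unit = "BW")),
        cbind(base_row, data.frame(outcome = "late_peak", value = pk$late, unit = "BW")),
        cbind(base_row, data.frame(outcome = "stride_time", value = stride_time, unit = "s")))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Generate a full synthetic data-collection session for a cohort
#'
#' Follows the experimental protocol: an initial no-mass trial, the eight
#' loading trials, and a final no-mass trial per subject. Subject-level
#' quantities (submaximal-MVC factors, random intercepts) are drawn once per
#' subject and shared across that subject's trials.
#'
#' @param cohort data frame from [generate_cohort()]
#' @param response a [response_model()]
#' @param seed integer seed
#' @param config model configuration
#' @param conditions condition table, default [study_conditions()]
#' @param n_strides strides per trial
#' @param emg_noise_sd EMG noise SD
#' @return list (per subject) of lists (per trial) of `gait_trial`s
#' @export
generate_session <- function(cohort, response = response_model(), seed = 1,
                             config = default_model_config(),
                             conditions = study_conditions(), n_strides = 3,
                             emg_noise_sd = 0) {
  protocol <- rbind(
    transform(conditions[conditions$name == "none", ], name = "none_initial"),
    conditions[conditions$name != "none", ],
    transform(conditions[conditions$name == "none", ], name = "none_final"))
  out <- list()
  measured <- config$emg$measured
  for (i in seq_len(nrow(cohort))) {
    subj <- cohort[i, ]
    submax <- with_seed(derive_seed(seed, 7919 + i), {
      stats::setNames(1 / stats::runif(length(measured), 0.55, 0.95), measured)
    })
    subject_effects <- with_seed(derive_seed(seed, 6007 + i), list(
      offset_early = stats::rnorm(1, 0, response$subject_offset_sd),
      offset_late = stats::rnorm(1, 0, response$subject_offset_sd)))
    trials <- list()
    baseline <- NULL
    for (j in seq_len(nrow(protocol))) {
      cond <- protocol[j, ]
      tr <- generate_stride(subj, cond, response,
                            seed = derive_seed(seed, i * 101 + j),
                            config = config, n_strides = n_strides,
                            baseline = baseline, submax = submax,
                            subject_effects = subject_effects,
                            emg_noise_sd = emg_noise_sd)
      if (cond$thigh + cond$shank + cond$foot == 0 && is.null(baseline))
        baseline <- tr$truth$baseline
      trials[[cond$name]] <- tr
    }
    out[[subj$subject_id]] <- trials
  }
  out
}
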