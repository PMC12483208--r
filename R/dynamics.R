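# Planar whole-body kinematics and Newton-Euler inverse dynamics.
#
# Generalized coordinates (9 DOF): trunk_x, trunk_y (hip-joint position, m),
# trunk_rot (forward lean positive, rad), then hip/knee/ankle flexion per
# leg. Absolute segment angles: thigh/shank measured from the downward
# vertical with forward positive; foot long axis from the horizontal with
# toe-up positive. Knee flexion is zero at full extension, positive in
# flexion; ankle dorsiflexion positive.

coord_names <- c("trunk_x", "trunk_y", "trunk_rot",
                 "hip_r", "knee_r", "ankle_r", "hip_l", "knee_l", "ankle_l")

# direction of a thigh/shank segment axis (proximal -> distal)
seg_dir <- function(alpha) cbind(sin(alpha), -cos(alpha))
seg_dir_d <- function(alpha) cbind(cos(alpha), sin(alpha))
# foot long axis (ankle -> toe)
foot_dir <- function(gamma) cbind(cos(gamma), sin(gamma))

cross2 <- function(a, b) a[, 1] * b[, 2] - a[, 2] * b[, 1]

# Forward kinematics: per-segment COM positions, absolute angles, and joint
# positions, all n x 2 matrices / length-n vectors.
forward_kinematics <- function(model, q) {
  seg <- model$segments
  g <- function(nm) q[, nm]
  hip <- cbind(g("trunk_x"), g("trunk_y"))
  th <- g("trunk_rot")
  out <- list(joints = list(), coms = list(), angles = list())
  L <- function(nm) seg$length[match(nm, seg$name)]
  C <- function(nm) seg$com_offset[match(nm, seg$name)]
  # HAT extends upward from the hip point
  up <- cbind(sin(th), cos(th))
  out$coms$hat <- hip + C("hat") * up
  out$angles$hat <- th
  out$joints$hip_r <- out$joints$hip_l <- hip
  for (side in c("r", "l")) {
    a_th <- th + g(paste0("hip_", side))
    a_sh <- a_th - g(paste0("knee_", side))
    gam <- a_sh + g(paste0("ankle_", side))
    knee <- hip + L(paste0("thigh_", side)) * seg_dir(a_th)
    ankle <- knee + L(paste0("shank_", side)) * seg_dir(a_sh)
    out$joints[[paste0("knee_", side)]] <- knee
    out$joints[[paste0("ankle_", side)]] <- ankle
    out$coms[[paste0("thigh_", side)]] <- hip + C(paste0("thigh_", side)) * seg_dir(a_th)
    out$coms[[paste0("shank_", side)]] <- knee + C(paste0("shank_", side)) * seg_dir(a_sh)
    out$coms[[paste0("foot_", side)]] <- ankle + C(paste0("foot_", side)) * foot_dir(gam)
    out$angles[[paste0("thigh_", side)]] <- a_th
    out$angles[[paste0("shank_", side)]] <- a_sh
    out$angles[[paste0("foot_", side)]] <- gam
    out$joints[[paste0("toe_", side)]] <- ankle + L(paste0("foot_", side)) * foot_dir(gam)
  }
  out
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) filtering with a Butterworth design of the
#' configured order, the convention used for ground-reaction-force and
#' kinematic data prior to inverse dynamics.
#'
#' @param x signal vector (or matrix; columns filtered)
#' @param fc cutoff frequency, Hz (default 8)
#' @param fs sampling frequency, Hz
#' @param order filter order (default 4; applied twice by the zero-phase pass)
#' @return filtered signal, same length as input
#' @export
lowpass_filter <- function(x, fc = 8, fs, order = 4) {
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the cutoff frequency")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  one <- function(col) {
    # even-reflection padding suppresses the start/end transients of the
    # forward-backward pass
    n <- length(col)
    np <- min(n - 1, max(round(3 * fs / fc), 10))
    padded <- c(2 * col[1] - col[(np + 1):2], col, 2 * col[n] - col[(n - 1):(n - np)])
    signal::filtfilt(bf, padded)[(np + 1):(np + n)]
  }
  if (is.matrix(x)) return(apply(x, 2, one))
  one(x)
}

# Kinematic derivatives shared by the generator and inverse dynamics: COM
# accelerations and angular accelerations by central differences of the
# forward-kinematics trajectories.
kinematic_derivatives <- function(model, q, dt) {
  fk <- forward_kinematics(model, q)
  acc <- lapply(fk$coms, function(p) central_diff(central_diff(p, dt), dt))
  omega_dot <- lapply(fk$angles, function(a) central_diff(central_diff(a, dt), dt))
  list(fk = fk, acc = acc, omega_dot = omega_dot)
}

# Total external force (both feet combined) required for whole-body dynamic
# consistency, and the whole-body moment about the origin.
whole_body_wrench <- function(model, q, dt) {
  kd <- kinematic_derivatives(model, q, dt)
  seg <- model$segments
  gvec <- c(0, -model$gravity)
  n <- nrow(q)
  F <- matrix(0, n, 2)
  M <- numeric(n)
  for (nm in c("hat", seg$name[seg$name != "hat"])) {
    m <- seg$mass[match(nm, seg$name)]
    I <- seg$inertia_com[match(nm, seg$name)]
    r <- kd$fk$coms[[nm]]
    a <- kd$acc[[nm]]
    F <- F + m * (a - matrix(gvec, n, 2, byrow = TRUE))
    M <- M + I * kd$omega_dot[[nm]] +
      cross2(r, m * (a - matrix(gvec, n, 2, byrow = TRUE)))
  }
  list(force = F, moment_origin = M, kd = kd)
}

# Convert (fx, fy, cop_x) ground reaction samples into a wrench about the
# world origin; the center of pressure lies on the ground line y = 0.
grf_wrench <- function(grf) {
  F <- cbind(grf[, "fx"], grf[, "fy"])
  M <- grf[, "cop"] * grf[, "fy"]
  list(F = F, M = M)
}

#' Planar inverse dynamics of the lower limbs
#'
#' Net joint moments (generalized-coordinate convention: positive moment
#' drives the joint toward its positive coordinate) at the hip, knee and
#' ankle, from Newton-Euler balances of the distal subsystems with
#' center-of-mass accelerations obtained by central differences of the
#' forward-kinematics trajectories.
#'
#' @param model a `planar_model` (including any added mass)
#' @param kin list with `time` (uniform grid, s) and `q` (matrix with the
#'   nine coordinate columns, see package conventions)
#' @param grf right-foot ground reaction samples on the same grid: matrix
#'   with columns `fx`, `fy`, `cop` (N, N, m)
#' @param grf_left optional left-foot ground reaction samples
#' @return list with `time` and `moments` (matrix with columns `hip_r`,
#'   `knee_r`, `ankle_r` and the left-side analogues when `grf_left` given)
#' @export
inverse_dynamics <- function(model, kin, grf, grf_left = NULL) {
  q <- kin$q
  if (anyNA(q) || anyNA(grf)) stop("NaN in inverse dynamics inputs")
  dt <- kin$time[2] - kin$time[1]
  kd <- kinematic_derivatives(model, q, dt)
  sides <- if (is.null(grf_left)) "r" else c("r", "l")
  n <- nrow(q)
  seg <- model$segments
  gvec <- matrix(c(0, -model$gravity), n, 2, byrow = TRUE)
  cols <- as.vector(outer(c("hip_", "knee_", "ankle_"), sides, paste0))
  mom <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  for (side in sides) {
    wr <- grf_wrench(if (side == "r") grf else grf_left)
    chain <- list(
      hip = paste0(c("thigh_", "shank_", "foot_"), side),
      knee = paste0(c("shank_", "foot_"), side),
      ankle = paste0("foot_", side)
    )
    sgn <- c(hip = 1, knee = -1, ankle = 1)
    for (jn in names(chain)) {
      jpos <- kd$fk$joints[[paste0(jn, "_", side)]]
      tot <- numeric(n)
      for (nm in chain[[jn]]) {
        i <- match(nm, seg$name)
        mi <- seg$mass[i]; Ii <- seg$inertia_com[i]
        angle_key <- sub(paste0("_", side), "", nm)
        angle_key <- paste0(angle_key, "_", side)
        r <- kd$fk$coms[[nm]]
        a <- kd$acc[[nm]]
        tot <- tot + Ii * kd$omega_dot[[angle_key]] +
          cross2(r - jpos, mi * (a - gvec))
      }
      # external GRF acts on this side's foot
      tot <- tot - (wr$M - cross2(jpos, wr$F))
      mom[, paste0(jn, "_", side)] <- sgn[[jn]] * tot
    }
  }
  list(time = kin$time, moments = mom)
}

#' Intersegmental (muscle-free) axial knee reaction force
#'
#' Free-body analysis of the foot+shank subsystem under the ground reaction
#' force, gravity and inertial loads, with pure torques at the joints: the
#' knee joint reaction force on the tibia, projected onto the tibia long
#' axis (compression positive). This is the skeleton-only contribution to
#' tibiofemoral contact force and is invariant to muscle parameters.
#'
#' @inheritParams inverse_dynamics
#' @param side `"r"` (default) or `"l"`
#' @return list with `time`, `axial` (N, compression positive) and `force`
#'   (n x 2 matrix, reaction force of femur on tibia, world frame)
#' @export
intersegmental_reaction <- function(model, kin, grf, side = "r") {
  q <- kin$q
  dt <- kin$time[2] - kin$time[1]
  kd <- kinematic_derivatives(model, q, dt)
  n <- nrow(q)
  seg <- model$segments
  gvec <- matrix(c(0, -model$gravity), n, 2, byrow = TRUE)
  wr <- grf_wrench(grf)
  F <- -wr$F
  for (nm in paste0(c("shank_", "foot_"), side)) {
    i <- match(nm, seg$name)
    F <- F + seg$mass[i] * (kd$acc[[nm]] - gvec)
  }
  axis <- seg_dir(kd$fk$angles[[paste0("shank_", side)]])  # knee -> ankle
  list(time = kin$time, axial = rowSums(F * axis), force = F)
}

# --- single-state algebraic dynamics (used for the forward/inverse
# --- round-trip oracle on a hanging leg with the trunk clamped)

# Inverse dynamics of the right leg at one state, trunk fixed at the origin.
id_leg_state <- function(model, q, qd, qdd) {
  seg <- model$segments
  g <- model$gravity
  L <- function(nm) seg$length[match(nm, seg$name)]
  C <- function(nm) seg$com_offset[match(nm, seg$name)]
  Mm <- function(nm) seg$mass[match(nm, seg$name)]
  Im <- function(nm) seg$inertia_com[match(nm, seg$name)]
  al <- c(q[1], q[1] - q[2], q[1] - q[2])          # thigh, shank abs angles
  gam <- q[1] - q[2] + q[3]
  ald <- c(qd[1], qd[1] - qd[2], qd[1] - qd[2] + qd[3])
  aldd <- c(qdd[1], qdd[1] - qdd[2], qdd[1] - qdd[2] + qdd[3])
  d <- function(a) c(sin(a), -cos(a)); dp <- function(a) c(cos(a), sin(a))
  f <- function(a) c(cos(a), sin(a)); fp <- function(a) c(-sin(a), cos(a))
  # positions
  hip <- c(0, 0)
  knee <- hip + L("thigh_r") * d(al[1])
  ankle <- knee + L("shank_r") * d(al[2])
  # com kinematics by analytic propagation
  pt <- function(base, ab, aab, cc, dirf, dirfp, a, adot, addot) {
    pos <- base$pos + cc * dirf(a)
    acc <- base$acc + cc * (addot * dirfp(a) - adot^2 * dirf(a))
    list(pos = pos, acc = acc)
  }
  base0 <- list(pos = hip, acc = c(0, 0))
  th <- pt(base0, NULL, NULL, C("thigh_r"), d, dp, al[1], ald[1], aldd[1])
  kneept <- pt(base0, NULL, NULL, L("thigh_r"), d, dp, al[1], ald[1], aldd[1])
  sh <- list(pos = kneept$pos + C("shank_r") * d(al[2]),
             acc = kneept$acc + C("shank_r") * (aldd[2] * dp(al[2]) - ald[2]^2 * d(al[2])))
  anklept <- list(pos = kneept$pos + L("shank_r") * d(al[2]),
                  acc = kneept$acc + L("shank_r") * (aldd[2] * dp(al[2]) - ald[2]^2 * d(al[2])))
  gamd <- ald[3]; gamdd <- aldd[3]
  ft <- list(pos = anklept$pos + C("foot_r") * f(gam),
             acc = anklept$acc + C("foot_r") * (gamdd * fp(gam) - gamd^2 * f(gam)))
  gvec <- c(0, -g)
  crossz <- function(a, b) a[1] * b[2] - a[2] * b[1]
  segs <- list(
    thigh = list(m = Mm("thigh_r"), I = Im("thigh_r"), com = th, wd = aldd[1]),
    shank = list(m = Mm("shank_r"), I = Im("shank_r"), com = sh, wd = aldd[2]),
    foot = list(m = Mm("foot_r"), I = Im("foot_r"), com = ft, wd = gamdd))
  tau_at <- function(jpos, members, sgn) {
    tot <- 0
    for (s in members) {
      tot <- tot + s$I * s$wd + crossz(s$com$pos - jpos, s$m * (s$com$acc - gvec))
    }
    sgn * tot
  }
  c(hip = tau_at(hip, segs, 1),
    knee = tau_at(kneept$pos, segs[c("shank", "foot")], -1),
    ankle = tau_at(anklept$pos, segs["foot"], 1))
}

# Forward dynamics of the hanging right leg (trunk clamped): RK4 integration
# with the mass matrix and bias vector extracted from id_leg_state.
simulate_leg <- function(model, tau_fun, q0, qd0, t_end, dt = 1e-3) {
  deriv <- function(t, q, qd) {
    bias <- id_leg_state(model, q, qd, c(0, 0, 0))
    M <- sapply(1:3, function(i) {
      ei <- numeric(3); ei[i] <- 1
      id_leg_state(model, q, rep(0, 3), ei) - id_leg_state(model, q, rep(0, 3), c(0, 0, 0))
    })
    qdd <- solve(M, tau_fun(t) - bias)
    list(qd = qd, qdd = qdd)
  }
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  Q <- matrix(0, n, 3); QD <- matrix(0, n, 3); QDD <- matrix(0, n, 3)
  q <- q0; qd <- qd0
  for (k in seq_len(n)) {
    d1 <- deriv(times[k], q, qd)
    Q[k, ] <- q; QD[k, ] <- qd; QDD[k, ] <- d1$qdd
    if (k == n) break
    d2 <- deriv(times[k] + dt / 2, q + dt / 2 * d1$qd, qd + dt / 2 * d1$qdd)
    d3 <- deriv(times[k] + dt / 2, q + dt / 2 * d2$qd, qd + dt / 2 * d2$qdd)
    d4 <- deriv(times[k] + dt, q + dt * d3$qd, qd + dt * d3$qdd)
    q <- q + dt / 6 * (d1$qd + 2 * d2$qd + 2 * d3$qd + d4$qd)
    qd <- qd + dt / 6 * (d1$qdd + 2 * d2$qdd + 2 * d3$qdd + d4$qdd)
  }
  list(time = times, q = Q, qd = QD, qdd = QDD)
}
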