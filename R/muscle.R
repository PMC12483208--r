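# Hill-type muscle mechanics: first-order activation dynamics with distinct
# activation/deactivation time constants, rigid-tendon force generation with
# Gaussian active force-length, hyperbolic force-velocity and exponential-free
# passive curves, polynomial moment arms, and the fraction of each
# knee-spanning muscle's force directed along the tibia long axis.

#' First-order activation dynamics
#'
#' Integrates `da/dt = (e - a)/tau` with `tau = tau_act` while excitation
#' exceeds activation and `tau = tau_deact` otherwise, using the trapezoidal
#' rule. Output is clipped to `[0, 1]`.
#'
#' @param e excitation series in `[0, 1]`
#' @param a0 initial activation
#' @param dt time step in seconds
#' @param tau_act,tau_deact activation/deactivation time constants (s),
#'   nominal 15 and 60 ms
#' @return activation series of the same length as `e`
#' @export
activation_dynamics <- function(e, a0 = e[1], dt, tau_act = 0.015, tau_deact = 0.060) {
  if (any(e < -1e-12 | e > 1 + 1e-12)) stop("excitations must lie in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  if (dt >= min(tau_act, tau_deact) / 2)
    warning("dt >= min(tau)/2: trapezoidal activation integration may be inaccurate")
  n <- length(e)
  a <- numeric(n)
  a[1] <- clamp(a0, 0, 1)
  tau_of <- function(ek, ak) if (ek > ak) tau_act else tau_deact
  for (k in seq_len(n - 1)) {
    tk <- tau_of(e[k], a[k])
    # tau at k+1 depends on a[k+1]; one predictor-corrector pass resolves it
    tk1 <- tau_of(e[k + 1], a[k])
    for (it in 1:2) {
      anew <- (a[k] * (1 - dt / (2 * tk)) + dt / 2 * (e[k] / tk + e[k + 1] / tk1)) /
        (1 + dt / (2 * tk1))
      tnew <- tau_of(e[k + 1], anew)
      if (tnew == tk1) break
      tk1 <- tnew
    }
    a[k + 1] <- clamp(anew, 0, 1)
  }
  a
}

# Invert first-order activation dynamics: given a smooth activation series,
# return the excitation e = a + tau(da/dt) * da/dt that reproduces it (to
# discretization accuracy) under the same dynamics. The derivative is taken
# by central differences: the exact inverse of the trapezoidal recursion is
# marginally stable and rings, while the smooth inverse commits only an
# O(dt^2) defect. Used by the synthetic-truth channel.
excitation_from_activation <- function(a, dt, tau_act = 0.015, tau_deact = 0.060) {
  f <- central_diff(a, dt)
  tau <- ifelse(f > 0, tau_act, tau_deact)
  clamp(a + tau * f, 0, 1)
}

force_length <- function(lnorm, width = 0.45) exp(-((lnorm - 1) / width)^2)

force_velocity <- function(vnorm, conc = 0.25, ecc_max = 1.5) {
  out <- numeric(length(vnorm))
  neg <- vnorm < 0
  v <- pmax(vnorm[neg], -1)
  out[neg] <- (1 + v) / (1 - v / conc)
  vp <- vnorm[!neg]
  # eccentric branch matched to the concentric slope 1/conc + 1 at v = 0
  s <- 1 / conc + 1
  h <- (ecc_max - 1) / s
  out[!neg] <- 1 + (ecc_max - 1) * vp / (vp + h)
  out
}

force_passive <- function(lnorm, strain = 0.6) {
  ifelse(lnorm > 1, ((lnorm - 1) / strain)^2, 0)
}

#' Moment arm of a muscle-tendon unit at a joint
#'
#' Evaluates the configured moment-arm polynomial at the joint angle. The
#' sign convention is that a positive arm produces a moment toward the
#' positive joint coordinate (hip flexion, knee flexion, ankle dorsiflexion).
#'
#' @param mtu one element of `model$muscles`
#' @param joint `"hip"`, `"knee"` or `"ankle"`
#' @param q joint angle(s) in radians
#' @return moment arm(s) in meters
#' @export
moment_arm <- function(mtu, joint, q) {
  coefs <- mtu$arms[[joint]]
  if (is.null(coefs)) stop("muscle does not span joint '", joint, "'")
  polyval_asc(coefs, q)
}

# Musculotendon length relative to the reference pose: the moment arm is the
# negative derivative of musculotendon length with respect to the joint angle.
mtu_length <- function(mtu, q) {
  # q: named list of joint angle vectors for the spanned joints
  l <- rep(mtu$lmt_ref, length(q[[1]]))
  for (j in names(mtu$arms)) {
    anti <- poly_antideriv(mtu$arms[[j]])
    l <- l - (polyval_asc(anti, q[[j]]) - polyval_asc(anti, mtu$q_ref[[j]]))
  }
  l
}

# Rigid-tendon fiber kinematics from joint angles/velocities.
mtu_fiber_state <- function(mtu, q, qdot, curves) {
  lmt <- mtu_length(mtu, q)
  vmt <- rep(0, length(q[[1]]))
  for (j in names(mtu$arms)) vmt <- vmt - moment_arm(mtu, j, q[[j]]) * qdot[[j]]
  h <- mtu$l_opt * sin(mtu$pen_opt)
  l_along <- lmt - mtu$l_slack
  if (any(l_along <= 0))
    stop("non-positive fiber length for muscle '", mtu$name %||% "?",
         "' within the requested joint range")
  l_fib <- sqrt(l_along^2 + h^2)
  cosp <- l_along / l_fib
  lnorm <- l_fib / mtu$l_opt
  vnorm <- cosp * vmt / (curves$vmax * mtu$l_opt)
  list(lnorm = lnorm, vnorm = vnorm, cosp = cosp,
       fl = force_length(lnorm, curves$fl_width),
       fv = force_velocity(vnorm, curves$fv_conc, curves$fv_ecc_max),
       fpass = force_passive(lnorm, curves$fpass_strain))
}

#' Rigid-tendon muscle force
#'
#' `F = f_max * (a * f_L * f_V + f_pass) * cos(pennation)` with fiber length
#' and velocity obtained from the musculotendon length (moment-arm integral)
#' minus tendon slack length, treating the tendon as inextensible.
#'
#' @param mtu one element of `model$muscles`
#' @param q named list of spanned joint angles (rad)
#' @param qdot named list of spanned joint angular velocities (rad/s)
#' @param a activation in `[0, 1]`
#' @param curves muscle curve constants, default from [default_model_config()]
#' @return tendon force in newtons (vectorized over time)
#' @export
rigid_tendon_force <- function(mtu, q, qdot, a, curves = default_model_config()$curves) {
  st <- mtu_fiber_state(mtu, q, qdot, curves)
  mtu$f_max * (a * st$fl * st$fv + st$fpass) * st$cosp
}

#' Quasi-static elastic-tendon muscle force
#'
#' Fidelity-check variant of [rigid_tendon_force()]: the tendon stretches by
#' the configured strain (default 4%) at one normalized tendon force, and
#' the force is found by fixed-point iteration of the force balance at each
#' sample. For walking-scale forces it differs from the rigid-tendon force
#' by a few percent; the rigid tendon is the default because it keeps force
#' affine in activation.
#'
#' @inheritParams rigid_tendon_force
#' @param tol fixed-point tolerance in normalized force
#' @return tendon force in newtons (vectorized over time)
#' @export
elastic_tendon_force <- function(mtu, q, qdot, a,
                                 curves = default_model_config()$curves,
                                 tol = 1e-8) {
  lmt <- mtu_length(mtu, q)
  vmt <- rep(0, length(q[[1]]))
  for (j in names(mtu$arms)) vmt <- vmt - moment_arm(mtu, j, q[[j]]) * qdot[[j]]
  h <- mtu$l_opt * sin(mtu$pen_opt)
  strain <- curves$tendon_strain
  fn <- rep(0.2, length(lmt))  # normalized tendon force
  for (it in 1:200) {
    lslack_eff <- mtu$l_slack * (1 + strain * fn)
    l_along <- pmax(lmt - lslack_eff, 1e-6)
    l_fib <- sqrt(l_along^2 + h^2)
    cosp <- l_along / l_fib
    lnorm <- l_fib / mtu$l_opt
    vnorm <- cosp * vmt / (curves$vmax * mtu$l_opt)
    f_new <- (a * force_length(lnorm, curves$fl_width) *
                force_velocity(vnorm, curves$fv_conc, curves$fv_ecc_max) +
                force_passive(lnorm, curves$fpass_strain)) * cosp
    if (max(abs(f_new - fn)) < tol) {
      fn <- f_new
      break
    }
    fn <- 0.5 * fn + 0.5 * f_new  # damped fixed point
  }
  mtu$f_max * fn
}

#' Compressive (tibia-axial) component of a muscle force
#'
#' Multiplies the muscle force by the configured compressive-fraction
#' polynomial in knee angle (which encodes, for the quadriceps, the
#' patellar-tendon redirection). Muscles that do not span the knee
#' contribute zero.
#'
#' @param mtu one element of `model$muscles`
#' @param knee_angle knee flexion angle(s), rad
#' @param force muscle tendon force(s), N
#' @return compressive force(s) along the tibia axis, N
#' @export
compressive_component <- function(mtu, knee_angle, force) {
  if (is.null(mtu$comp)) return(rep(0, length(force)))
  frac <- polyval_asc(mtu$comp, knee_angle)
  frac * force
}

# Active gain and passive contribution of every muscle at every sample:
# with a rigid tendon, tendon force is affine in activation,
#   F_m(t) = k_m(t) * a_m(t) + p_m(t).
# Returns per-muscle gains plus per-DOF moment-arm matrices.
muscle_gains <- function(model, q, qdot) {
  curves <- model$config$curves
  n <- length(q$knee)
  mus <- model$muscles
  nm <- names(mus)
  K <- P <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  arms <- list(hip = K, knee = K, ankle = K)
  comp <- K
  for (m in seq_along(nm)) {
    mu <- mus[[m]]
    mu$name <- nm[m]
    spans <- names(mu$arms)
    st <- mtu_fiber_state(mu, q[spans], qdot[spans], curves)
    K[, m] <- mu$f_max * st$fl * st$fv * st$cosp
    P[, m] <- mu$f_max * st$fpass * st$cosp
    for (j in spans) arms[[j]][, m] <- moment_arm(mu, j, q[[j]])
    if (!is.null(mu$comp)) comp[, m] <- polyval_asc(mu$comp, q$knee)
  }
  list(K = K, P = P, arms = arms, comp = comp)
}
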