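# Two-stage EMG-informed muscle redundancy optimization over one stance
# phase. Direct transcription on N collocation nodes with trapezoidal
# activation dynamics; with a rigid tendon the muscle moment contributions
# are affine in activation, so reserves are eliminated analytically
# (r_dof = M_ID - muscle moment) and the problem reduces to a
# box-constrained convex quadratic program in the excitations, solved by
# projected quasi-Newton iterations. Calibration additionally estimates a
# bounded EMG scale factor per measured channel by coordinate descent with
# multistarts.

# Build the affine map a = L e + u a_init of trapezoidal activation
# dynamics for a fixed activation/deactivation switching pattern, where
# a_init is the activation state carried into the first node.
activation_map <- function(tau_nodes, dt) {
  n <- length(tau_nodes)
  L <- matrix(0, n, n)
  u <- numeric(n)
  u[1] <- 1
  for (k in seq_len(n - 1)) {
    ck <- dt / (2 * tau_nodes[k])
    ck1 <- dt / (2 * tau_nodes[k + 1])
    den <- 1 + ck1
    L[k + 1, ] <- (1 - ck) / den * L[k, ]
    L[k + 1, k] <- L[k + 1, k] + ck / den
    L[k + 1, k + 1] <- ck1 / den
    u[k + 1] <- (1 - ck) / den * u[k]
  }
  list(L = L, u = u)
}

# Non-warning trapezoidal activation integration with adaptive switching.
act_integrate <- function(e, dt, tau_act, tau_deact, a0 = e[1]) {
  n <- length(e)
  a <- numeric(n)
  a[1] <- clamp(a0, 0, 1)
  tau <- numeric(n)
  tau[1] <- if (e[1] > a[1]) tau_act else tau_deact
  for (k in seq_len(n - 1)) {
    tk <- if (e[k] > a[k]) tau_act else tau_deact
    tk1 <- if (e[k + 1] > a[k]) tau_act else tau_deact
    for (it in 1:2) {
      anew <- (a[k] * (1 - dt / (2 * tk)) + dt / 2 * (e[k] / tk + e[k + 1] / tk1)) /
        (1 + dt / (2 * tk1))
      tnew <- if (e[k + 1] > anew) tau_act else tau_deact
      if (tnew == tk1) break
      tk1 <- tnew
    }
    a[k + 1] <- clamp(anew, 0, 1)
    tau[k + 1] <- tk1
  }
  list(a = a, tau = tau)
}

#' Assemble the discretized EMG-informed optimal control problem
#'
#' Transcribes one stance phase onto `n_nodes` collocation nodes:
#' prescribed kinematics and net joint moments, per-node muscle force gains
#' (rigid tendon), trapezoidal activation dynamics, reference excitations
#' for EMG tracking, and the stage weights
#' `J = w1*J_excitation + w2*J_knee/ankle + w3*J_reserve + w4*J_EMG`.
#'
#' @param trial a `gait_trial`
#' @param model the loaded `planar_model` for this trial
#' @param reference matrix of reference excitations for the 12 muscles on
#'   the trial's 100 Hz grid (delayed, normalized, mapped), or `NULL`
#' @param weights list with `w1`, `w2`, `w3`, `w4`
#' @param stage `"calibration"` or `"execution"`
#' @param stride which detected stance phase to transcribe (default 1)
#' @param config model configuration
#' @return problem list (class `ocp_problem`) with node times, gains, net
#'   moments, reference, quadrature weights and transcription metadata
#'   (`n_variables`, `n_constraints`)
#' @export
assemble_ocp <- function(trial, model, reference, weights,
                         stage = c("execution", "calibration"), stride = 1,
                         config = default_model_config()) {
  stage <- match.arg(stage)
  ev <- trial$events[stride, ]
  if (is.na(ev$heel_strike)) stop("assembly error: no stance phase ", stride)
  # collocate on the native kinematic samples inside the stance window: the
  # moment and gain evaluations then involve no cross-grid interpolation
  idx <- which(trial$time >= ev$heel_strike & trial$time <= ev$toe_off)
  if (length(idx) < 10) stop("assembly error: stance window too short")
  times <- trial$time[idx]
  N <- length(idx)
  dtn <- times[2] - times[1]
  dt100 <- 1 / trial$fs
  kin <- list(time = trial$time, q = trial$q)
  id <- inverse_dynamics(model, kin, trial$grf)
  tau <- id$moments[idx, c("hip_r", "knee_r", "ankle_r")]
  colnames(tau) <- c("hip", "knee", "ankle")
  qd100 <- central_diff(trial$q, dt100)
  qn <- list(hip = trial$q[idx, "hip_r"], knee = trial$q[idx, "knee_r"],
             ankle = trial$q[idx, "ankle_r"])
  qdn <- list(hip = qd100[idx, "hip_r"], knee = qd100[idx, "knee_r"],
              ankle = qd100[idx, "ankle_r"])
  gains <- muscle_gains(model, qn, qdn)
  nmus <- colnames(gains$K)
  ref <- if (is.null(reference)) NULL else {
    sapply(nmus, function(nm) interp1(trial$time, reference[, nm], times))
  }
  # initial activation state: the muscles enter stance with late-swing
  # activation history, obtained by integrating the (unscaled) reference
  # over a lead-in window; scale factors multiply it linearly
  a_init_base <- stats::setNames(rep(0, length(nmus)), nmus)
  if (!is.null(reference)) {
    lead <- which(trial$time >= ev$heel_strike - 0.5 & trial$time <= ev$heel_strike)
    if (length(lead) > 3) {
      for (nm in nmus) {
        ai <- act_integrate(reference[lead, nm], dt100,
                            config$activation$tau_act, config$activation$tau_deact)
        a_init_base[nm] <- ai$a[length(lead)]
      }
    }
  }
  n_mus <- length(nmus)
  structure(list(
    stage = stage, times = times, dt = dtn, weights = weights,
    tau = tau, gains = gains, ref = ref, muscles = nmus,
    a_init_base = a_init_base,
    wq = trapz_weights(N, dtn),
    channel_map = config$emg$channel_map,
    measured = config$emg$measured,
    act = config$activation,
    n_nodes = N,
    n_variables = N * (2 * n_mus + 3) + if (stage == "calibration") length(config$emg$measured) else 0,
    n_constraints = n_mus * N + 3 * N,
    maxit = config$ocp$maxit
  ), class = "ocp_problem")
}

# reference matrix for the 12 muscles given per-channel scale factors
scaled_reference <- function(pr, s) {
  ref <- pr$ref
  for (m in pr$muscles) {
    src <- if (m %in% names(pr$channel_map)) pr$channel_map[[m]] else m
    ref[, m] <- pr$ref[, m] * s[[src]]
  }
  ref
}

# initial activations scaled consistently with the reference
scaled_init <- function(pr, s) {
  ai <- pr$a_init_base
  for (m in pr$muscles) {
    src <- if (m %in% names(pr$channel_map)) pr$channel_map[[m]] else m
    ai[m] <- pr$a_init_base[m] * s[[src]]
  }
  ai
}

# Exact solver for min x'Hx/2 - c'x subject to box bounds, by projected
# Newton / active-set iterations: variables pinned at a bound with an
# outward gradient are frozen, the free subsystem is solved by Cholesky,
# and the step is truncated at the first blocking bound.
solve_box_qp <- function(H, c, lower, upper, x0, tol = 1e-8, maxit = 40L) {
  x <- clamp(x0, lower, upper)
  gscale <- 1 + max(abs(c))
  Jval <- function(v) 0.5 * sum(v * as.vector(H %*% v)) - sum(c * v)
  J <- Jval(x)
  converged <- FALSE
  kkt <- Inf
  it <- 0L
  for (it in seq_len(maxit)) {
    g <- as.vector(H %*% x) - c
    at_lo <- x <= lower + 1e-12
    at_hi <- x >= upper - 1e-12
    free <- !((at_lo & g > 0) | (at_hi & g < 0))
    kkt <- if (any(free)) max(abs(g[free])) / gscale else 0
    if (kkt < tol) {
      converged <- TRUE
      break
    }
    # two-metric projection (Bertsekas): the Newton system couples only the
    # strictly interior variables; free variables sitting at a bound (with
    # an inward gradient) take diagonally scaled gradient steps, so the
    # combined direction is always a descent direction for the projection
    eps_b <- 1e-9
    interior <- free & (x > lower + eps_b) & (x < upper - eps_b)
    dirn <- numeric(length(x))
    if (any(interior)) {
      Hii <- H[interior, interior, drop = FALSE]
      dirn[interior] <- tryCatch({
        R <- chol(Hii)
        -backsolve(R, forwardsolve(t(R), g[interior]))
      }, error = function(e) -g[interior] / pmax(diag(Hii), 1e-12))
    }
    nearb <- free & !interior
    dirn[nearb] <- -g[nearb] / pmax(diag(H)[nearb], 1e-12)
    alpha <- 1
    improved <- FALSE
    for (bt in 1:30) {
      xt <- clamp(x + alpha * dirn, lower, upper)
      Jt <- Jval(xt)
      if (Jt < J - 1e-15 * abs(J)) {
        x <- xt
        J <- Jt
        improved <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!improved) {
      converged <- kkt < 1e-6
      break
    }
  }
  list(x = x, converged = converged, kkt = kkt, iterations = it)
}

# Solve the box-constrained QP in the excitations for a fixed reference.
# `qp` optionally carries the precomputed quadratic form (valid for reuse
# across scale-factor iterations on the same stride: the switching pattern
# is invariant to positive rescaling of the reference).
solve_qp_stage <- function(pr, ref12, e0 = NULL, qp = NULL, a_init = NULL) {
  N <- pr$n_nodes
  nm <- length(pr$muscles)
  w <- pr$weights
  wq <- pr$wq
  K <- pr$gains$K; P <- pr$gains$P; arms <- pr$gains$arms
  Kd <- list(hip = K * arms$hip, knee = K * arms$knee, ankle = K * arms$ankle)
  Pd <- sapply(names(Kd), function(d) rowSums(P * arms[[d]]))
  wd <- c(hip = w$w3, knee = w$w2, ankle = w$w2)
  if (is.null(e0)) e0 <- if (is.null(ref12)) matrix(0.05, N, nm) else clamp(ref12, 0, 1)
  tauA <- pr$act$tau_act; tauD <- pr$act$tau_deact
  # the activation/deactivation switching pattern is fixed from the
  # reference excitations (or the warm start): re-deriving it from the
  # current iterate makes the quadratic model non-stationary and can
  # limit-cycle between passes
  patt_src <- if (!is.null(pr$ref)) pr$ref else e0
  patt_a0 <- if (!is.null(pr$ref)) pr$a_init_base else e0[1, ]
  Ls <- if (!is.null(qp)) qp$Ls else {
    lapply(seq_len(nm), function(m) {
      patt <- act_integrate(patt_src[, m], pr$dt, tauA, tauD, a0 = patt_a0[m])$tau
      activation_map(patt, pr$dt)
    })
  }
  if (is.null(a_init)) a_init <- stats::setNames(e0[1, ], pr$muscles)
  amap <- function(E) {
    A <- E
    for (m in seq_len(nm)) A[, m] <- Ls[[m]]$L %*% E[, m] + Ls[[m]]$u * a_init[m]
    A
  }
  obj_terms <- function(E) {
    A <- amap(E)
    r <- sapply(names(Kd), function(d) pr$tau[, d] - rowSums(Kd[[d]] * A) - Pd[, d])
    J_exc <- sum(wq * rowSums(E^2))
    J_ka <- sum(wq * (r[, "knee"]^2 + r[, "ankle"]^2))
    J_res <- sum(wq * r[, "hip"]^2)
    J_emg <- if (is.null(ref12)) 0 else sum(wq * rowSums((E - ref12)^2))
    list(A = A, r = r, J_exc = J_exc, J_ka = J_ka, J_res = J_res, J_emg = J_emg,
         total = w$w1 * J_exc + w$w2 * J_ka + w$w3 * J_res + w$w4 * J_emg)
  }
  # exact quadratic form J(x) = x' H x / 2 - c' x + const for x = vec(E):
  # the stiff reserve terms make iterative first-order solvers too noisy to
  # resolve the calibration objective, so the box QP is solved exactly
  n <- N * nm
  if (is.null(qp)) {
    H <- diag(rep(2 * wq * (w$w1 + if (is.null(ref12)) 0 else w$w4), nm), n, n)
    Bs <- list()
    for (d in names(Kd)) {
      B <- matrix(0, N, n)
      for (m in seq_len(nm)) B[, ((m - 1) * N + 1):(m * N)] <- Kd[[d]][, m] * Ls[[m]]$L
      H <- H + 2 * wd[[d]] * crossprod(B, wq * B)
      Bs[[d]] <- B
    }
    qp <- list(H = H, Bs = Bs, Ls = Ls)
  }
  # initial-state contribution to the per-DOF moment constant
  Uinit <- sapply(seq_len(nm), function(m) Ls[[m]]$u * a_init[m])
  cvec <- if (is.null(ref12)) rep(0, n) else 2 * w$w4 * rep(wq, nm) * as.vector(ref12)
  for (d in names(Kd)) {
    y <- pr$tau[, d] - Pd[, d] - rowSums(Kd[[d]] * Uinit)
    cvec <- cvec + 2 * wd[[d]] * crossprod(qp$Bs[[d]], wq * y)
  }
  sol_qp <- solve_box_qp(qp$H, as.vector(cvec), rep(0, n), rep(1, n),
                         as.vector(clamp(e0, 0, 1)))
  E <- matrix(sol_qp$x, N, nm)
  total_counts <- sol_qp$iterations
  ot <- obj_terms(E)
  A <- ot$A
  dimnames(E) <- dimnames(A) <- list(NULL, pr$muscles)
  # residual of the trapezoidal dynamics under the solve's (fixed) switching
  # pattern, and the gap to fully adaptive switching (plateaus where
  # excitation and activation nearly coincide can flip the time constant)
  dyn_res <- 0
  pattern_gap <- 0
  for (m in seq_len(nm)) {
    ai <- act_integrate(E[, m], pr$dt, tauA, tauD, a0 = a_init[m])$a
    pattern_gap <- max(pattern_gap, max(abs(ai - A[, m])))
    # recursion residual under the map actually used
    res_m <- max(abs(A[, m] - (Ls[[m]]$L %*% E[, m] + Ls[[m]]$u * a_init[m])))
    dyn_res <- max(dyn_res, res_m)
  }
  structure(list(
    e = E, a = A, r = ot$r, times = pr$times, problem = pr, qp = qp,
    objective = list(total = ot$total, J_excitation = ot$J_exc,
                     J_knee_ankle = ot$J_ka, J_reserve = ot$J_res,
                     J_EMG = ot$J_emg, weights = pr$weights),
    diagnostics = list(fn_evals = total_counts,
                       convergence = if (sol_qp$converged) 0L else 1L,
                       kkt_residual = sol_qp$kkt,
                       dynamics_residual = dyn_res,
                       pattern_gap = pattern_gap,
                       moment_residual = 0)  # reserves close the moments exactly
  ), class = "ocp_solution")
}

#' Calibrate EMG scale factors on unloaded strides
#'
#' For each stride, jointly estimates adjusted excitations and one EMG scale
#' factor per measured channel (bounds 0.5-1) by coordinate descent (QP in
#' the excitations for fixed scales; closed-form bounded update of the
#' scales), started from multiple initial scale values; the best objective
#' is kept. Per-stride scale factors are averaged per muscle.
#'
#' @param strides list of assembled calibration problems
#'   ([assemble_ocp()] with the unscaled reference and stage "calibration")
#' @param weights calibration weights (default from configuration)
#' @param config model configuration
#' @return list of class `scale_factors`: `s` (named, in `[0.5, 1]`),
#'   `per_stride` (matrix), `n_converged`
#' @export
solve_calibration <- function(strides, weights = default_model_config()$weights$calibration,
                              config = default_model_config()) {
  measured <- config$emg$measured
  bounds <- config$ocp$s_bounds
  per_stride <- matrix(NA_real_, length(strides), length(measured),
                       dimnames = list(NULL, measured))
  groups <- lapply(measured, function(ch) {
    c(ch, names(config$emg$channel_map)[config$emg$channel_map == ch])
  })
  names(groups) <- measured
  n_ok <- 0
  for (i in seq_along(strides)) {
    pr <- strides[[i]]
    best <- NULL
    qp_cache <- NULL
    e_warm <- NULL  # warm start carries across multistarts: the inner QP is convex
    for (s0 in config$ocp$multistart) {
      s <- stats::setNames(rep(s0, length(measured)), measured)
      sol <- NULL
      for (it in seq_len(config$ocp$cd_maxit)) {
        ref12 <- scaled_reference(pr, s)
        sol <- solve_qp_stage(pr, ref12, e0 = e_warm, qp = qp_cache,
                              a_init = scaled_init(pr, s))
        qp_cache <- sol$qp
        e_warm <- sol$e
        s_new <- s
        for (ch in measured) {
          g <- groups[[ch]]
          num <- sum(pr$wq * rowSums(sol$e[, g, drop = FALSE] * pr$ref[, g, drop = FALSE]))
          den <- sum(pr$wq * rowSums(pr$ref[, g, drop = FALSE]^2))
          s_new[ch] <- if (den > 1e-12) clamp(num / den, bounds[1], bounds[2]) else s[ch]
        }
        if (max(abs(s_new - s)) < config$ocp$cd_tol) {
          s <- s_new
          break
        }
        s <- s_new
      }
      ref12 <- scaled_reference(pr, s)
      Jfin <- solve_qp_stage(pr, ref12, e0 = e_warm, qp = qp_cache,
                             a_init = scaled_init(pr, s))$objective$total
      if (is.null(best) || Jfin < best$J) best <- list(s = s, J = Jfin)
    }
    if (!is.null(best)) {
      per_stride[i, ] <- best$s
      n_ok <- n_ok + 1
    } else warning("calibration stride ", i, " did not converge; dropped")
  }
  if (n_ok == 0) stop("calibration error: no stride converged")
  s_mean <- clamp(colMeans(per_stride, na.rm = TRUE), bounds[1], bounds[2])
  structure(list(s = s_mean, per_stride = per_stride, n_converged = n_ok),
            class = "scale_factors")
}

#' Solve the Execution stage for one stance phase
#'
#' Scales the reference EMG by the calibrated factors, solves the QP for
#' adjusted excitations and reserve torques, and attaches solver
#' diagnostics.
#'
#' @param problem an assembled problem ([assemble_ocp()], stage "execution")
#' @param scale_factors a `scale_factors` object (or named vector)
#' @param weights execution weights (default from configuration)
#' @return an `ocp_solution` with excitations `e`, activations `a`, reserve
#'   torques `r` (N x 3: hip, knee, ankle), objective breakdown and
#'   diagnostics
#' @export
solve_execution <- function(problem, scale_factors,
                            weights = default_model_config()$weights$execution) {
  s <- if (inherits(scale_factors, "scale_factors")) scale_factors$s else scale_factors
  problem$weights <- weights
  ref12 <- scaled_reference(problem, s)
  sol <- solve_qp_stage(problem, ref12, a_init = scaled_init(problem, s))
  sol$scale_factors <- s
  sol$reference <- ref12
  if (sol$diagnostics$kkt_residual > 1e-5)
    warning("execution solve: KKT residual ",
            signif(sol$diagnostics$kkt_residual, 3),
            " above tolerance; solution may be inaccurate")
  sol
}

#' Root-mean-square EMG tracking error in the region of interest
#'
#' RMS difference between adjusted excitations and the (scaled, delayed)
#' reference per muscle over the stance region of interest, averaged across
#' muscles with a reference.
#'
#' @param solution an `ocp_solution`
#' @param reference reference matrix (default the one stored in the solution)
#' @param roi percent-stance window, default 10-90
#' @return average RMS tracking error (excitation units)
#' @export
tracking_rmse <- function(solution, reference = solution$reference, roi = c(10, 90)) {
  times <- solution$times
  pct <- (times - times[1]) / diff(range(times)) * 100
  i <- pct >= roi[1] & pct <= roi[2]
  if (!any(i)) stop("empty region of interest")
  rms <- sqrt(colMeans((solution$e[i, , drop = FALSE] - reference[i, , drop = FALSE])^2))
  mean(rms)
}

#' @export
print.ocp_solution <- function(x, ...) {
  cat(sprintf("EMG-informed stance solution: %d nodes over %.3f-%.3f s\n",
              length(x$times), x$times[1], x$times[length(x$times)]))
  ob <- x$objective
  cat(sprintf("  J = %.4g (exc %.4g, knee/ankle %.4g, reserve %.4g, EMG %.4g)\n",
              ob$total, ob$J_excitation, ob$J_knee_ankle, ob$J_reserve, ob$J_EMG))
  cat(sprintf("  dynamics residual %.2e, %d objective evaluations\n",
              x$diagnostics$dynamics_residual, x$diagnostics$fn_evals))
  invisible(x)
}

#' @export
print.scale_factors <- function(x, ...) {
  cat("Calibrated EMG scale factors (bounds 0.5-1):\n")
  print(round(x$s, 3))
  invisible(x)
}
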