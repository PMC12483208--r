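# Construction, strength scaling and mass perturbation of the planar
# sagittal musculoskeletal model, plus the steel-rod loadout used to realize
# a prescribed added mass.

#' Subject anthropometry
#' @param subject_id identifier string
#' @param mass body mass in kg (> 0)
#' @param height stature in m (> 0)
#' @return list of class `subject_anthro`
#' @export
subject_anthropometry <- function(subject_id, mass, height) {
  if (!is.finite(mass) || mass <= 0) stop("subject mass must be positive")
  if (!is.finite(height) || height <= 0) stop("subject height must be positive")
  structure(list(subject_id = as.character(subject_id), mass = mass, height = height),
            class = "subject_anthro")
}

segment_row <- function(name, frac, mass, height) {
  m <- frac$mass_frac * mass
  L <- frac$length_frac * height
  com <- frac$com_frac * L
  I <- m * (frac$gyr_frac * L)^2
  data.frame(name = name, mass = m, length = L, com_offset = com,
             inertia_com = I, stringsAsFactors = FALSE)
}

#' Build the default planar musculoskeletal model for a subject
#'
#' Scales segment masses, lengths, centers of mass and planar moments of
#' inertia from configurable anthropometric fractions of subject mass and
#' height, and attaches the twelve right-leg muscle-tendon units with their
#' default parameter tables. Deterministic for a fixed configuration.
#'
#' @param subject a [subject_anthropometry()] object
#' @param config model configuration, default [default_model_config()]
#' @return list of class `planar_model` with `subject`, `segments`
#'   (data frame), `muscles`, `gravity` and the configuration snapshot
#' @export
build_default_model <- function(subject, config = default_model_config()) {
  validate_model_config(config)
  sf <- config$segments
  segs <- rbind(
    segment_row("hat", sf$hat, subject$mass, subject$height),
    segment_row("thigh_r", sf$thigh, subject$mass, subject$height),
    segment_row("shank_r", sf$shank, subject$mass, subject$height),
    segment_row("foot_r", sf$foot, subject$mass, subject$height),
    segment_row("thigh_l", sf$thigh, subject$mass, subject$height),
    segment_row("shank_l", sf$shank, subject$mass, subject$height),
    segment_row("foot_l", sf$foot, subject$mass, subject$height)
  )
  muscles <- config$muscles
  # Calibrate each muscle's tendon+fiber path length at the reference pose so
  # the fiber operates at optimal length there (rigid-tendon kinematics).
  rp <- config$reference_pose
  for (nm in names(muscles)) {
    mu <- muscles[[nm]]
    muscles[[nm]]$lmt_ref <- mu$l_slack + mu$l_opt * cos(mu$pen_opt)
    muscles[[nm]]$q_ref <- rp
  }
  structure(list(subject = subject, segments = segs, muscles = muscles,
                 gravity = config$gravity, config = config,
                 added = data.frame(segment = character(), mass = numeric(),
                                    attach_frac = numeric())),
            class = "planar_model")
}

#' Scale peak isometric muscle forces to subject size
#'
#' Multiplies every muscle's peak isometric force by
#' `(subject mass * subject height) / (reference mass * reference height)`,
#' leaving all other parameters unchanged.
#'
#' @param model a `planar_model`
#' @param reference_mass,reference_height reference anthropometry (defaults
#'   from the model configuration, 75 kg and 1.70 m)
#' @return the rescaled model
#' @export
scale_muscle_strength <- function(model,
                                  reference_mass = model$config$reference$mass,
                                  reference_height = model$config$reference$height) {
  if (!is.finite(reference_mass) || reference_mass <= 0 ||
      !is.finite(reference_height) || reference_height <= 0)
    stop("reference anthropometry must be positive")
  fac <- (model$subject$mass * model$subject$height) / (reference_mass * reference_height)
  for (nm in names(model$muscles)) model$muscles[[nm]]$f_max <- model$muscles[[nm]]$f_max * fac
  model$strength_scaled <- TRUE
  model
}

#' Best combination of 300 g and 75 g rods for a target mass
#'
#' Exhaustively searches nonnegative rod counts minimizing the absolute
#' discrepancy between achieved and target mass. Ties are broken toward the
#' smaller total mass, then toward fewer rods. The 75 g granularity bounds
#' the discrepancy by 37.5 g.
#'
#' @param target target mass in grams (>= 0)
#' @return list of class `rod_set`: `n_large`, `n_small`, `total_mass` (g)
#'   and `discrepancy` (achieved minus target, g)
#' @export
rod_combination <- function(target) {
  if (!is.finite(target) || target < 0) stop("rod target mass must be nonnegative")
  n_l_max <- ceiling(target / 300) + 1
  grid <- expand.grid(n_large = 0:n_l_max, n_small = 0:4)
  tot <- 300 * grid$n_large + 75 * grid$n_small
  err <- abs(tot - target)
  ord <- order(err, tot, grid$n_large + grid$n_small)
  best <- ord[1]
  structure(list(n_large = grid$n_large[best], n_small = grid$n_small[best],
                 total_mass = tot[best], discrepancy = tot[best] - target),
            class = "rod_set")
}

#' The nine loading conditions of the added-mass protocol
#'
#' Added mass per leg in percent body weight: no mass; 2 and 4% at each
#' thigh; 1.5 and 3% at each shank; 1 and 2% at each foot; and all-segment
#' conditions combining the low (4.5%) and high (9%) magnitudes.
#'
#' @return data frame with columns `name`, `thigh`, `shank`, `foot` (% BW per leg)
#' @export
study_conditions <- function() {
  data.frame(
    name = c("none", "thigh_low", "thigh_high", "shank_low", "shank_high",
             "foot_low", "foot_high", "all_low", "all_high"),
    thigh = c(0, 2, 4, 0, 0, 0, 0, 2, 4),
    shank = c(0, 0, 0, 1.5, 3, 0, 0, 1.5, 3),
    foot = c(0, 0, 0, 0, 0, 1, 2, 1, 2),
    stringsAsFactors = FALSE
  )
}

#' A loading condition
#' @param name condition label
#' @param thigh,shank,foot added mass per leg, percent body weight (>= 0)
#' @param attachment named list of attachment fractions along each segment
#'   (distance from the proximal joint as a fraction of segment length);
#'   defaults to the configured approximate segment mass center
#' @return one-row data frame matching [study_conditions()] plus attachment
#' @export
loading_condition <- function(name, thigh = 0, shank = 0, foot = 0,
                              attachment = NULL) {
  if (any(c(thigh, shank, foot) < 0)) stop("added masses must be nonnegative")
  out <- data.frame(name = name, thigh = thigh, shank = shank, foot = foot,
                    stringsAsFactors = FALSE)
  attr(out, "attachment") <- attachment
  out
}

#' Attach added mass to the model's limb segments
#'
#' For each loaded segment on both legs, adds a point mass of
#' `pct/100 * subject mass` at the attachment point and updates segment mass,
#' center of mass (mass-weighted) and planar inertia about the new center of
#' mass via the parallel-axis theorem.
#'
#' @param model a `planar_model`
#' @param condition one row of [study_conditions()] or a [loading_condition()]
#' @param attachment attachment fraction(s) in `[0, 1]` from the proximal
#'   joint; default from the model configuration
#' @return the augmented model
#' @export
apply_added_mass <- function(model, condition,
                             attachment = model$config$attachment_default) {
  att <- attr(condition, "attachment")
  get_att <- function(seg) {
    a <- if (!is.null(att) && !is.null(att[[seg]])) att[[seg]] else attachment
    if (a < 0 || a > 1) stop("attachment fraction outside [0, 1] for ", seg)
    a
  }
  pct <- c(thigh = condition$thigh, shank = condition$shank, foot = condition$foot)
  for (seg in names(pct)) {
    if (pct[[seg]] == 0) next
    m_add <- pct[[seg]] / 100 * model$subject$mass
    a <- get_att(seg)
    for (side in c("_r", "_l")) {
      i <- match(paste0(seg, side), model$segments$name)
      s <- model$segments[i, ]
      d <- a * s$length
      m_new <- s$mass + m_add
      com_new <- (s$mass * s$com_offset + m_add * d) / m_new
      I_new <- s$inertia_com + s$mass * (s$com_offset - com_new)^2 +
        m_add * (d - com_new)^2
      model$segments$mass[i] <- m_new
      model$segments$com_offset[i] <- com_new
      model$segments$inertia_com[i] <- I_new
      model$added <- rbind(model$added,
                           data.frame(segment = paste0(seg, side), mass = m_add,
                                      attach_frac = a))
    }
  }
  model$condition <- condition
  model
}

#' @export
print.planar_model <- function(x, ...) {
  cat("Planar sagittal musculoskeletal model\n")
  cat(sprintf("  subject: %s (%.1f kg, %.2f m)\n", x$subject$subject_id,
              x$subject$mass, x$subject$height))
  cat(sprintf("  total segment mass: %.3f kg (%d added point masses)\n",
              sum(x$segments$mass), nrow(x$added)))
  cat(sprintf("  muscles: %d right-leg muscle-tendon units\n", length(x$muscles)))
  invisible(x)
}
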