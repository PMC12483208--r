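# End-to-end study pipeline: synthetic session -> EMG processing ->
# calibration -> execution -> contact force -> outcomes -> statistics.
# `kcf_study()` is the main fitting-style entry point and returns a classed
# object with print/summary/coef/predict/plot methods.

#' Process a trial's EMG into reference excitations
#'
#' Runs the processing chain on a trial's EMG channels: envelope extraction
#' (skipped when the channels are already envelope-scale, as for synthetic
#' trials), MVC normalization, electromechanical-delay compensation,
#' channel-to-muscle mapping, and resampling onto the trial's kinematic
#' grid.
#'
#' @param trial a `gait_trial`
#' @param config model configuration
#' @param channels_are_envelopes skip the 20 Hz/rectify/6 Hz envelope stage
#'   (default TRUE: synthetic channels are already envelope-scale)
#' @return matrix (time x 12 muscles) of reference excitations in `[0, 1]`
#' @export
process_emg <- function(trial, config = default_model_config(),
                        channels_are_envelopes = TRUE) {
  fs <- trial$fs_emg
  measured <- config$emg$measured
  gait_env <- lapply(measured, function(ch) {
    x <- trial$emg[[ch]]
    if (channels_are_envelopes) x
    else emg_envelope(x, fs, config$emg$highpass, config$emg$lowpass, config$emg$filter_order)
  })
  names(gait_env) <- measured
  norm <- mvc_normalize(gait_env, trial$mvc[measured], fs, config$emg$mvc_window)
  delayed <- lapply(norm$channels, apply_emg_delay, fs = fs, delay = config$emg$delay)
  mapped <- map_channels(delayed, config$emg$channel_map)
  ref <- sapply(names(mapped), function(nm)
    interp1(trial$emg$time, mapped[[nm]], trial$time))
  ref
}

subject_models <- function(subject, config) {
  scale_muscle_strength(build_default_model(subject, config))
}

# Run calibration and all executions for one subject's session.
run_subject <- function(subject, trials, config = default_model_config(),
                        verbose = FALSE) {
  if (inherits(subject, "data.frame"))
    subject <- subject_anthropometry(subject$subject_id[1], subject$mass[1], subject$height[1])
  model0 <- subject_models(subject, config)
  # low-pass GRF and kinematics before inverse dynamics: intended for
  # measured data; synthetic trials are noise-free and band-limited, and
  # their dynamic-consistency truth is defined on the unfiltered signals
  if (isTRUE(config$dynamics$prefilter)) {
    trials <- lapply(trials, function(tr) {
      tr$q <- lowpass_filter(tr$q, config$dynamics$kin_lowpass, tr$fs,
                             config$dynamics$filter_order)
      tr$grf[, c("fx", "fy")] <- lowpass_filter(tr$grf[, c("fx", "fy")],
                                                config$dynamics$grf_lowpass, tr$fs,
                                                config$dynamics$filter_order)
      tr
    })
  }
  refs <- lapply(trials, process_emg, config = config)

  cal_names <- names(trials)[grepl("^none", names(trials))]
  cal_probs <- list()
  for (nm in cal_names) {
    tr <- trials[[nm]]
    for (k in seq_len(nrow(tr$events))) {
      cal_probs[[length(cal_probs) + 1]] <-
        assemble_ocp(tr, model0, refs[[nm]], config$weights$calibration,
                     stage = "calibration", stride = k, config = config)
    }
  }
  scales <- solve_calibration(cal_probs, config$weights$calibration, config)

  res <- list()
  for (nm in names(trials)) {
    tr <- trials[[nm]]
    model_c <- apply_added_mass(model0, tr$condition)
    prob <- assemble_ocp(tr, model_c, refs[[nm]], config$weights$execution,
                         stage = "execution", stride = 1, config = config)
    sol <- solve_execution(prob, scales, config$weights$execution)
    trace <- total_contact_force(sol, model_c, list(time = tr$time, q = tr$q), tr$grf)
    peaks <- extract_peaks(trace, config)
    pct <- (sol$times - sol$times[1]) / diff(range(sol$times)) * 100
    roi <- pct >= config$stance$roi[1] & pct <= config$stance$roi[2]
    reserve_ratio <- c(
      knee = max(abs(sol$r[roi, "knee"])) / max(abs(prob$tau[roi, "knee"])),
      ankle = max(abs(sol$r[roi, "ankle"])) / max(abs(prob$tau[roi, "ankle"])))
    res[[nm]] <- list(solution = sol, trace = trace, peaks = peaks,
                      reserve_ratio = reserve_ratio,
                      rmse = tracking_rmse(sol, roi = config$stance$roi),
                      temporal = temporal_outcomes(tr))
    if (verbose) message("  ", subject$subject_id, " / ", nm, " done")
  }
  list(subject = subject, scales = scales, results = res)
}

outcome_table <- function(subject_runs) {
  rows <- list()
  for (sr in subject_runs) {
    for (nm in names(sr$results)) {
      r <- sr$results[[nm]]
      tmp <- r$temporal[1, c("subject_id", "condition", "thigh", "shank", "foot")]
      rows[[length(rows) + 1]] <- rbind(
        cbind(tmp, data.frame(outcome = "early_peak", value = r$peaks$early, unit = "BW")),
        cbind(tmp, data.frame(outcome = "late_peak", value = r$peaks$late, unit = "BW")),
        r$temporal)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

single_segment_rows <- function(tab) {
  n_loaded <- (tab$thigh > 0) + (tab$shank > 0) + (tab$foot > 0)
  tab[n_loaded <= 1, ]
}

fit_outcome <- function(pc_tab, outcome) {
  d <- single_segment_rows(pc_tab[pc_tab$outcome == outcome, ])
  fit_origin_regression(d$value, d[, c("thigh", "shank", "foot")])
}

#' Run the full added-mass knee-loading study on synthetic data
#'
#' Generates a synthetic cohort and session, processes EMG, calibrates EMG
#' scale factors on the unloaded trials, executes the EMG-informed solve on
#' every trial, computes contact-force traces and peaks, and fits the
#' statistical models: through-origin regressions of percent change in the
#' early- and late-stance peaks (and stride time) on added segment mass,
#' random-intercept mixed models on the raw peaks, and the coefficient-wise
#' CI prediction check on the all-segment conditions.
#'
#' @param n_subjects cohort size (default 10)
#' @param seed integer seed controlling every random draw
#' @param response a [response_model()] defining the injected condition
#'   effects
#' @param config model configuration
#' @param conditions condition table (default [study_conditions()])
#' @param n_strides strides per trial (default 3)
#' @param emg_noise_sd EMG noise SD (default 0.005)
#' @param verbose print progress
#' @return object of class `kcf_study`
#' @export
kcf_study <- function(n_subjects = 10, seed = 1, response = response_model(),
                      config = default_model_config(),
                      conditions = study_conditions(), n_strides = 3,
                      emg_noise_sd = 0.005, verbose = FALSE) {
  cohort <- generate_cohort(n_subjects, seed)
  session <- generate_session(cohort, response, seed, config, conditions,
                              n_strides, emg_noise_sd)
  runs <- list()
  for (sid in names(session)) {
    if (verbose) message("subject ", sid)
    runs[[sid]] <- run_subject(cohort[cohort$subject_id == sid, ], session[[sid]],
                               config, verbose)
  }
  tab <- outcome_table(runs)
  pc <- percent_change(tab)
  fits <- list(early = fit_outcome(pc, "early_peak"),
               late = fit_outcome(pc, "late_peak"),
               stride_time = fit_outcome(pc, "stride_time"))
  lmm <- list(
    early = fit_random_intercept_lmm(
      tab$value[tab$outcome == "early_peak"],
      tab[tab$outcome == "early_peak", c("thigh", "shank", "foot")],
      tab$subject_id[tab$outcome == "early_peak"], intercept = TRUE),
    late = fit_random_intercept_lmm(
      tab$value[tab$outcome == "late_peak"],
      tab[tab$outcome == "late_peak", c("thigh", "shank", "foot")],
      tab$subject_id[tab$outcome == "late_peak"], intercept = TRUE))
  allseg <- conditions[conditions$name %in% c("all_low", "all_high"), ]
  interaction_check <- lapply(c(early = "early_peak", late = "late_peak"), function(oc) {
    fit <- if (oc == "early_peak") fits$early else fits$late
    pred <- predict_with_ci(fit, allseg)
    obs <- sapply(allseg$name, function(cn)
      mean(pc$value[pc$outcome == oc & pc$condition == cn]))
    cbind(condition = allseg$name, pred, observed = obs)
  })
  structure(list(
    cohort = cohort, session = session, runs = runs,
    outcomes = tab, percent_change = pc,
    fits = fits, lmm = lmm, interaction_check = interaction_check,
    seed = seed, response = response, config = config
  ), class = "kcf_study")
}

#' @export
print.kcf_study <- function(x, ...) {
  cat(sprintf("EMG-informed knee-loading study: %d subjects x %d trials\n",
              nrow(x$cohort), length(x$runs[[1]]$results)))
  cat("\nEarly-stance peak model (%change per %BW per leg):\n")
  print(x$fits$early)
  cat("\nLate-stance peak model:\n")
  print(x$fits$late)
  invisible(x)
}

#' @export
summary.kcf_study <- function(object, ...) {
  print(object)
  cat("\nStride-time model:\n")
  print(object$fits$stride_time)
  cat("\nSolver diagnostics (all executions):\n")
  rr <- sapply(object$runs, function(sr)
    sapply(sr$results, function(r) r$reserve_ratio["knee"]))
  rm <- sapply(object$runs, function(sr) sapply(sr$results, function(r) r$rmse))
  cat(sprintf("  max knee reserve / peak knee moment: %.3f\n", max(rr)))
  cat(sprintf("  max EMG tracking RMSE (10-90%% stance): %.4f\n", max(rm)))
  invisible(object)
}

#' @export
coef.kcf_study <- function(object, ...) {
  rbind(early = coef(object$fits$early), late = coef(object$fits$late))
}

#' @export
predict.kcf_study <- function(object, newdata,
                              peak = c("early", "late"), ...) {
  peak <- match.arg(peak)
  predict_with_ci(object$fits[[peak]], newdata)
}

#' @export
plot.kcf_study <- function(x, subject = 1, ...) {
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  sr <- x$runs[[subject]]
  tr0 <- sr$results[[1]]$trace
  plot(tr0, main = paste0(x$cohort$subject_id[subject], ": unloaded"))
  pc <- single_segment_rows(x$percent_change[x$percent_change$outcome == "early_peak", ])
  pred <- predict_with_ci(x$fits$early, pc[, c("thigh", "shank", "foot")])$point
  graphics::plot(pred, pc$value, xlab = "Model-predicted %change",
                 ylab = "Observed %change", main = "Early-stance peak")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run the pipeline from a configuration and write artifacts
#'
#' Thin driver over [kcf_study()]: runs the full synthetic study and writes
#' the outcome table (CSV), fitted models and diagnostics (JSON), the first
#' subject's unloaded contact trace (STO dialect) and a seed manifest to
#' `outdir`. Rerunning with the same seeds reproduces the JSON byte for
#' byte.
#'
#' @param config pipeline configuration: a list with optional entries
#'   `n_subjects`, `seed`, `n_strides`, `emg_noise_sd`, `outdir`, `response`
#' @return the `kcf_study` object, invisibly
#' @export
run_pipeline <- function(config = list()) {
  outdir <- config$outdir %||% tempfile("kneeload_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- kcf_study(n_subjects = config$n_subjects %||% 10,
                  seed = config$seed %||% 1,
                  response = config$response %||% response_model(),
                  conditions = config$conditions %||% study_conditions(),
                  n_strides = config$n_strides %||% 3,
                  emg_noise_sd = config$emg_noise_sd %||% 0.005,
                  verbose = isTRUE(config$verbose))
  utils::write.csv(st$outcomes, file.path(outdir, "outcomes.csv"), row.names = FALSE)
  results <- list(
    coefficients = list(
      early = as.list(coef(st$fits$early)), late = as.list(coef(st$fits$late)),
      stride_time = as.list(coef(st$fits$stride_time))),
    pearson_r = list(early = st$fits$early$pearson_r, late = st$fits$late$pearson_r),
    interaction_check = st$interaction_check,
    seed = st$seed)
  jsonlite::write_json(results, file.path(outdir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tr <- st$runs[[1]]$results[[1]]$trace
  write_sto(list(name = "contact_trace", labels = c("time", "total", "muscle", "inter"),
                 data = cbind(time = tr$pct, total = tr$total, muscle = tr$muscle,
                              inter = tr$inter)),
            file.path(outdir, "contact_trace_s01_none.sto"))
  jsonlite::write_json(list(seed = st$seed), file.path(outdir, "seeds.json"),
                       auto_unbox = TRUE)
  invisible(st)
}

#' Write a gait trial to disk (STO/CSV/JSON)
#'
#' Joint angles as an STO table (100 Hz), right-foot ground reaction force
#' as an STO table (1250 Hz), EMG channels as CSV, and a JSON truth sidecar
#' (scale factors, true peaks, injected effects).
#'
#' @param trial a `gait_trial`
#' @param dir output directory (created)
#' @return `dir`, invisibly
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sto(list(name = "angles", labels = c("time", colnames(trial$q)),
                 data = cbind(time = trial$time, trial$q)),
            file.path(dir, "angles.sto"))
  gm <- as.matrix(trial$grf_hi)
  write_sto(list(name = "grf", labels = colnames(gm), data = gm),
            file.path(dir, "grf.sto"))
  utils::write.csv(trial$emg, file.path(dir, "emg.csv"), row.names = FALSE)
  truth <- trial$truth
  jsonlite::write_json(list(
    subject = unclass(trial$subject), condition = as.list(trial$condition),
    scale_factors = as.list(truth$scale_factors),
    peaks = unclass(truth$peaks), stride_time = truth$stride_time,
    delta_injected = as.list(truth$delta_injected), seed = trial$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a gait trial written by [write_trial()]
#'
#' Reconstructs the channels needed by the processing pipeline (angles,
#' GRF resampled to the kinematic grid, EMG, unit MVC plateaus, stance
#' events) plus the truth sidecar.
#'
#' @param dir directory written by [write_trial()]
#' @param config model configuration
#' @return a `gait_trial` (without the full truth record)
#' @export
read_trial <- function(dir, config = default_model_config()) {
  ang <- read_sto(file.path(dir, "angles.sto"))
  grf <- read_sto(file.path(dir, "grf.sto"))
  emg <- utils::read.csv(file.path(dir, "emg.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  time <- ang$data[, 1]
  q <- ang$data[, -1, drop = FALSE]
  fs <- round(1 / (time[2] - time[1]))
  fs_grf <- round(1 / (grf$data[2, 1] - grf$data[1, 1]))
  grf_hi <- as.data.frame(grf$data)
  grf100 <- cbind(fx = interp1(grf_hi$time, grf_hi$fx, time),
                  fy = interp1(grf_hi$time, grf_hi$fy, time),
                  cop = interp1(grf_hi$time, grf_hi$cop, time))
  segm <- detect_stance(pmax(grf_hi$fy, 0), fs_grf,
                        config$stance$threshold, config$stance$debounce)
  measured <- config$emg$measured
  cond <- loading_condition(truth$condition$name, truth$condition$thigh,
                            truth$condition$shank, truth$condition$foot)
  structure(list(
    subject = subject_anthropometry(truth$subject$subject_id, truth$subject$mass,
                                    truth$subject$height),
    condition = cond, time = time, q = q, fs = fs,
    grf = grf100, grf_hi = grf_hi, fs_grf = fs_grf,
    emg = emg, fs_emg = fs_grf,
    mvc = stats::setNames(lapply(measured, function(ch) rep(1, 500)), measured),
    events = segm$events, stride_time = segm$stride_time,
    duty_factor = segm$duty_factor,
    truth = truth, seed = truth$seed
  ), class = "gait_trial")
}
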