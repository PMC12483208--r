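# Total compressive tibiofemoral contact force: intersegmental (muscle-free)
# reaction plus the tibia-axial components of the knee-spanning muscle
# forces, expressed in body weights on a 0-100% stance grid, with
# early/late-stance peak extraction.

#' Total compressive tibiofemoral contact force from a solved stance
#'
#' Combines the intersegmental axial knee reaction (free-body, muscle-free)
#' with the compressive components of the muscle forces implied by the
#' solution's activations. Normalized by the subject's unweighted body
#' weight (not the rod-augmented weight) and resampled to a 0-100% stance
#' grid.
#'
#' @param solution an `ocp_solution` from [solve_execution()]
#' @param model the (loaded) `planar_model` used for the solve
#' @param kin trial kinematics (`time`, `q`) on the 100 Hz grid
#' @param grf right-foot ground reaction samples on the same grid
#' @return data frame of class `contact_trace` with columns `pct`, `total`,
#'   `muscle`, `inter` (BW, compression positive)
#' @export
total_contact_force <- function(solution, model, kin, grf) {
  pr <- solution$problem
  F <- pr$gains$K * solution$a + pr$gains$P
  muscle_n <- rowSums(pr$gains$comp * F)
  inter <- intersegmental_reaction(model, kin, grf)
  if (max(abs(pr$times - clamp(pr$times, min(kin$time), max(kin$time)))) > 1e-9)
    stop("alignment error: solution nodes outside the kinematic time base")
  inter_nodes <- interp1(kin$time, inter$axial, pr$times)
  bw <- model$subject$mass * model$gravity
  pct_nodes <- (pr$times - pr$times[1]) / diff(range(pr$times)) * 100
  out <- data.frame(pct = stance_pct_grid(),
                    total = resample_pct(pct_nodes, (inter_nodes + muscle_n) / bw),
                    muscle = resample_pct(pct_nodes, muscle_n / bw),
                    inter = resample_pct(pct_nodes, inter_nodes / bw))
  class(out) <- c("contact_trace", "data.frame")
  out
}

#' Decompose a contact trace into muscle and intersegmental contributions
#'
#' Pointwise `muscle = total - intersegmental`, plus the muscle share of the
#' total at the early- and late-stance peak locations.
#'
#' @param total_trace data frame with `pct` and `total`
#' @param intersegmental_trace data frame with `pct` and `inter` (or `total`)
#' @param config model configuration (peak windows)
#' @return `contact_trace` with an attribute `peak_shares` (percent of the
#'   total carried by muscle at each peak)
#' @export
decompose_contributions <- function(total_trace, intersegmental_trace,
                                    config = default_model_config()) {
  inter <- intersegmental_trace$inter %||% intersegmental_trace$total
  if (length(inter) != nrow(total_trace) ||
      max(abs(total_trace$pct - intersegmental_trace$pct)) > 1e-9)
    stop("alignment error: traces are on different stance grids")
  out <- data.frame(pct = total_trace$pct, total = total_trace$total,
                    muscle = total_trace$total - inter, inter = inter)
  class(out) <- c("contact_trace", "data.frame")
  pk <- extract_peaks(out, config = config)
  at <- function(loc) {
    i <- which.min(abs(out$pct - loc))
    100 * out$muscle[i] / out$total[i]
  }
  attr(out, "peak_shares") <- c(early = at(pk$early_loc), late = at(pk$late_loc))
  out
}

#' Early- and late-stance peaks of a contact-force trace
#'
#' Maxima restricted to the 15-40% and 60-90% stance windows, with arg-max
#' locations; ties break toward the earlier location.
#'
#' @param trace data frame with `pct` and `total` (BW)
#' @param config model configuration providing the peak windows
#' @return list of class `peak_summary`: `early`, `late` (BW), `early_loc`,
#'   `late_loc` (% stance)
#' @export
extract_peaks <- function(trace, config = default_model_config()) {
  win <- function(w) {
    i <- which(trace$pct >= w[1] & trace$pct <= w[2])
    y <- trace$total[i]
    if (anyNA(y)) stop("NaN inside a peak window")
    j <- i[which.max(y)]
    c(peak = trace$total[j], loc = trace$pct[j])
  }
  e <- win(config$stance$early_window)
  l <- win(config$stance$late_window)
  structure(list(early = unname(e["peak"]), early_loc = unname(e["loc"]),
                 late = unname(l["peak"]), late_loc = unname(l["loc"])),
            class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf("Knee contact force peaks: early %.2f BW at %.0f%%, late %.2f BW at %.0f%% of stance\n",
              x$early, x$early_loc, x$late, x$late_loc))
  invisible(x)
}

#' @export
plot.contact_trace <- function(x, ..., main = "Tibiofemoral contact force") {
  graphics::plot(x$pct, x$total, type = "l", lwd = 2, xlab = "% stance",
                 ylab = "Contact force (BW)", main = main, ylim = c(min(0, min(x$inter)), max(x$total) * 1.05), ...)
  graphics::lines(x$pct, x$muscle, col = "firebrick")
  graphics::lines(x$pct, x$inter, col = "steelblue")
  graphics::legend("topright", c("total", "muscle", "intersegmental"),
                   col = c("black", "firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
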