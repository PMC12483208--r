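# Surface-EMG processing: envelope extraction, MVC normalization,
# electromechanical-delay compensation, stance segmentation from the
# vertical ground reaction force, and the 9-channel to 12-muscle mapping.

#' EMG linear envelope
#'
#' Zero-phase Butterworth high-pass at 20 Hz, full-wave rectification, then
#' zero-phase Butterworth low-pass at 6 Hz. Length-preserving.
#'
#' @param raw raw EMG vector
#' @param fs sampling frequency, Hz (> 40)
#' @param highpass,lowpass cutoff frequencies, Hz
#' @param order Butterworth design order (zero-phase pass squares the response)
#' @return envelope vector
#' @export
emg_envelope <- function(raw, fs, highpass = 20, lowpass = 6, order = 4) {
  if (fs <= 2 * highpass) stop("sampling rate too low for the 20 Hz high-pass")
  bh <- signal::butter(order, highpass / (fs / 2), type = "high")
  bl <- signal::butter(order, lowpass / (fs / 2), type = "low")
  signal::filtfilt(bl, abs(signal::filtfilt(bh, raw)))
}

# 250 ms sliding-window mean (centered), used for the MVC normalization
# denominator; window invariance on constants is exact.
sliding_mean_max <- function(x, fs, window = 0.250) {
  w <- max(1L, round(window * fs))
  cs <- cumsum(c(0, x))
  n <- length(x)
  starts <- pmax(0L, seq_len(n) - w)
  means <- (cs[seq_len(n) + 1] - cs[starts + 1]) / (seq_len(n) - starts)
  max(means)
}

#' Normalize gait EMG envelopes by MVC
#'
#' The per-muscle denominator is the larger of the 250 ms sliding-window
#' mean maximum over the MVC envelope and the gait envelope maximum, so no
#' normalized signal exceeds 1.
#'
#' @param gait_envelopes named list of gait envelope vectors
#' @param mvc_envelopes named list of MVC envelope vectors (same names)
#' @param fs sampling frequency, Hz
#' @param window sliding-window length, s (default 0.250)
#' @return list of class `emg_envelope_set`: `channels` (normalized,
#'   `[0, 1]`), `mvc_max` (denominators), `invalid` (all-zero channels)
#' @export
mvc_normalize <- function(gait_envelopes, mvc_envelopes, fs, window = 0.250) {
  nms <- names(gait_envelopes)
  if (!setequal(nms, names(mvc_envelopes)))
    stop("gait and MVC envelope sets must share muscle names")
  channels <- list(); mvc_max <- numeric(0); invalid <- character(0)
  for (nm in nms) {
    denom <- max(sliding_mean_max(mvc_envelopes[[nm]], fs, window),
                 max(gait_envelopes[[nm]]))
    if (denom <= 0) {
      invalid <- c(invalid, nm)
      channels[[nm]] <- gait_envelopes[[nm]] * 0
      mvc_max[nm] <- NA_real_
      next
    }
    channels[[nm]] <- gait_envelopes[[nm]] / denom
    mvc_max[nm] <- denom
  }
  structure(list(channels = channels, mvc_max = mvc_max, invalid = invalid,
                 fs = fs, delay_applied = 0),
            class = "emg_envelope_set")
}

#' Compensate the electromechanical delay
#'
#' Shifts the envelope forward in time by `round(delay * fs)` samples so
#' that neural excitation aligns with force production (EMG leads force by
#' the electromechanical delay, 53 ms by default). Edges are padded by
#' extension.
#'
#' @param env envelope vector
#' @param fs sampling frequency, Hz
#' @param delay delay in seconds (>= 0), default 0.053
#' @return shifted envelope, same length
#' @export
apply_emg_delay <- function(env, fs, delay = 0.053) {
  if (delay < 0) stop("delay must be nonnegative")
  k <- round(delay * fs)
  n <- length(env)
  if (k >= n) stop("delay exceeds signal duration")
  if (k == 0) return(env)
  c(rep(env[1], k), env[seq_len(n - k)])
}

#' Detect stance phases from the vertical ground reaction force
#'
#' Heel strike is an upward crossing of the threshold sustained for at least
#' the debounce duration; toe-off is the following downward crossing. Also
#' reports stride time (successive heel strikes) and duty factor
#' (stance/stride ratio).
#'
#' @param grf_vertical vertical GRF vector, N (nonnegative)
#' @param fs sampling frequency, Hz
#' @param threshold contact threshold, N (default 20)
#' @param debounce minimum contact duration, s (default 0.050)
#' @return list of class `stance_segmentation`: `events` (data frame with
#'   `heel_strike`, `toe_off` times in s), `stride_time`, `duty_factor`
#' @export
detect_stance <- function(grf_vertical, fs, threshold = 20, debounce = 0.050) {
  if (any(grf_vertical < -1e-9)) stop("vertical GRF must be nonnegative")
  on <- grf_vertical > threshold
  if (!any(on)) stop("no stance found: GRF never exceeds the threshold")
  d <- diff(c(FALSE, on, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  keep <- (ends - starts + 1) >= round(debounce * fs)
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) stop("no stance found: no contact sustained past debounce")
  t <- (seq_along(grf_vertical) - 1) / fs
  ev <- data.frame(heel_strike = t[starts], toe_off = t[pmin(ends + 1, length(t))])
  stride <- if (nrow(ev) >= 2) mean(diff(ev$heel_strike)) else NA_real_
  duty <- if (nrow(ev) >= 2)
    mean((ev$toe_off - ev$heel_strike)[seq_len(nrow(ev) - 1)]) / stride
  else (ev$toe_off - ev$heel_strike) / NA_real_
  structure(list(events = ev, stride_time = stride, duty_factor = duty, fs = fs),
            class = "stance_segmentation")
}

#' Map nine measured channels onto the twelve modeled muscles
#'
#' Copies vastus medialis to vastus intermedius, biceps femoris long head to
#' the short head, and semitendinosus to semimembranosus; the nine measured
#' channels are retained.
#'
#' @param channels named list of nine normalized channel vectors
#' @param channel_map named character vector `target = source`, default from
#'   [default_model_config()]
#' @return named list of twelve reference excitation vectors
#' @export
map_channels <- function(channels,
                         channel_map = default_model_config()$emg$channel_map) {
  out <- channels
  for (target in names(channel_map)) {
    src <- channel_map[[target]]
    if (is.null(channels[[src]]))
      stop("cannot map '", target, "': source channel '", src, "' missing")
    out[[target]] <- channels[[src]]
  }
  out
}

# Flag strides whose EMG sits at a bound (0 or 1) for longer than max_flat
# seconds: a programmatic stand-in for visual artifact screening.
flag_saturated <- function(channels, fs, max_flat = 0.5) {
  bad <- vapply(channels, function(x) {
    r <- rle(x <= 1e-9 | x >= 1 - 1e-9)
    any(r$lengths[r$values] > max_flat * fs)
  }, logical(1))
  names(bad)[bad]
}
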