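#' Raw EMG recording
#'
#' @param channels Numeric matrix (samples x channels) or data frame of raw
#'   signals, mV, with column names.
#' @param fs Sampling rate, Hz.
#' @return An object of class \code{emg_recording}.
#' @export
emg_recording <- function(channels, fs) {
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) stop("channels must be named")
  if (!all(is.finite(channels))) stop("EMG samples must be finite")
  stopifnot(is.numeric(fs), fs > 0)
  structure(list(channels = channels, fs = fs), class = "emg_recording")
}

#' Envelope series
#'
#' @param channels Numeric matrix (samples x channels) of nonnegative
#'   envelopes.
#' @param fs Sampling rate, Hz.
#' @param delay_applied Electromechanical delay already applied, s.
#' @return An object of class \code{envelope_series}.
#' @export
envelope_series <- function(channels, fs, delay_applied = 0) {
  channels <- as.matrix(channels)
  if (any(channels < 0)) stop("envelope values must be nonnegative")
  structure(list(channels = channels, fs = fs,
                 delay_applied = delay_applied),
            class = "envelope_series")
}

# Zero-phase IIR filtering with odd-reflection padding of 3x the filter
# order at each end, then forward-backward application.
filtfilt_reflect <- function(filt, x) {
  b <- filt$b; a <- filt$a
  npad <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= npad)
    stop("signal too short for zero-phase filtering (need > ", npad,
         " samples)")
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  xx <- c(front, x, back)
  y <- signal::filter(b, a, xx)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(npad + 1):(npad + n)])
}

#' EMG linear envelope
#'
#' Bandpass filter (30-500 Hz Butterworth, zero-phase), full-wave rectify,
#' then low-pass filter (6 Hz, 4th order Butterworth, zero-phase). The
#' bandpass upper edge is clamped to 0.99 of Nyquist (with a warning) when
#' the sampling rate is too low for a 500 Hz edge.
#'
#' @param rec An \code{emg_recording}.
#' @param channels Channel names (default: all).
#' @param band Pass band, Hz (default c(30, 500)).
#' @param lowpass Envelope cutoff, Hz (default 6).
#' @return An \code{envelope_series} at the recording rate.
#' @export
compute_envelope <- function(rec, channels = colnames(rec$channels),
                             band = c(30, 500), lowpass = 6) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (band[2] >= nyq) {
    warning("bandpass upper edge clamped to 0.99 * Nyquist (fs = ",
            rec$fs, " Hz)")
    band[2] <- 0.99 * nyq
  }
  bp <- signal::butter(2, band / nyq, type = "pass")   # 4th-order bandpass
  lp <- signal::butter(4, lowpass / nyq, type = "low")
  env <- sapply(channels, function(ch) {
    x <- rec$channels[, ch]
    pmax(filtfilt_reflect(lp, abs(filtfilt_reflect(bp, x))), 0)
  })
  envelope_series(env, rec$fs)
}

#' Normalize envelopes by maximum voluntary contraction
#'
#' Divides each channel by the scalar maximum of its MVC envelope (computed
#' with identical filter settings). Values above 1 are allowed (MVC
#' underestimation is common) and reported via a message; values above 1.5
#' trigger a warning.
#'
#' @param env An \code{envelope_series} to normalize.
#' @param mvc Either an \code{envelope_series} from the MVC trials or a named
#'   numeric vector of per-channel MVC maxima.
#' @return A normalized \code{envelope_series} (fraction of MVC).
#' @export
normalize_mvc <- function(env, mvc) {
  stopifnot(inherits(env, "envelope_series"))
  maxima <- if (inherits(mvc, "envelope_series"))
    apply(mvc$channels, 2, max) else mvc
  chans <- colnames(env$channels)
  if (!all(chans %in% names(maxima)))
    stop("MVC maxima missing for channel(s): ",
         paste(setdiff(chans, names(maxima)), collapse = ", "))
  if (any(maxima[chans] <= 0)) stop("MVC maxima must be positive")
  out <- sweep(env$channels, 2, maxima[chans], "/")
  over <- colSums(out > 1) > 0
  if (any(out > 1.5))
    warning("normalized envelope exceeds 1.5 of MVC; check MVC trials")
  else if (any(over))
    message("normalized envelope exceeds 1 of MVC for: ",
            paste(chans[over], collapse = ", "))
  envelope_series(out, env$fs, env$delay_applied)
}

#' Apply an electromechanical delay
#'
#' Shifts every channel later in time by \code{round(delay * fs)} samples,
#' holding the leading edge at its first value.
#'
#' @param env An \code{envelope_series}.
#' @param delay Delay, s (>= 0; default 0.040).
#' @return A shifted \code{envelope_series}.
#' @export
apply_delay <- function(env, delay = 0.040) {
  stopifnot(inherits(env, "envelope_series"), delay >= 0)
  shift <- round(delay * env$fs)
  n <- nrow(env$channels)
  if (shift >= n) stop("delay exceeds signal duration")
  if (shift == 0) return(env)
  out <- apply(env$channels, 2, function(x)
    c(rep(x[1], shift), x[seq_len(n - shift)]))
  envelope_series(out, env$fs, env$delay_applied + shift / env$fs)
}

#' Gastrocnemius-to-soleus activation ratio
#'
#' Stance-averaged gastrocnemius envelope divided by the sum of the
#' stance-averaged gastrocnemius and soleus envelopes.
#'
#' @param gastroc_env,soleus_env Numeric envelope vectors (normalized),
#'   sharing a time base.
#' @param stance_mask Logical vector selecting stance samples.
#' @return Dimensionless ratio in [0, 1].
#' @export
activation_ratio <- function(gastroc_env, soleus_env, stance_mask) {
  stopifnot(length(gastroc_env) == length(soleus_env),
            length(stance_mask) == length(gastroc_env))
  if (!any(stance_mask)) stop("stance mask selects no samples")
  g <- mean(gastroc_env[stance_mask])
  s <- mean(soleus_env[stance_mask])
  if (g + s <= 0) stop("activation ratio undefined: zero denominator")
  g / (g + s)
}

#' Stance detection from vertical ground reaction force
#'
#' @param grf_vertical Vertical GRF, N.
#' @param threshold Contact threshold, N (default 20).
#' @return Logical stance mask.
#' @export
detect_stance <- function(grf_vertical, threshold = 20) {
  grf_vertical > threshold
}

#' Biofeedback target state
#'
#' @param baseline_ratio Baseline activation ratio.
#' @param baseline_gastroc Baseline stance-averaged gastrocnemius envelope,
#'   fraction of MVC.
#' @param target_reduction Current target fractional reduction (>= 0.15).
#' @return An object of class \code{feedback_state}.
#' @export
feedback_state <- function(baseline_ratio, baseline_gastroc,
                           target_reduction = 0.15) {
  stopifnot(baseline_ratio >= 0, baseline_ratio <= 1,
            target_reduction >= 0.15)
  structure(list(baseline_ratio = baseline_ratio,
                 baseline_gastroc = baseline_gastroc,
                 target_reduction = target_reduction),
            class = "feedback_state")
}

#' Adaptive feedback-target update
#'
#' The next trial's target is the larger of the 15\% floor and the reduction
#' actually achieved in the previous trial.
#'
#' @param state A \code{feedback_state}.
#' @param achieved_reduction Fractional reduction achieved in the previous
#'   trial.
#' @return Updated \code{feedback_state}.
#' @export
update_feedback_target <- function(state, achieved_reduction) {
  stopifnot(inherits(state, "feedback_state"),
            is.finite(achieved_reduction))
  state$target_reduction <- max(0.15, achieved_reduction)
  state
}
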