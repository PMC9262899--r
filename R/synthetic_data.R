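#' Normative sagittal gait kinematics
#'
#' Smooth analytic joint-angle profiles over one gait cycle, qualitatively
#' matching normative treadmill walking: hip flexed at heel strike and
#' extended in late stance; a small stance knee-flexion wave followed by the
#' large swing flexion; early-stance plantarflexion, mid-stance dorsiflexion
#' and a push-off plantarflexion burst. Angles in radians; hip flexion, knee
#' flexion, and ankle plantarflexion positive.
#'
#' @param cycle_frac Gait-cycle fraction(s) in [0, 1] (stance is the first
#'   60\% by default in the generator).
#' @return Matrix \code{length(cycle_frac) x 3} with columns
#'   \code{hip_flexion}, \code{knee_flexion}, \code{ankle_plantarflexion}.
#' @export
gait_kinematics <- function(cycle_frac) {
  c_ <- cycle_frac
  bump <- function(center, width) exp(-((c_ - center) / width)^2)
  hip <- 0.12 + 0.28 * cos(2 * pi * c_)
  knee <- 0.06 + 0.20 * bump(0.09, 0.08) + 1.05 * bump(0.73, 0.12)
  ankle <- 0.08 * bump(0.04, 0.05) - 0.20 * bump(0.40, 0.18) +
    0.35 * bump(0.62, 0.07)
  out <- cbind(hip_flexion = hip, knee_flexion = knee,
               ankle_plantarflexion = ankle)
  out
}

eval_bumps <- function(bumps, baseline, cycle_frac) {
  a <- rep(baseline, length(cycle_frac))
  for (b in bumps)
    a <- a + b$amp * exp(-((cycle_frac - b$center) / b$width)^2)
  a
}

default_activation_bumps <- function() {
  # centers/widths in cycle fraction (stance = first 60% of the cycle);
  # phasing: hamstrings dominate the first ~10% of stance, quadriceps
  # 10-40% of stance, plantarflexors 40-90% of stance
  list(
    iliopsoas = list(list(center = 0.62, width = 0.08, amp = 0.35)),
    glut_max  = list(list(center = 0.05, width = 0.07, amp = 0.30)),
    rect_fem  = list(list(center = 0.12, width = 0.07, amp = 0.20),
                     list(center = 0.62, width = 0.05, amp = 0.15)),
    vas_med   = list(list(center = 0.12, width = 0.07, amp = 0.35)),
    vas_lat   = list(list(center = 0.12, width = 0.07, amp = 0.35)),
    bf_long   = list(list(center = 0.03, width = 0.05, amp = 0.35),
                     list(center = 0.95, width = 0.05, amp = 0.25)),
    bf_short  = list(list(center = 0.03, width = 0.05, amp = 0.25),
                     list(center = 0.95, width = 0.05, amp = 0.20)),
    semiten   = list(list(center = 0.03, width = 0.05, amp = 0.30),
                     list(center = 0.95, width = 0.05, amp = 0.25)),
    semimem   = list(list(center = 0.03, width = 0.05, amp = 0.35),
                     list(center = 0.95, width = 0.05, amp = 0.25)),
    gas_med   = list(list(center = 0.42, width = 0.09, amp = 0.65)),
    gas_lat   = list(list(center = 0.42, width = 0.09, amp = 0.50)),
    soleus    = list(list(center = 0.44, width = 0.10, amp = 0.60)),
    tib_ant   = list(list(center = 0.02, width = 0.04, amp = 0.30),
                     list(center = 0.75, width = 0.12, amp = 0.25)),
    tfl       = list(list(center = 0.30, width = 0.20, amp = 0.08))
  )
}

#' Synthetic trial configuration
#'
#' Assembles the parameters of one generated gait trial. The
#' \code{"normative"} preset uses the default ground-truth activation bumps.
#' The \code{"retention"} preset emulates a learned gastrocnemius-avoidance
#' pattern: both gastrocnemius heads' bump amplitudes are scaled by
#' \code{gastroc_scale} and the soleus amplitude is scaled up by the factor
#' (computed in closed form from the stance-mean modulators) that reduces the
#' ground-truth medial gastrocnemius-to-soleus activation ratio by exactly
#' \code{ratio_reduction}.
#'
#' @param preset \code{"normative"} or \code{"retention"}.
#' @param cycle_duration Gait-cycle duration, s (default 1.1).
#' @param dt Time step, s (default 0.01).
#' @param stance_fraction Stance share of the cycle (default 0.6).
#' @param bumps Ground-truth activation bumps (named list per muscle of
#'   \code{list(center, width, amp)} in cycle fraction).
#' @param baseline Tonic baseline activation added to every muscle (default
#'   0.01).
#' @param gastroc_scale Retention-preset gastrocnemius amplitude scale
#'   (default 0.7).
#' @param ratio_reduction Retention-preset target fractional reduction of the
#'   ground-truth activation ratio (default 0.25).
#' @param interseg_noise_sd SD of smooth noise added to the intersegmental
#'   axial force, as a fraction of bodyweight (default 0.005).
#' @param amp_jitter Optional named numeric of per-muscle amplitude scale
#'   factors (used by \code{\link{make_cohort}}).
#' @return A list of class \code{trial_config}.
#' @export
trial_config <- function(preset = c("normative", "retention"),
                         cycle_duration = 1.1, dt = 0.01,
                         stance_fraction = 0.6,
                         bumps = default_activation_bumps(),
                         baseline = 0.01,
                         gastroc_scale = 0.7,
                         ratio_reduction = 0.25,
                         interseg_noise_sd = 0.005,
                         amp_jitter = NULL) {
  preset <- match.arg(preset)
  stopifnot(cycle_duration > 0, dt > 0, stance_fraction > 0,
            stance_fraction < 1)
  scale_bumps <- function(bs, f) lapply(bs, function(b) {
    b$amp <- b$amp * f; b
  })
  if (!is.null(amp_jitter))
    for (mu in names(amp_jitter))
      bumps[[mu]] <- scale_bumps(bumps[[mu]], amp_jitter[[mu]])
  if (preset == "retention") {
    sgrid <- seq(0, stance_fraction, by = dt / cycle_duration)
    g0 <- mean(eval_bumps(bumps$gas_med, baseline, sgrid))
    s0 <- mean(eval_bumps(bumps$soleus, baseline, sgrid))
    r0 <- g0 / (g0 + s0)
    r1 <- (1 - ratio_reduction) * r0
    g1 <- mean(eval_bumps(scale_bumps(bumps$gas_med, gastroc_scale),
                          baseline, sgrid))
    soleus_scale_num <- g1 * (1 - r1) / r1   # required soleus stance mean
    soleus_scale <- stats::uniroot(function(f)
      mean(eval_bumps(scale_bumps(bumps$soleus, f), baseline, sgrid)) -
        soleus_scale_num, c(0.1, 10))$root
    bumps$gas_med <- scale_bumps(bumps$gas_med, gastroc_scale)
    bumps$gas_lat <- scale_bumps(bumps$gas_lat, gastroc_scale)
    bumps$soleus <- scale_bumps(bumps$soleus, soleus_scale)
  }
  for (mu in names(bumps)) {
    peak <- max(eval_bumps(bumps[[mu]], baseline, seq(0, 1, by = 0.001)))
    if (peak > 1)
      stop("activation bumps for '", mu, "' exceed 1 (peak ", round(peak, 3),
           "); reduce amplitudes")
  }
  structure(list(preset = preset, cycle_duration = cycle_duration, dt = dt,
                 stance_fraction = stance_fraction, bumps = bumps,
                 baseline = baseline, interseg_noise_sd = interseg_noise_sd),
            class = "trial_config")
}

smooth_noise <- function(n, sd) {
  if (sd <= 0 || n < 5) return(numeric(n))
  x <- stats::rnorm(n + 20)
  k <- stats::dnorm(seq(-3, 3, length.out = 11))
  k <- k / sum(k)
  y <- stats::filter(x, k, sides = 2)
  y <- y[11:(10 + n)]
  y <- y - mean(y)
  y * sd / stats::sd(y)
}

#' Generate one synthetic gait trial with known ground truth
#'
#' Builds a gait trial whose inverse-dynamics joint moments are computed
#' forward from smooth ground-truth activations through the musculotendon
#' model and moment-arm matrix, so the moments are exactly achievable by
#' construction. Fiber equilibrium during generation threads the previous
#' frame's ground-truth activation, mirroring the solver. The intersegmental
#' knee axial force is a smooth double-bump stance profile scaled to
#' bodyweight with a small seeded smooth noise component; the seed affects
#' only noise draws.
#'
#' @param model A \code{planar_model}.
#' @param config A \code{trial_config}.
#' @param seed Integer seed for the noise draws.
#' @return List with elements \code{trial} (class \code{gait_trial}: t, q,
#'   M_ID, stance_mask, interseg_axial, grf_vertical, bodyweight) and
#'   \code{truth} (class \code{synthetic_truth}: activations, forces,
#'   fiber_lengths, t, cycle_frac, stance_mask, seed, config).
#' @export
generate_trial <- function(model, config = trial_config(), seed = 1L) {
  stopifnot(inherits(model, "planar_model"), inherits(config, "trial_config"))
  set.seed(as.integer(seed))
  t <- seq(0, config$cycle_duration, by = config$dt)
  cf <- t / config$cycle_duration
  nT <- length(t)
  stance_mask <- cf <= config$stance_fraction
  q <- gait_kinematics(cf)
  mus <- names(model$muscles)
  nM <- length(mus)

  act <- matrix(config$baseline, nT, nM, dimnames = list(NULL, mus))
  for (mu in intersect(names(config$bumps), mus))
    act[, mu] <- eval_bumps(config$bumps[[mu]], config$baseline, cf)

  forces <- matrix(0, nT, nM, dimnames = list(NULL, mus))
  fiber_lm <- matrix(NA_real_, nT, nM, dimnames = list(NULL, mus))
  M_ID <- matrix(0, nT, length(model$dofs),
                 dimnames = list(NULL, model$dofs))
  prev_lm <- setNames(rep(NA_real_, nM), mus)
  for (k in seq_len(nT)) {
    qk <- q[k, ]
    a_prev <- act[max(k - 1, 1), ]
    Fk <- numeric(nM)
    for (i in seq_len(nM)) {
      mu <- mus[i]
      lm_init <- if (is.na(prev_lm[i])) NULL else prev_lm[[i]]
      fib <- solve_fiber_equilibrium(model$muscles[[mu]]$params,
                                     model$curves, a_prev[[i]],
                                     mtu_length(model, mu, qk),
                                     l_m_init = lm_init)
      co <- mtu_force_coeffs(model$muscles[[mu]]$params, model$curves, fib)
      Fk[i] <- co$c0 + co$c1 * act[k, i]
      fiber_lm[k, i] <- fib$l_m
      prev_lm[i] <- fib$l_m
    }
    forces[k, ] <- Fk
    M_ID[k, ] <- moment_arm_matrix(model, qk) %*% Fk
  }

  s <- cf / config$stance_fraction            # stance fraction in [0,1]
  ramp <- pmin(1, pmax(0, s / 0.08)) * pmin(1, pmax(0, (1 - s) / 0.08))
  interseg <- model$bodyweight * ramp *
    (0.55 + 0.55 * exp(-((s - 0.25) / 0.14)^2) +
       0.60 * exp(-((s - 0.78) / 0.12)^2))
  interseg[!stance_mask] <- 0
  noise <- smooth_noise(nT, config$interseg_noise_sd * model$bodyweight)
  interseg[stance_mask] <- pmax(interseg[stance_mask] +
                                  noise[stance_mask], 0)
  grf <- model$bodyweight * ramp *
    (0.65 + 0.45 * exp(-((s - 0.22) / 0.13)^2) +
       0.45 * exp(-((s - 0.78) / 0.12)^2))
  grf[!stance_mask] <- 0

  trial <- structure(
    list(t = t, q = q, M_ID = M_ID, stance_mask = stance_mask,
         interseg_axial = interseg, grf_vertical = grf,
         bodyweight = model$bodyweight),
    class = "gait_trial")
  truth <- structure(
    list(activations = act, forces = forces, fiber_lengths = fiber_lm,
         t = t, cycle_frac = cf, stance_mask = stance_mask,
         seed = as.integer(seed), config = config),
    class = "synthetic_truth")
  list(trial = trial, truth = truth)
}

#' Generate raw surface EMG consistent with a ground truth
#'
#' Each channel is band-limited zero-mean noise (the carrier), amplitude-
#' modulated by the ground-truth activation advanced by the electromechanical
#' delay — so that the processed, delayed envelope re-aligns with the truth —
#' plus additive sensor noise. A matching MVC recording (modulator held at 1)
#' is returned for normalization with identical filter settings.
#'
#' @param truth A \code{synthetic_truth}.
#' @param fs Sampling rate, Hz (>= 1000).
#' @param channels Muscle channels to synthesize.
#' @param delay Electromechanical delay, s (default 0.040).
#' @param carrier_band Carrier pass band, Hz (default 30-450).
#' @param sensor_noise Additive sensor noise SD as a fraction of the carrier
#'   amplitude scale (default 0.01).
#' @param gain_mv Overall raw-signal gain, mV (default 0.5).
#' @param seed Integer seed.
#' @return List with \code{walk} and \code{mvc} (\code{emg_recording}
#'   objects), \code{modulators} (matrix on the EMG time grid), \code{t}
#'   (EMG time grid, s) and \code{delay}.
#' @export
generate_emg <- function(truth, fs = 2000,
                         channels = c("gas_med", "gas_lat", "soleus",
                                      "tib_ant"),
                         delay = 0.040, carrier_band = c(30, 450),
                         sensor_noise = 0.01, gain_mv = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"), fs >= 1000)
  set.seed(as.integer(seed))
  tf <- seq(0, max(truth$t), by = 1 / fs)
  bp <- signal::butter(2, carrier_band / (fs / 2), type = "pass")
  carrier <- function(n) {
    x <- stats::rnorm(n + 400)
    y <- signal::filter(bp, x)[-(1:400)]
    y / mean(abs(y))
  }
  mods <- sapply(channels, function(ch)
    stats::approx(truth$t, truth$activations[, ch], xout = tf + delay,
                  rule = 2)$y)
  raw <- sapply(seq_along(channels), function(j)
    gain_mv * (mods[, j] * carrier(length(tf)) +
                 sensor_noise * stats::rnorm(length(tf))))
  colnames(raw) <- channels
  n_mvc <- as.integer(1.5 * fs)
  mvc_raw <- sapply(channels, function(ch)
    gain_mv * (carrier(n_mvc) + sensor_noise * stats::rnorm(n_mvc)))
  list(walk = emg_recording(raw, fs),
       mvc = emg_recording(mvc_raw, fs),
       modulators = mods, t = tf, delay = delay)
}

#' Generate a synthetic cohort of baseline/retention trial pairs
#'
#' Draws per-subject jitter (bodyweight within +/-10\%, per-muscle bump
#' amplitudes within +/-8\%) and generates, for each subject, a normative
#' baseline trial and a retention trial with the gastrocnemius-avoidance-like
#' ground truth, each with matched raw EMG.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; subject-level seeds are derived from it.
#' @param bodyweight Mean bodyweight, N (default 736).
#' @param with_emg Generate EMG recordings too (default TRUE).
#' @param ratio_reduction Retention-preset truth ratio reduction
#'   (default 0.25).
#' @return List of subjects; each has \code{model}, \code{baseline} and
#'   \code{retention}, the latter two holding \code{trial}, \code{truth} and
#'   (optionally) \code{emg}.
#' @export
make_cohort <- function(n_subjects, seed = 1L, bodyweight = 736,
                        with_emg = TRUE, ratio_reduction = 0.25) {
  stopifnot(n_subjects >= 1)
  set.seed(as.integer(seed))
  mus <- names(default_activation_bumps())
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    bw <- bodyweight * stats::runif(1, 0.9, 1.1)
    jit <- setNames(stats::runif(length(mus), 0.92, 1.08), mus)
    sub_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    model <- default_model(bodyweight = bw)
    out <- list(model = model)
    for (preset in c("normative", "retention")) {
      cfg <- trial_config(preset = preset, amp_jitter = jit,
                          ratio_reduction = ratio_reduction)
      gen <- generate_trial(model, cfg, seed = sub_seed)
      cond <- list(trial = gen$trial, truth = gen$truth)
      if (with_emg)
        cond$emg <- generate_emg(gen$truth, seed = sub_seed + 500L)
      out[[if (preset == "normative") "baseline" else "retention"]] <- cond
    }
    subjects[[i]] <- out
  }
  subjects
}
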