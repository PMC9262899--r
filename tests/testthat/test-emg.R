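test_that("a DC signal has an (essentially) zero envelope", {
  fs <- 2000
  rec <- emg_recording(cbind(ch = rep(0.8, 2 * fs)), fs)
  env <- compute_envelope(rec)
  mid <- seq(fs / 2, 3 * fs / 2)
  expect_lt(max(env$channels[mid, "ch"]), 1e-3)
})

test_that("a sinusoid's steady-state envelope is 2A/pi", {
  fs <- 2000
  t <- seq(0, 3, by = 1 / fs)
  A <- 0.7
  rec <- emg_recording(cbind(ch = A * sin(2 * pi * 100 * t)), fs)
  env <- compute_envelope(rec)
  mid <- seq(fs, 2 * fs)
  expect_equal(mean(env$channels[mid, "ch"]), 2 * A / pi, tolerance = 0.02)
})

test_that("the envelope operator is positively homogeneous", {
  fs <- 2000
  set.seed(11)
  x <- rnorm(3 * fs)
  e1 <- compute_envelope(emg_recording(cbind(ch = x), fs))$channels
  e3 <- compute_envelope(emg_recording(cbind(ch = 3 * x), fs))$channels
  expect_equal(e3, 3 * e1, tolerance = 1e-9)
})

test_that("zero-phase filtering keeps a symmetric burst centered", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  center <- 1
  burst <- exp(-((t - center) / 0.08)^2) * sin(2 * pi * 120 * t)
  env <- compute_envelope(emg_recording(cbind(ch = burst), fs))
  peak_t <- t[which.max(env$channels[, "ch"])]
  expect_lt(abs(peak_t - center), 1.5 / fs + 0.005)
})

test_that("bandpass edge is clamped with a warning at low sampling rates", {
  rec <- emg_recording(cbind(ch = rnorm(3000)), fs = 800)
  expect_warning(compute_envelope(rec), "Nyquist")
})

test_that("too-short signals are rejected", {
  rec <- emg_recording(cbind(ch = rnorm(10)), fs = 2000)
  expect_error(compute_envelope(rec), "too short")
})

test_that("MVC normalization is a per-channel scalar division", {
  fs <- 2000
  set.seed(3)
  x <- abs(rnorm(fs))
  env <- envelope_series(cbind(gas_med = x, soleus = 2 * x), fs)
  # an envelope normalized by its own maxima peaks at exactly 1
  self <- normalize_mvc(env, env)
  expect_equal(unname(apply(self$channels, 2, max)), c(1, 1))
  # doubling the raw gain leaves the normalized envelope unchanged
  env2 <- envelope_series(2 * env$channels, fs)
  mvc <- c(gas_med = 1.5, soleus = 2.5)
  # values above 1.5 of MVC are flagged
  expect_warning(n1 <- normalize_mvc(env, c(gas_med = 1.5 / 2,
                                            soleus = 2.5 / 2)), "MVC")
  expect_warning(n2 <- normalize_mvc(env2, mvc), "MVC")
  expect_equal(n1$channels, n2$channels)
  # zero signal stays zero; non-positive MVC is an error
  z <- envelope_series(cbind(gas_med = numeric(10)), fs)
  expect_equal(max(normalize_mvc(z, c(gas_med = 1))$channels), 0)
  expect_error(normalize_mvc(z, c(gas_med = 0)), "positive")
})

test_that("electromechanical delay shifts by round(delay * fs) samples", {
  fs <- 2000
  x <- seq_len(400) / 400
  env <- envelope_series(cbind(ch = x), fs)
  expect_identical(apply_delay(env, 0)$channels, env$channels)
  d <- apply_delay(env, 0.040)
  expect_equal(unname(d$channels[81:400, "ch"]), x[1:320])
  expect_equal(unname(d$channels[1:80, "ch"]), rep(x[1], 80))
  # two 20 ms delays compose to one 40 ms delay
  d2 <- apply_delay(apply_delay(env, 0.020), 0.020)
  expect_equal(d2$channels, d$channels)
  expect_equal(d2$delay_applied, 0.040)
  expect_error(apply_delay(env, 1), "exceeds")
})

test_that("activation ratio follows its defining arithmetic", {
  mask <- rep(TRUE, 4)
  expect_equal(activation_ratio(rep(0.2, 4), rep(0.2, 4), mask), 0.5)
  expect_equal(activation_ratio(rep(0.3, 4), rep(0.1, 4), mask), 0.75)
  expect_equal(activation_ratio(rep(0, 4), rep(0.1, 4), mask), 0)
  # invariant to common rescaling of both channels
  expect_equal(activation_ratio(rep(0.3, 4) * 7, rep(0.1, 4) * 7, mask), 0.75)
  expect_error(activation_ratio(rep(0, 4), rep(0, 4), mask), "denominator")
  expect_error(activation_ratio(rep(1, 4), rep(1, 4), rep(FALSE, 4)),
               "stance")
})

test_that("the adaptive feedback target is max(15%, achieved reduction)", {
  st <- feedback_state(baseline_ratio = 0.5, baseline_gastroc = 0.3)
  expect_equal(update_feedback_target(st, 0.10)$target_reduction, 0.15)
  expect_equal(update_feedback_target(st, 0.22)$target_reduction, 0.22)
  expect_equal(update_feedback_target(st, 0.15)$target_reduction, 0.15)
})
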