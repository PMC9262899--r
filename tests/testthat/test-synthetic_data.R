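test_that("generated moments are exactly the truth's muscle moments", {
  nc <- normative_case()
  for (k in c(1, 20, 45, 80)) {
    R <- moment_arm_matrix(nc$model, nc$trial$q[k, ])
    expect_equal(as.numeric(R %*% nc$truth$forces[k, ]),
                 unname(nc$trial$M_ID[k, ]), tolerance = 1e-13)
  }
})

test_that("the seed reproduces the trial and touches only the noise", {
  model <- default_model()
  g1 <- generate_trial(model, trial_config(), seed = 7)
  g2 <- generate_trial(model, trial_config(), seed = 7)
  g3 <- generate_trial(model, trial_config(), seed = 8)
  expect_identical(g1$trial, g2$trial)
  expect_identical(g1$truth$activations, g2$truth$activations)
  # a different seed redraws only the intersegmental noise
  expect_identical(g1$trial$M_ID, g3$trial$M_ID)
  expect_identical(g1$truth$activations, g3$truth$activations)
  expect_false(identical(g1$trial$interseg_axial, g3$trial$interseg_axial))
})

test_that("overfull activation bumps are rejected", {
  bumps <- default_activation_bumps()
  bumps$soleus[[1]]$amp <- 1.2
  expect_error(trial_config(bumps = bumps), "exceed")
})

test_that("the retention preset reduces the truth ratio by the configured fraction", {
  cfg_b <- trial_config("normative")
  cfg_r <- trial_config("retention", ratio_reduction = 0.25)
  sgrid <- seq(0, 0.6, by = 0.01 / 1.1)
  ratio_of <- function(cfg) {
    g <- mean(kneeload:::eval_bumps(cfg$bumps$gas_med, cfg$baseline, sgrid))
    s <- mean(kneeload:::eval_bumps(cfg$bumps$soleus, cfg$baseline, sgrid))
    g / (g + s)
  }
  r0 <- ratio_of(cfg_b)
  r1 <- ratio_of(cfg_r)
  expect_equal(r1 / r0, 0.75, tolerance = 1e-6)
})

test_that("synthetic EMG envelopes recover the ground-truth modulators", {
  ec <- emg_informed_case()
  env <- compute_envelope(ec$emg$walk)
  env <- apply_delay(normalize_mvc(env, compute_envelope(ec$emg$mvc)),
                     ec$emg$delay)
  for (ch in c("gas_med", "soleus")) {
    truth_mod <- approx(ec$truth$t, ec$truth$activations[, ch],
                        xout = ec$emg$t, rule = 2)$y
    expect_gt(cor(env$channels[, ch], truth_mod), 0.95)
  }
  # stance-averaged activation ratio from EMG matches the truth ratio
  stance_emg <- ec$emg$t <= 0.6 * max(ec$truth$t)
  r_emg <- activation_ratio(env$channels[, "gas_med"],
                            env$channels[, "soleus"], stance_emg)
  r_truth <- activation_ratio(ec$truth$activations[, "gas_med"],
                              ec$truth$activations[, "soleus"],
                              ec$truth$stance_mask)
  expect_lt(abs(r_emg - r_truth), 0.03)
})

test_that("an always-silent channel stays at the noise floor", {
  nc <- normative_case()
  truth <- nc$truth
  truth$activations <- cbind(truth$activations,
                             silent = rep(0, nrow(truth$activations)))
  emg <- generate_emg(truth, channels = c("silent", "soleus"), seed = 4)
  env <- normalize_mvc(compute_envelope(emg$walk),
                       compute_envelope(emg$mvc))
  expect_lt(mean(env$channels[, "silent"]), 0.02)
  expect_gt(mean(env$channels[, "soleus"]), 5 * mean(env$channels[, "silent"]))
})

test_that("cohort generation is seeded and jitters subjects", {
  c1 <- make_cohort(2, seed = 5, with_emg = FALSE)
  c2 <- make_cohort(2, seed = 5, with_emg = FALSE)
  expect_length(c1, 2)
  expect_identical(c1[[1]]$baseline$trial, c2[[1]]$baseline$trial)
  expect_identical(c1[[2]]$retention$truth$activations,
                   c2[[2]]$retention$truth$activations)
  expect_false(c1[[1]]$model$bodyweight == c1[[2]]$model$bodyweight)
  # each subject carries a baseline/retention pair with reduced truth ratio
  sub <- c1[[1]]
  r <- function(cond) activation_ratio(cond$truth$activations[, "gas_med"],
                                       cond$truth$activations[, "soleus"],
                                       cond$truth$stance_mask)
  expect_equal(r(sub$retention) / r(sub$baseline), 0.75, tolerance = 1e-6)
})

test_that("normative KCF shows the expected muscle-dominance phasing", {
  nc <- normative_case()
  cf <- nc$truth$cycle_frac / 0.6      # stance fraction
  peak_at <- function(group) {
    contrib <- nc$kcf$group_contribs_bw[, group]
    contrib[!nc$kcf$stance_mask] <- -Inf
    cf[which.max(contrib)]
  }
  expect_lt(peak_at("hamstrings"), 0.15)          # early stance
  expect_true(peak_at("quadriceps") > 0.10 && peak_at("quadriceps") < 0.45)
  expect_gt(peak_at("gastrocnemius"), 0.5)        # late stance
  # two-peaked total within stance
  tot <- nc$kcf$total_bw[nc$kcf$stance_mask]
  n <- length(tot)
  expect_gt(max(tot[seq_len(n %/% 2)]), 1.5)
  expect_gt(max(tot[(n %/% 2):n]), 1.5)
  expect_lt(min(tot[round(n * 0.35):round(n * 0.65)]),
            min(max(tot[seq_len(n %/% 2)]), max(tot[(n %/% 2):n])))
})
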