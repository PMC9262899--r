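const_trial <- function(model, nT = 5, M = zero_moments()) {
  q <- matrix(0, nT, 3,
              dimnames = list(NULL, model$dofs))
  M_ID <- matrix(rep(M, each = nT), nT, 3,
                 dimnames = list(NULL, model$dofs))
  structure(list(t = seq(0, by = 0.01, length.out = nT), q = q, M_ID = M_ID,
                 stance_mask = rep(TRUE, nT),
                 interseg_axial = rep(0, nT),
                 grf_vertical = rep(0, nT), bodyweight = model$bodyweight),
            class = "gait_trial")
}

test_that("single-muscle frame inverts the affine force law exactly", {
  model <- toy_one_muscle()
  q <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 0)
  M <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 30)
  a_prev <- c(pf = 0)
  st <- solve_timestep(model, q, M, a_prev, objective_spec("natural"))
  # independent closed form: a = (M / r - c0) / c1
  p <- model$muscles$pf$params
  fib <- solve_fiber_equilibrium(p, model$curves, 0,
                                 mtu_length(model, "pf", q))
  mf <- mtu_force(p, model$curves, 0, fib)
  a_closed <- (30 / 0.05 - mf$c0) / mf$c1
  expect_equal(unname(st$a["pf"]), a_closed, tolerance = 1e-6)
  expect_lt(max(abs(st$moment_residual)), 1e-6)
})

test_that("identical agonists share the load equally", {
  model <- toy_two_muscle()
  M <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 40)
  st <- solve_timestep(model, toy_frame(model, M)$q, M,
                       c(gas_med = 0, soleus = 0),
                       objective_spec("natural"))
  expect_equal(unname(st$a["gas_med"]), unname(st$a["soleus"]),
               tolerance = 1e-10)
})

test_that("avoidance weight w drives the activation ratio to 1/w", {
  model <- toy_two_muscle()
  M <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 40)
  st <- solve_timestep(model, toy_frame(model, M)$q, M,
                       c(gas_med = 0, soleus = 0),
                       objective_spec("gastroc_avoidance",
                                      gastroc_weight = 100))
  # Lagrange stationarity: 2 w a_g = lambda r c1 = 2 a_s  =>  a_g/a_s = 1/100
  expect_equal(unname(st$a["gas_med"] / st$a["soleus"]), 1 / 100,
               tolerance = 1e-8)
})

test_that("QP solution matches the exhaustive-search oracle on small toys", {
  for (case in list(
    list(model = toy_two_muscle(), obj = objective_spec("natural"),
         M = c(0, 0, 40), step = 1e-3),
    list(model = toy_two_muscle(),
         obj = objective_spec("gastroc_avoidance"),
         M = c(0, 0, 40), step = 1e-3),
    list(model = toy_three_muscle(), obj = objective_spec("natural"),
         M = c(0, 25, 60), step = 2e-3))) {
    M <- setNames(case$M, case$model$dofs)
    frame <- toy_frame(case$model, M)
    orc <- brute_force_oracle(case$model, frame, case$obj,
                              grid_step = case$step)
    expect_true(orc$feasible)
    st <- solve_timestep(case$model, frame$q, M, frame$a_prev, case$obj)
    expect_lt(max(abs(st$a - orc$a)), case$step + 1e-9)
    expect_lt(abs(st$objective_value - orc$objective_value), 1e-4)
    # oracle never beats the QP
    expect_gte(orc$objective_value, st$objective_value - 1e-12)
  }
})

test_that("oracle flags an empty feasible set beyond total capacity", {
  model <- toy_two_muscle()
  M <- c(hip_flexion = 0, knee_flexion = 0, ankle_plantarflexion = 5000)
  orc <- brute_force_oracle(model, toy_frame(model, M),
                            objective_spec("natural"))
  expect_false(orc$feasible)
  expect_true(is.na(orc$objective_value))
})

test_that("a zero-moment trial at the reference posture stays silent", {
  model <- toy_two_muscle()
  trial <- const_trial(model)
  sol <- solve_trial(model, trial)
  expect_lt(max(abs(sol$activations)), 1e-8)
  expect_lt(max(abs(sol$reserves)), 1e-8)
})

test_that("moment conservation holds at every frame of a full solve", {
  nc <- normative_case()
  expect_lt(max(abs(nc$solution$moment_residuals)), 1e-6)
  # reconstructed muscle moments + reserves = inverse-dynamics moments
  k <- which.max(nc$trial$M_ID[, "ankle_plantarflexion"])
  R <- moment_arm_matrix(nc$model, nc$trial$q[k, ])
  recon <- as.numeric(R %*% nc$solution$forces[k, ]) +
    unname(nc$solution$reserves[k, ])
  expect_equal(recon, unname(nc$trial$M_ID[k, ]), tolerance = 1e-9)
})

test_that("reserve usage is negligible on an achievable synthetic trial", {
  nc <- normative_case()
  expect_lt(max(abs(nc$solution$reserves)), 1e-6)
})

test_that("repeated solves are bit-identical", {
  model <- toy_three_muscle()
  M <- setNames(c(0, 20, 50), model$dofs)
  frame <- toy_frame(model, M)
  s1 <- solve_timestep(model, frame$q, M, frame$a_prev,
                       objective_spec("natural"))
  s2 <- solve_timestep(model, frame$q, M, frame$a_prev,
                       objective_spec("natural"))
  expect_identical(s1$a, s2$a)
  expect_identical(s1$reserves, s2$reserves)
})

test_that("raising the gastrocnemius penalty never raises its activation", {
  model <- toy_three_muscle()
  M <- setNames(c(0, 20, 50), model$dofs)
  frame <- toy_frame(model, M)
  a_g <- sapply(c(1, 10, 100, 1000), function(w) {
    obj <- if (w == 1) objective_spec("natural")
           else objective_spec("gastroc_avoidance", gastroc_weight = w)
    solve_timestep(model, frame$q, M, frame$a_prev, obj)$a[["gas_med"]]
  })
  expect_true(all(diff(a_g) <= 1e-10))
})

test_that("ratio band constraints are honored within tolerance", {
  model <- toy_three_muscle()
  M <- setNames(c(0, 20, 50), model$dofs)
  frame <- toy_frame(model, M)
  rf <- list(heads = "gas_med", r = 0.2, enforce = TRUE, soleus = "soleus",
             tolerance = 0.02)
  st <- solve_timestep(model, frame$q, M, frame$a_prev,
                       objective_spec("natural"), ratio_frame = rf)
  expect_lte(st$ratio_residual, 0.02 + 1e-9)
  expect_lt(max(abs(st$moment_residual)), 1e-6)
})
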