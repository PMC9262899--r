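test_that("characteristic curves satisfy their qualitative invariants", {
  cv <- default_curves()
  x_below <- seq(0.5, 1, by = 0.05)
  x_above <- seq(1.001, 1.2, by = 0.001)

  expect_true(all(cv$tendon_fl(x_below) == 0))
  expect_true(all(diff(cv$tendon_fl(x_above)) > 0))
  expect_equal(cv$tendon_fl(1 + cv$tendon_strain_at_fo), 1)

  lm <- seq(0.3, 1.8, by = 0.01)
  expect_equal(cv$active_fl(1), 1)
  expect_true(all(cv$active_fl(lm) >= 0))
  expect_true(max(cv$active_fl(lm)) == cv$active_fl(1))

  expect_true(all(cv$passive_fl(x_below) == 0))
  expect_true(all(diff(cv$passive_fl(seq(1, 1.8, by = 0.01))) >= 0))

  # C1 at the tendon/passive engagement point: derivative ~ 0 from above
  h <- 1e-7
  expect_lt((cv$tendon_fl(1 + h) - cv$tendon_fl(1)) / h, 1e-4)
  expect_lt((cv$passive_fl(1 + h) - cv$passive_fl(1)) / h, 1e-4)
})

test_that("eval_curves returns the landmark multiplier values", {
  cv <- default_curves()
  out <- eval_curves(cv, l_m_norm = 1, l_t_norm = 1)
  expect_equal(out$f_l, 1)
  expect_equal(out$f_t, 0)
  expect_equal(eval_curves(cv, 0.9, 1.02)$f_pe, 0)
  expect_error(eval_curves(cv, -1, 1), "positive")
  expect_error(eval_curves(cv, 1, 0), "positive")
})

test_that("muscle_params validates its invariants", {
  expect_error(muscle_params("m", -1, 0.1, 0.2, 0), "f_o_m")
  expect_error(muscle_params("m", 100, 0, 0.2, 0), "l_o_m")
  expect_error(muscle_params("m", 100, 0.1, -0.1, 0), "l_s_t")
  expect_error(muscle_params("m", 100, 0.1, 0.2, pi / 2), "alpha_o")
})

test_that("zero-force configuration returns the optimal fiber length", {
  cv <- default_curves()
  p <- muscle_params("m", 1000, 0.05, 0.25, 0.3)
  l_mtu <- p$l_s_t + p$l_o_m * cos(p$alpha_o)
  fib <- solve_fiber_equilibrium(p, cv, a_prev = 0, l_mtu = l_mtu)
  expect_equal(fib$l_m, p$l_o_m, tolerance = 1e-9)
  expect_equal(fib$l_t, p$l_s_t, tolerance = 1e-9)
})

test_that("equilibrium residual is below 1e-8 of max isometric force", {
  cv <- default_curves()
  model <- default_model()
  for (mu in c("soleus", "gas_med", "vas_lat", "semimem")) {
    p <- model$muscles[[mu]]$params
    l0 <- p$l_s_t + p$l_o_m * cos(p$alpha_o)
    for (a in c(0.05, 0.5, 1)) {
      for (dl in c(-0.01, 0, 0.015)) {
        fib <- solve_fiber_equilibrium(p, cv, a, l0 + dl)
        res <- kneeload:::equilibrium_residual(p, cv, a, l0 + dl, fib$l_m)
        expect_lt(abs(res), 1e-8 * p$f_o_m)
        expect_equal(fib$l_m * cos(fib$alpha) + fib$l_t, l0 + dl,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("stiffened compliant tendon approaches the rigid-tendon solution", {
  p <- muscle_params("m", 1500, 0.06, 0.30, 0.25)
  l_mtu <- p$l_s_t + p$l_o_m * cos(p$alpha_o) + 0.008
  rigid <- rigid_tendon_fiber(p, l_mtu)
  stiff <- default_curves(tendon_strain_at_fo = 0.049 / 100)
  fib100 <- solve_fiber_equilibrium(p, stiff, a_prev = 0.8, l_mtu = l_mtu)
  expect_lt(abs(fib100$l_m - rigid$l_m) / rigid$l_m, 0.01)

  # fiber projection converges to l_mtu - l_s_t as stiffness grows
  soft <- solve_fiber_equilibrium(p, default_curves(), 0.8, l_mtu)
  gap <- function(f) abs(f$l_m * cos(f$alpha) - (l_mtu - p$l_s_t))
  expect_lt(gap(fib100), gap(soft))
})

test_that("rigid-tendon fiber geometry is exact", {
  p0 <- muscle_params("flat", 1000, 0.05, 0.20, 0)
  expect_equal(rigid_tendon_fiber(p0, 0.26)$l_m, 0.06)
  p <- muscle_params("penn", 1000, 0.05, 0.20, 0.4)
  fib <- rigid_tendon_fiber(p, p$l_s_t + p$l_o_m * cos(p$alpha_o))
  expect_equal(fib$l_m, p$l_o_m, tolerance = 1e-12)
  expect_error(rigid_tendon_fiber(p, 0.19), "slack")
})

test_that("MTU force is exactly affine in activation", {
  cv <- default_curves()
  p <- muscle_params("m", 1200, 0.07, 0.25, 0.2)
  fib <- solve_fiber_equilibrium(p, cv, 0.4, p$l_s_t + 0.95 * p$l_o_m)
  f0 <- mtu_force(p, cv, 0, fib)$force
  f1 <- mtu_force(p, cv, 1, fib)$force
  fh <- mtu_force(p, cv, 0.5, fib)$force
  expect_identical(fh, (f0 + f1) / 2)
  f3 <- mtu_force(p, cv, 0.3, fib)
  expect_identical(f3$force, f3$c0 + f3$c1 * 0.3)
  expect_gte(f3$c1, 0)
})

test_that("MTU force landmarks: zero at rest, f_o_m at full activation", {
  cv <- default_curves()
  p <- muscle_params("m", 1300, 0.08, 0.30, 0)
  fib <- kneeload:::new_fiber_state(p$l_o_m, p$l_s_t, 0, 0)
  expect_equal(mtu_force(p, cv, 0, fib)$force, 0)
  expect_equal(mtu_force(p, cv, 1, fib)$force, p$f_o_m)
})

test_that("equilibrium tendon force is monotone in previous activation", {
  cv <- default_curves()
  p <- muscle_params("m", 2000, 0.05, 0.25, 0.3)
  l_mtu <- p$l_s_t + p$l_o_m * cos(p$alpha_o) + 0.004
  f_t <- sapply(seq(0, 1, by = 0.1), function(a) {
    fib <- solve_fiber_equilibrium(p, cv, a, l_mtu)
    cv$tendon_fl(fib$l_t / p$l_s_t)
  })
  expect_true(all(diff(f_t) >= -1e-12))
})

test_that("fixed-height pennation keeps muscle height constant", {
  cv <- default_curves()
  p <- muscle_params("m", 1000, 0.06, 0.25, 0.35)
  lms <- seq(0.5, 1.5, by = 0.25) * p$l_o_m
  heights <- lms * sin(pennation_angle(p, lms, cv$pennation_cap))
  expect_equal(heights, rep(p$l_o_m * sin(p$alpha_o), length(lms)),
               tolerance = 1e-12)
})

test_that("infeasible geometry is rejected with the muscle named", {
  cv <- default_curves()
  p <- muscle_params("soleus_toy", 1000, 0.05, 0.25, 0)
  expect_error(solve_fiber_equilibrium(p, cv, 0.5, 0.24), "soleus_toy")
})
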