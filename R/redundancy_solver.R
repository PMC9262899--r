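#' Static-optimization objective specification
#'
#' The natural objective minimizes the sum of squared activations (a common
#' surrogate for metabolic cost). The gastrocnemius-avoidance objective
#' additionally weights the squared activation of both gastrocnemius heads
#' (default weight 100), shifting plantarflexion duty to the soleus and knee
#' flexion duty to the hamstrings. Reserve torque actuators (one ideal torque
#' per DOF) guarantee feasibility and carry a heavy quadratic penalty so that
#' muscles do essentially all the work.
#'
#' @param kind \code{"natural"} or \code{"gastroc_avoidance"}.
#' @param gastroc_weight Penalty weight on gastrocnemius activations for the
#'   avoidance objective (> 1; default 100).
#' @param reserve_weight Quadratic penalty per (N m)^2 of reserve torque
#'   (default 1e6, keeping reserve usage near 1e-8 N m on achievable trials).
#' @param gastroc_muscles Names of the penalized gastrocnemius heads.
#' @return An object of class \code{objective_spec}.
#' @export
objective_spec <- function(kind = c("natural", "gastroc_avoidance"),
                           gastroc_weight = 100, reserve_weight = 1e6,
                           gastroc_muscles = c("gas_med", "gas_lat")) {
  kind <- match.arg(kind)
  if (kind == "gastroc_avoidance" && gastroc_weight <= 1)
    stop("gastroc_weight must exceed 1 for the avoidance objective")
  structure(list(kind = kind, gastroc_weight = gastroc_weight,
                 reserve_weight = reserve_weight,
                 gastroc_muscles = gastroc_muscles),
            class = "objective_spec")
}

activation_weights <- function(objective, muscle_names) {
  w <- setNames(rep(1, length(muscle_names)), muscle_names)
  if (objective$kind == "gastroc_avoidance")
    w[intersect(objective$gastroc_muscles, muscle_names)] <-
      objective$gastroc_weight
  w
}

#' EMG ratio-constraint specification
#'
#' Per-timestep target activation ratios for each gastrocnemius head against
#' the soleus, with the tolerance band of the constraint
#' \eqn{|r_{EMG} - a_g/(a_g + a_s)| < tol}. Enforcement is masked to frames
#' where the delayed gastrocnemius-plus-soleus envelope exceeds a floor (the
#' ratio is ill-conditioned when both envelopes are near zero).
#'
#' @param ratios Matrix (timesteps x heads) of target ratios in [0, 1], with
#'   column names naming the gastrocnemius heads.
#' @param mask Logical matrix of the same shape: where the constraint is
#'   enforced.
#' @param soleus Name of the soleus muscle (default \code{"soleus"}).
#' @param tolerance Ratio tolerance (default 0.02).
#' @param delay Electromechanical delay already applied to the envelopes, s.
#' @return An object of class \code{ratio_constraint_spec}.
#' @export
ratio_constraint_spec <- function(ratios, mask, soleus = "soleus",
                                  tolerance = 0.02, delay = 0.040) {
  ratios <- as.matrix(ratios)
  mask <- as.matrix(mask)
  stopifnot(all(dim(ratios) == dim(mask)), !is.null(colnames(ratios)),
            tolerance > 0, tolerance < 0.5)
  if (any(ratios[mask] < 0 | ratios[mask] > 1))
    stop("target ratios must lie in [0, 1] on enforced frames")
  structure(list(ratios = ratios, mask = mask, soleus = soleus,
                 tolerance = tolerance, delay = delay),
            class = "ratio_constraint_spec")
}

#' Build a ratio-constraint spec from raw EMG on a trial's time grid
#'
#' Runs the full envelope pipeline (envelope, MVC normalization,
#' electromechanical delay), resamples the delayed normalized envelopes onto
#' the trial's time grid, and forms per-frame target ratios for each
#' gastrocnemius head against the soleus. Frames outside stance or with a
#' delayed gastrocnemius-plus-soleus envelope below \code{floor} are masked
#' out.
#'
#' @param trial A \code{gait_trial}.
#' @param emg Output of \code{\link{generate_emg}} or a list with
#'   \code{walk} and \code{mvc} \code{emg_recording}s.
#' @param heads Gastrocnemius channel names.
#' @param soleus Soleus channel name.
#' @param delay Electromechanical delay, s (default 0.040).
#' @param tolerance Ratio tolerance (default 0.02).
#' @param floor Enforcement floor on the summed delayed envelope, fraction of
#'   MVC (default 0.01).
#' @return A \code{ratio_constraint_spec} on the trial grid.
#' @export
ratio_spec_from_emg <- function(trial, emg, heads = c("gas_med", "gas_lat"),
                                soleus = "soleus", delay = 0.040,
                                tolerance = 0.02, floor = 0.01) {
  chans <- c(heads, soleus)
  env <- compute_envelope(emg$walk, channels = chans)
  mvc <- compute_envelope(emg$mvc, channels = chans)
  env <- apply_delay(normalize_mvc(env, mvc), delay)
  t_emg <- seq(0, by = 1 / env$fs, length.out = nrow(env$channels))
  on_grid <- sapply(chans, function(ch)
    stats::approx(t_emg, env$channels[, ch], xout = trial$t, rule = 2)$y)
  sol <- on_grid[, soleus]
  ratios <- sapply(heads, function(h)
    ifelse(on_grid[, h] + sol > 0, on_grid[, h] / (on_grid[, h] + sol), 0))
  mask <- sapply(heads, function(h)
    trial$stance_mask & (on_grid[, h] + sol >= floor))
  ratio_constraint_spec(ratios, mask, soleus = soleus,
                        tolerance = tolerance, delay = delay)
}

# Assemble and solve the per-frame QP:
#   min sum_i w_i a_i^2 + w_res sum_j res_j^2
#   s.t. sum_i R[j,i] (c0_i + c1_i a_i) + res_j = M_j   (each DOF)
#        lb <= a <= 1, ratio band constraints on enforced heads
solve_frame_qp <- function(R, c0, c1, M, w_act, w_res, lb,
                           ratio_frame = NULL) {
  nM <- length(c0)
  nD <- nrow(R)
  n <- nM + nD
  Dmat <- diag(c(2 * w_act, rep(2 * w_res, nD)))
  dvec <- rep(0, n)
  Aeq <- cbind(R %*% diag(c1, nM), diag(nD))
  beq <- as.numeric(M - R %*% c0)
  A_lb <- cbind(diag(nM), matrix(0, nM, nD))
  A_ub <- -A_lb
  Amat <- rbind(Aeq, A_lb, A_ub)
  bvec <- c(beq, lb, rep(-1, nM))
  if (!is.null(ratio_frame)) {
    i_s <- ratio_frame$i_soleus
    for (h in seq_along(ratio_frame$i_heads)) {
      if (!ratio_frame$enforce[h]) next
      i_g <- ratio_frame$i_heads[h]
      r <- ratio_frame$r[h]
      tol <- ratio_frame$tolerance
      up <- numeric(n); lo <- numeric(n)
      up[i_g] <- -(1 - (r + tol)); up[i_s] <- r + tol       # ratio <= r+tol
      lo[i_g] <- 1 - (r - tol);    lo[i_s] <- -(r - tol)    # ratio >= r-tol
      Amat <- rbind(Amat, up, lo)
      bvec <- c(bvec, 0, 0)
    }
  }
  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, t(Amat), bvec, meq = nD),
    error = function(e) e)
  if (inherits(sol, "error")) {
    # fallback: penalized box-constrained NLP (logged)
    warning("QP solve failed (", conditionMessage(sol),
            "); falling back to penalized NLP")
    obj <- function(x) {
      eqres <- Aeq %*% x - beq
      ineq <- Amat[-(seq_len(nD)), , drop = FALSE] %*% x -
        bvec[-(seq_len(nD))]
      sum(w_act * x[seq_len(nM)]^2) + w_res * sum(x[-(seq_len(nM))]^2) +
        1e10 * sum(eqres^2) + 1e10 * sum(pmin(ineq, 0)^2)
    }
    fit <- stats::optim(c(pmax(lb, 0), rep(0, nD)), obj,
                        method = "L-BFGS-B",
                        lower = c(lb, rep(-1e4, nD)),
                        upper = c(rep(1, nM), rep(1e4, nD)),
                        control = list(maxit = 2000, factr = 1e4))
    x <- fit$par
  } else x <- sol$solution
  list(a = pmin(pmax(x[seq_len(nM)], 0), 1), reserves = x[nM + seq_len(nD)])
}

#' Solve muscle redundancy at one timestep
#'
#' Solves each muscle's fiber equilibrium at the frame's posture using the
#' previous timestep's activation, freezes the fiber lengths (making MTU
#' force affine in activation), and solves the resulting strictly convex QP:
#' activation cost subject to moment matching at every DOF, activation
#' bounds, and optional EMG ratio band constraints.
#'
#' @param model A \code{planar_model}.
#' @param q Named posture vector, rad.
#' @param M_ID Named inverse-dynamics moment vector, N m.
#' @param a_prev Named activation vector from the previous timestep.
#' @param objective An \code{objective_spec}.
#' @param ratio_frame Optional per-frame ratio constraint: list with
#'   \code{heads}, \code{r}, \code{enforce}, \code{soleus},
#'   \code{tolerance}.
#' @param fiber_init Optional named numeric of initial fiber lengths, m.
#' @return List with activations \code{a}, \code{reserves} (N m),
#'   \code{forces} (N), affine coefficients \code{c0}, \code{c1},
#'   \code{fiber_lengths}, \code{equilibrium_residuals},
#'   \code{moment_residual} (N m), \code{objective_value} and
#'   \code{ratio_residual}.
#' @export
solve_timestep <- function(model, q, M_ID, a_prev, objective,
                           ratio_frame = NULL, fiber_init = NULL) {
  mus <- names(model$muscles)
  nM <- length(mus)
  c0 <- c1 <- lm <- eqres <- setNames(numeric(nM), mus)
  for (i in seq_len(nM)) {
    mu <- mus[i]
    init <- if (!is.null(fiber_init)) fiber_init[[mu]] else NULL
    fib <- solve_fiber_equilibrium(model$muscles[[mu]]$params, model$curves,
                                   a_prev[[mu]], mtu_length(model, mu, q),
                                   l_m_init = init)
    co <- mtu_force_coeffs(model$muscles[[mu]]$params, model$curves, fib)
    c0[i] <- co$c0; c1[i] <- co$c1
    lm[i] <- fib$l_m; eqres[i] <- fib$equilibrium_residual
  }
  R <- moment_arm_matrix(model, q)
  w_act <- activation_weights(objective, mus)
  lb <- rep(0, nM)
  rf <- NULL
  if (!is.null(ratio_frame) && any(ratio_frame$enforce)) {
    rf <- ratio_frame
    rf$i_heads <- match(ratio_frame$heads, mus)
    rf$i_soleus <- match(ratio_frame$soleus, mus)
    if (anyNA(c(rf$i_heads, rf$i_soleus)))
      stop("ratio constraint names unknown to the model")
    lb[c(rf$i_heads[rf$enforce], rf$i_soleus)] <- 1e-6
  }
  sol <- solve_frame_qp(R, c0, c1, M_ID[model$dofs], w_act,
                        objective$reserve_weight, lb, rf)
  a <- setNames(sol$a, mus)
  forces <- c0 + c1 * a
  mres <- as.numeric(R %*% forces + sol$reserves - M_ID[model$dofs])
  rres <- NA_real_
  if (!is.null(rf)) {
    res_h <- rep(NA_real_, length(rf$heads))
    for (h in seq_along(rf$heads)) {
      if (!rf$enforce[h]) next
      ag <- a[[rf$heads[h]]]; as_ <- a[[rf$soleus]]
      res_h[h] <- abs(ag / (ag + as_) - rf$r[h])
    }
    rres <- if (all(is.na(res_h))) NA_real_ else max(res_h, na.rm = TRUE)
  }
  list(a = a, reserves = setNames(sol$reserves, model$dofs),
       forces = forces, c0 = c0, c1 = c1, fiber_lengths = lm,
       equilibrium_residuals = eqres,
       moment_residual = setNames(mres, model$dofs),
       objective_value = sum(w_act * a^2),
       ratio_residual = rres)
}

#' Solve muscle redundancy over a full trial
#'
#' Sequential per-timestep solves with the activation history threading into
#' the fiber-equilibrium stage. The first frame is bootstrapped with zero
#' previous activation and then re-solved once with its own optimized
#' activations (one warm-start pass).
#'
#' @param model A \code{planar_model}.
#' @param trial A \code{gait_trial}.
#' @param objective An \code{objective_spec} (default: natural).
#' @param ratio Optional \code{ratio_constraint_spec} on the trial grid.
#' @return An object of class \code{activation_solution} with per-frame
#'   matrices: \code{activations}, \code{forces}, \code{fiber_lengths},
#'   \code{equilibrium_residuals}, \code{reserves},
#'   \code{moment_residuals}, plus \code{objective_values},
#'   \code{ratio_residuals}, the trial time grid and stance mask.
#' @export
solve_trial <- function(model, trial, objective = objective_spec("natural"),
                        ratio = NULL) {
  stopifnot(inherits(model, "planar_model"), inherits(trial, "gait_trial"))
  if (!is.null(ratio)) stopifnot(inherits(ratio, "ratio_constraint_spec"))
  mus <- names(model$muscles)
  nT <- length(trial$t)
  nM <- length(mus)
  act <- forces <- flm <- eqr <- matrix(NA_real_, nT, nM,
                                        dimnames = list(NULL, mus))
  res <- mres <- matrix(NA_real_, nT, length(model$dofs),
                        dimnames = list(NULL, model$dofs))
  objv <- rres <- rep(NA_real_, nT)
  frame_ratio <- function(k) {
    if (is.null(ratio)) return(NULL)
    list(heads = colnames(ratio$ratios), r = ratio$ratios[k, ],
         enforce = ratio$mask[k, ], soleus = ratio$soleus,
         tolerance = ratio$tolerance)
  }
  a_prev <- setNames(rep(0, nM), mus)
  fiber_init <- NULL
  for (pass in c(1L, 2L)) {
    # pass 2 = warm-start re-solve of frame 1 with its optimized activations
    ks <- if (pass == 1L) seq_len(nT) else 1L
    if (pass == 2L) {
      a_prev <- act[1, ]
      fiber_init <- flm[1, ]
    }
    for (k in ks) {
      st <- tryCatch(
        solve_timestep(model, trial$q[k, ], trial$M_ID[k, ], a_prev,
                       objective, frame_ratio(k), fiber_init),
        error = function(e)
          stop("frame ", k, ": ", conditionMessage(e), call. = FALSE))
      act[k, ] <- st$a
      forces[k, ] <- st$forces
      flm[k, ] <- st$fiber_lengths
      eqr[k, ] <- st$equilibrium_residuals
      res[k, ] <- st$reserves
      mres[k, ] <- st$moment_residual
      objv[k] <- st$objective_value
      rres[k] <- st$ratio_residual
      a_prev <- st$a
      fiber_init <- st$fiber_lengths
    }
  }
  structure(
    list(activations = act, forces = forces, fiber_lengths = flm,
         equilibrium_residuals = eqr, reserves = res,
         moment_residuals = mres, objective_values = objv,
         ratio_residuals = rres, t = trial$t,
         stance_mask = trial$stance_mask, objective = objective),
    class = "activation_solution")
}

#' Exhaustive-search oracle for small redundancy problems
#'
#' Verification oracle for frames with at most 4 muscles and 2 DOFs:
#' enumerates a grid over the activations of \code{nMuscles - nDOF} free
#' muscles and solves the remaining activations exactly from the moment
#' equalities (so every evaluated point satisfies the constraints exactly),
#' returning the feasible point of least cost. No reserve actuators.
#'
#' @param model A \code{planar_model} (small toy model).
#' @param trial_frame List with \code{q}, \code{M_ID} and optional
#'   \code{a_prev} (default all zero).
#' @param objective An \code{objective_spec}.
#' @param grid_step Grid resolution in activation (default 1e-3).
#' @return List with \code{a}, \code{objective_value} and \code{feasible}
#'   (FALSE with empty results when no grid point satisfies the bounds).
#' @export
brute_force_oracle <- function(model, trial_frame, objective,
                               grid_step = 1e-3) {
  mus <- names(model$muscles)
  nM <- length(mus)
  stopifnot(nM <= 4)
  q <- trial_frame$q
  a_prev <- trial_frame$a_prev
  if (is.null(a_prev)) a_prev <- setNames(rep(0, nM), mus)
  c0 <- c1 <- setNames(numeric(nM), mus)
  for (mu in mus) {
    fib <- solve_fiber_equilibrium(model$muscles[[mu]]$params, model$curves,
                                   a_prev[[mu]], mtu_length(model, mu, q))
    co <- mtu_force_coeffs(model$muscles[[mu]]$params, model$curves, fib)
    c0[mu] <- co$c0; c1[mu] <- co$c1
  }
  R <- moment_arm_matrix(model, q)
  A <- R %*% diag(c1, nM)
  rhs <- as.numeric(trial_frame$M_ID[model$dofs] - R %*% c0)
  w <- activation_weights(objective, mus)

  # keep only DOFs some muscle actuates; unactuated DOFs must carry no moment
  live <- apply(abs(A), 1, max) > 1e-12
  if (any(abs(rhs[!live]) > 1e-9))
    return(list(a = setNames(rep(NA_real_, nM), mus),
                objective_value = NA_real_, feasible = FALSE))
  A <- A[live, , drop = FALSE]
  rhs <- rhs[live]
  nD <- nrow(A)
  stopifnot(nD <= 2, nM >= nD)

  # pick the best-conditioned elimination set of nD muscles
  combs <- utils::combn(nM, nD)
  dets <- apply(combs, 2, function(ix)
    abs(det(A[, ix, drop = FALSE])))
  elim <- combs[, which.max(dets)]
  if (max(dets) < 1e-12) stop("moment map is rank deficient")
  free <- setdiff(seq_len(nM), elim)
  A_e_inv <- solve(A[, elim, drop = FALSE])

  if (length(free) == 0) {
    a_e <- as.numeric(A_e_inv %*% rhs)
    feas <- all(a_e >= -1e-12 & a_e <= 1 + 1e-12)
    a <- setNames(pmin(pmax(a_e, 0), 1), mus[elim])[mus]
    return(list(a = if (feas) a else setNames(rep(NA_real_, nM), mus),
                objective_value = if (feas) sum(w * a^2) else NA_real_,
                feasible = feas))
  }
  grids <- rep(list(seq(0, 1, by = grid_step)), length(free))
  G <- as.matrix(expand.grid(grids))
  a_elim <- A_e_inv %*% (matrix(rhs, nD, nrow(G)) -
                           A[, free, drop = FALSE] %*% t(G))
  ok <- colSums(a_elim < -1e-12 | a_elim > 1 + 1e-12) == 0
  if (!any(ok))
    return(list(a = setNames(rep(NA_real_, nM), mus),
                objective_value = NA_real_, feasible = FALSE))
  cost <- colSums(w[free] * t(G^2)) +
    colSums(w[elim] * pmin(pmax(a_elim, 0), 1)^2)
  cost[!ok] <- Inf
  best <- which.min(cost)
  a <- setNames(numeric(nM), mus)
  a[free] <- G[best, ]
  a[elim] <- pmin(pmax(a_elim[, best], 0), 1)
  list(a = a, objective_value = cost[best], feasible = TRUE)
}
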