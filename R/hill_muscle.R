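#' Musculotendon parameter set
#'
#' Bundle the four constants of a Hill-type musculotendon actuator: maximum
#' isometric force, optimal fiber length, tendon slack length, and pennation
#' angle at optimal fiber length.
#'
#' @param name Muscle name (character scalar).
#' @param f_o_m Maximum isometric muscle force, N. Must be positive.
#' @param l_o_m Optimal fiber length, m. Must be positive.
#' @param l_s_t Tendon slack length, m. Must be non-negative.
#' @param alpha_o Pennation angle at optimal fiber length, rad, in [0, pi/2).
#' @return An object of class \code{muscle_params}.
#' @export
muscle_params <- function(name, f_o_m, l_o_m, l_s_t, alpha_o = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(f_o_m) || f_o_m <= 0) stop("f_o_m must be positive")
  if (!is.finite(l_o_m) || l_o_m <= 0) stop("l_o_m must be positive")
  if (!is.finite(l_s_t) || l_s_t < 0) stop("l_s_t must be non-negative")
  if (!is.finite(alpha_o) || alpha_o < 0 || alpha_o >= pi / 2)
    stop("alpha_o must lie in [0, pi/2)")
  structure(
    list(name = name, f_o_m = f_o_m, l_o_m = l_o_m,
         l_s_t = l_s_t, alpha_o = alpha_o),
    class = "muscle_params"
  )
}

#' Analytic musculotendon characteristic curves
#'
#' Smooth, once-differentiable analytic forms for the tendon force-length,
#' active fiber force-length, and passive fiber force-length multipliers:
#' \itemize{
#'   \item tendon: zero at or below slack length, then
#'     \eqn{(e^{k x} - 1 - k x)} in tendon strain \eqn{x}, normalized so the
#'     multiplier is 1 at strain \code{tendon_strain_at_fo}; the derivative
#'     vanishes at slack length so the curve is C1.
#'   \item active: Gaussian \eqn{\exp(-((l/l_o - 1)/w)^2)} with width
#'     \code{active_width}, maximum exactly 1 at optimal fiber length.
#'   \item passive: same exponential form as the tendon, engaging at optimal
#'     fiber length and reaching 1 at strain \code{passive_strain_at_fo}.
#' }
#'
#' @param tendon_strain_at_fo Tendon strain at which the tendon carries one
#'   maximum isometric force (default 0.049). Smaller values give a stiffer
#'   tendon; the rigid-tendon limit is approached as this goes to zero.
#' @param active_width Width of the active force-length Gaussian in
#'   normalized fiber length (default 0.45).
#' @param passive_strain_at_fo Fiber strain beyond optimal length at which the
#'   passive multiplier reaches 1 (default 0.7).
#' @param pennation_cap Maximum pennation angle, rad (default 84 degrees),
#'   guarding the fixed-height model against the vertical-fiber singularity.
#' @return An object of class \code{curve_set} with function elements
#'   \code{tendon_fl}, \code{active_fl}, \code{passive_fl} and the pennation
#'   cap.
#' @export
default_curves <- function(tendon_strain_at_fo = 0.049,
                           active_width = 0.45,
                           passive_strain_at_fo = 0.7,
                           pennation_cap = 84 * pi / 180) {
  stopifnot(tendon_strain_at_fo > 0, active_width > 0,
            passive_strain_at_fo > 0)
  # shape constants: k scales inversely with the strain at one F_o so that
  # curve shape is preserved as the tendon is stiffened
  k_t <- 3 / tendon_strain_at_fo
  k_p <- 8 / passive_strain_at_fo
  expc1 <- function(z) exp(z) - 1 - z   # = z^2/2 + O(z^3), C1 at 0
  tendon_norm <- expc1(k_t * tendon_strain_at_fo)
  passive_norm <- expc1(k_p * passive_strain_at_fo)
  structure(
    list(
      tendon_fl = function(l_t_norm) {
        s <- pmax(l_t_norm - 1, 0)
        expc1(k_t * s) / tendon_norm
      },
      active_fl = function(l_m_norm) {
        exp(-((l_m_norm - 1) / active_width)^2)
      },
      passive_fl = function(l_m_norm) {
        s <- pmax(l_m_norm - 1, 0)
        expc1(k_p * s) / passive_norm
      },
      tendon_strain_at_fo = tendon_strain_at_fo,
      pennation_cap = pennation_cap
    ),
    class = "curve_set"
  )
}

#' Evaluate the three force-length multipliers
#'
#' @param curves A \code{curve_set}.
#' @param l_m_norm Fiber length normalized by optimal fiber length (> 0).
#' @param l_t_norm Tendon length normalized by tendon slack length (> 0).
#' @return List with elements \code{f_l}, \code{f_pe}, \code{f_t}.
#' @export
eval_curves <- function(curves, l_m_norm, l_t_norm) {
  stopifnot(inherits(curves, "curve_set"))
  if (any(!is.finite(l_m_norm)) || any(l_m_norm <= 0))
    stop("l_m_norm must be positive")
  if (any(!is.finite(l_t_norm)) || any(l_t_norm <= 0))
    stop("l_t_norm must be positive")
  list(f_l = curves$active_fl(l_m_norm),
       f_pe = curves$passive_fl(l_m_norm),
       f_t = curves$tendon_fl(l_t_norm))
}

#' Pennation angle under the fixed-height assumption
#'
#' The muscle belly keeps constant height \eqn{l_o^m \sin\alpha_o}, so
#' \eqn{\alpha(l^m) = \arcsin(l_o^m \sin\alpha_o / l^m)}, capped to avoid the
#' vertical-fiber singularity.
#'
#' @param params A \code{muscle_params}.
#' @param l_m Fiber length, m.
#' @param cap Maximum pennation angle, rad.
#' @return Pennation angle, rad.
#' @export
pennation_angle <- function(params, l_m, cap = 84 * pi / 180) {
  h <- params$l_o_m * sin(params$alpha_o)
  asin(pmin(h / pmax(l_m, .Machine$double.eps), sin(cap)))
}

# Static fiber-tendon force balance at fixed MTU length and activation:
#   -F_o f^T(l^t / l_s^t) + F_o (a f^l + f^PE) cos(alpha) = 0
# Returned in newtons. A slack-free tendon (l_s_t == 0) is treated as rigid
# and never reaches this residual.
equilibrium_residual <- function(params, curves, a, l_mtu, l_m) {
  alpha <- pennation_angle(params, l_m, curves$pennation_cap)
  l_t <- l_mtu - l_m * cos(alpha)
  l_t_norm <- l_t / params$l_s_t
  f_t <- curves$tendon_fl(pmax(l_t_norm, 0))
  lm_n <- l_m / params$l_o_m
  fiber <- (a * curves$active_fl(lm_n) + curves$passive_fl(lm_n)) * cos(alpha)
  params$f_o_m * (fiber - f_t)
}

new_fiber_state <- function(l_m, l_t, alpha, residual) {
  structure(list(l_m = l_m, l_t = l_t, alpha = alpha,
                 equilibrium_residual = residual),
            class = "fiber_state")
}

#' Fiber length assuming a rigid tendon
#'
#' With the tendon pinned at slack length, fixed-height geometry gives the
#' fiber length in closed form:
#' \eqn{l^m = \sqrt{(l^{MTU} - l_s^t)^2 + (l_o^m \sin\alpha_o)^2}}.
#'
#' @param params A \code{muscle_params}.
#' @param l_mtu Musculotendon length, m; must exceed tendon slack length.
#' @return A \code{fiber_state} with \code{l_t} equal to the slack length.
#' @export
rigid_tendon_fiber <- function(params, l_mtu) {
  proj <- l_mtu - params$l_s_t
  if (!is.finite(proj) || proj <= 0)
    stop(sprintf("infeasible geometry for '%s': MTU length %.4f m does not exceed tendon slack length %.4f m",
                 params$name, l_mtu, params$l_s_t))
  h <- params$l_o_m * sin(params$alpha_o)
  l_m <- sqrt(proj^2 + h^2)
  alpha <- atan2(h, proj)
  new_fiber_state(l_m, params$l_s_t, alpha, residual = NA_real_)
}

#' Solve the musculotendon static equilibrium for fiber length
#'
#' Balances tendon force against active plus passive fiber force (projected
#' through the pennation angle) at a given MTU length, using the activation
#' carried over from the previous timestep. Newton iteration with a numeric
#' derivative, falling back to bisection on [0.3, 1.8] optimal fiber lengths
#' if Newton stalls.
#'
#' @param params A \code{muscle_params}.
#' @param curves A \code{curve_set}.
#' @param a_prev Activation from the previous timestep, in [0, 1].
#' @param l_mtu Current musculotendon length, m.
#' @param l_m_init Optional initial fiber length, m (e.g. the previous
#'   timestep's solution). Defaults to the rigid-tendon estimate.
#' @param tol Absolute residual tolerance as a fraction of maximum isometric
#'   force (default 1e-10; residuals are reliably below 1e-8 * f_o_m).
#' @param max_iter Newton iteration cap (default 50).
#' @return A \code{fiber_state}.
#' @export
solve_fiber_equilibrium <- function(params, curves, a_prev, l_mtu,
                                    l_m_init = NULL, tol = 1e-10,
                                    max_iter = 50L) {
  stopifnot(inherits(params, "muscle_params"), inherits(curves, "curve_set"))
  if (!is.finite(a_prev) || a_prev < 0 || a_prev > 1)
    stop("a_prev must lie in [0, 1]")
  if (params$l_s_t <= 0) {
    # no tendon to stretch: geometry alone fixes the fiber length
    return(rigid_tendon_fiber(params, l_mtu))
  }
  if (l_mtu <= params$l_s_t * (1 + 1e-9))
    stop(sprintf("infeasible geometry for '%s': MTU length %.4f m <= tendon slack length %.4f m",
                 params$name, l_mtu, params$l_s_t))

  f_tol <- tol * params$f_o_m
  lo <- 0.05 * params$l_o_m
  hi <- min(2.5 * params$l_o_m, l_mtu / cos(curves$pennation_cap))
  phi <- function(l_m) equilibrium_residual(params, curves, a_prev, l_mtu, l_m)

  l_m <- if (is.null(l_m_init)) rigid_tendon_fiber(params, l_mtu)$l_m
         else l_m_init
  l_m <- min(max(l_m, lo), hi)
  h <- 1e-7 * params$l_o_m
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- phi(l_m)
    if (abs(r) < f_tol) { converged <- TRUE; break }
    dr <- (phi(l_m + h) - phi(l_m - h)) / (2 * h)
    if (!is.finite(dr) || abs(dr) < .Machine$double.eps) break
    step <- r / dr
    # damp steps to stay inside the physical fiber-length window
    l_new <- l_m - step
    if (!is.finite(l_new)) break
    l_m <- min(max(l_new, lo), hi)
  }
  if (!converged && abs(phi(l_m)) >= f_tol) {
    b_lo <- 0.3 * params$l_o_m
    b_hi <- min(1.8 * params$l_o_m, hi)
    r_lo <- phi(b_lo)
    r_hi <- phi(b_hi)
    if (sign(r_lo) == sign(r_hi)) {
      # widen once to the full physical window before giving up
      b_lo <- lo; b_hi <- hi
      r_lo <- phi(b_lo); r_hi <- phi(b_hi)
    }
    if (sign(r_lo) != sign(r_hi)) {
      root <- stats::uniroot(phi, c(b_lo, b_hi), f.lower = r_lo,
                             f.upper = r_hi, tol = .Machine$double.eps^0.75)
      l_m <- root$root
    }
    if (abs(phi(l_m)) >= max(f_tol, 1e-8 * params$f_o_m))
      stop(sprintf("fiber equilibrium failed for muscle '%s' (l_mtu = %.4f m, a_prev = %.3f)",
                   params$name, l_mtu, a_prev))
  }
  alpha <- pennation_angle(params, l_m, curves$pennation_cap)
  new_fiber_state(l_m, l_mtu - l_m * cos(alpha), alpha, phi(l_m))
}

#' Musculotendon force as an affine function of activation
#'
#' With the fiber length frozen at its equilibrium value, MTU force is affine
#' in the activation design variable:
#' \eqn{F = c_0 + c_1 a} with \eqn{c_0 = F_o^m f^{PE} \cos\alpha} and
#' \eqn{c_1 = F_o^m f^l \cos\alpha}.
#'
#' @param params A \code{muscle_params}.
#' @param curves A \code{curve_set}.
#' @param a Activation in [0, 1].
#' @param fiber A \code{fiber_state} solved at the current timestep.
#' @return List with \code{force} (N), \code{c0} (N), \code{c1} (N).
#' @export
mtu_force <- function(params, curves, a, fiber) {
  stopifnot(inherits(fiber, "fiber_state"))
  if (!is.finite(a) || a < 0 || a > 1) stop("a must lie in [0, 1]")
  co <- mtu_force_coeffs(params, curves, fiber)
  list(force = co$c0 + co$c1 * a, c0 = co$c0, c1 = co$c1)
}

# Affine coefficients only (hot path for the per-frame QP assembly).
mtu_force_coeffs <- function(params, curves, fiber) {
  lm_n <- fiber$l_m / params$l_o_m
  ca <- cos(fiber$alpha)
  list(c0 = params$f_o_m * curves$passive_fl(lm_n) * ca,
       c1 = params$f_o_m * curves$active_fl(lm_n) * ca)
}
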