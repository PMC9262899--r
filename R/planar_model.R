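#' Sagittal-plane lower-limb model
#'
#' A reduced musculoskeletal model over three sagittal degrees of freedom
#' (hip flexion, knee flexion, ankle plantarflexion — all positive in the
#' named direction, for angles and moments alike). Each muscle carries
#' Hill-type parameters, per-DOF moment-arm polynomials (order <= 2 in the
#' DOF's own angle), a reference MTU length, and a constant axial projection
#' coefficient mapping its force onto compression along the tibia's
#' longitudinal axis at the knee.
#'
#' MTU length follows from the moment arms by the virtual-work relation
#' \eqn{r_{i,j}(q) = -\partial l^{MTU}_i / \partial q_j}: the length is the
#' reference length minus the path integral of each moment arm from the
#' reference posture.
#'
#' @param muscles Named list; each element a list with fields \code{params}
#'   (a \code{muscle_params}), \code{arms} (named list of polynomial
#'   coefficient vectors \code{c(c0, c1, c2)} per actuated DOF, metres),
#'   \code{knee_axial} (dimensionless, in [0, 1]) and optional
#'   \code{l_mtu_ref} (defaults to \code{l_s_t + l_o_m cos(alpha_o)}).
#' @param groups Named list of character vectors partitioning the
#'   knee-crossing muscles into functional groups for contact-force
#'   decomposition.
#' @param bodyweight Subject bodyweight, N.
#' @param curves A \code{curve_set} shared by all muscles.
#' @param q_ref Reference posture (rad) at which MTU lengths equal
#'   \code{l_mtu_ref}; default all zero (upright standing).
#' @return An object of class \code{planar_model}.
#' @export
planar_model <- function(muscles, groups, bodyweight,
                         curves = default_curves(),
                         q_ref = c(hip_flexion = 0, knee_flexion = 0,
                                   ankle_plantarflexion = 0)) {
  dofs <- c("hip_flexion", "knee_flexion", "ankle_plantarflexion")
  stopifnot(is.list(muscles), length(muscles) > 0, !is.null(names(muscles)),
            is.numeric(bodyweight), bodyweight > 0,
            inherits(curves, "curve_set"))
  for (nm in names(muscles)) {
    m <- muscles[[nm]]
    if (!inherits(m$params, "muscle_params"))
      stop("muscle '", nm, "' lacks muscle_params")
    if (length(m$arms) == 0)
      stop("muscle '", nm, "' actuates no degree of freedom")
    if (!all(names(m$arms) %in% dofs))
      stop("muscle '", nm, "' references unknown DOFs")
    if (is.null(m$knee_axial)) muscles[[nm]]$knee_axial <- 0
    ka <- muscles[[nm]]$knee_axial
    if (ka < 0 || ka > 1) stop("knee_axial must lie in [0, 1]")
    crosses_knee <- "knee_flexion" %in% names(m$arms) &&
      any(m$arms[["knee_flexion"]] != 0)
    if (crosses_knee != (ka > 0))
      stop("muscle '", nm,
           "': knee_axial must be nonzero iff the knee moment arm is nonzero")
    if (is.null(m$l_mtu_ref))
      muscles[[nm]]$l_mtu_ref <-
        m$params$l_s_t + m$params$l_o_m * cos(m$params$alpha_o)
  }
  grouped <- unlist(groups, use.names = FALSE)
  knee_crossing <- names(muscles)[vapply(muscles, function(m)
    isTRUE(m$knee_axial > 0), logical(1))]
  missing_grp <- setdiff(knee_crossing, grouped)
  if (length(missing_grp) > 0)
    stop("knee-crossing muscles not assigned to any group: ",
         paste(missing_grp, collapse = ", "))
  structure(
    list(dofs = dofs, muscles = muscles, groups = groups,
         bodyweight = bodyweight, curves = curves, q_ref = q_ref[dofs]),
    class = "planar_model"
  )
}

#' @export
print.planar_model <- function(x, ...) {
  cat("planar_model:", length(x$muscles), "muscles over",
      length(x$dofs), "DOFs;",
      "bodyweight", round(x$bodyweight, 1), "N\n")
  cat("groups:", paste(sprintf("%s(%d)", names(x$groups),
                               lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

poly_eval <- function(coef, q) {
  s <- 0
  for (k in seq_along(coef)) s <- s + coef[k] * q^(k - 1)
  s
}

poly_int <- function(coef, from, to) {
  s <- 0
  for (k in seq_along(coef)) s <- s + coef[k] * (to^k - from^k) / k
  s
}

#' Moment arm of one muscle about one DOF
#'
#' @param model A \code{planar_model}.
#' @param muscle Muscle name.
#' @param dof DOF name.
#' @param q Named posture vector, rad.
#' @return Moment arm, m (0 if the muscle does not cross the DOF).
#' @export
moment_arm <- function(model, muscle, dof, q) {
  m <- model$muscles[[muscle]]
  if (is.null(m)) stop("unknown muscle: ", muscle)
  coef <- m$arms[[dof]]
  if (is.null(coef)) return(0)
  poly_eval(coef, q[[dof]])
}

#' Musculotendon length at a posture
#'
#' @param model A \code{planar_model}.
#' @param muscle Muscle name.
#' @param q Named posture vector, rad.
#' @return MTU length, m.
#' @export
mtu_length <- function(model, muscle, q) {
  m <- model$muscles[[muscle]]
  if (is.null(m)) stop("unknown muscle: ", muscle)
  l <- m$l_mtu_ref
  for (dof in names(m$arms))
    l <- l - poly_int(m$arms[[dof]], model$q_ref[[dof]], q[[dof]])
  if (l <= 0) stop("infeasible posture: non-positive MTU length for ", muscle)
  if (l <= m$params$l_s_t)
    stop(sprintf("infeasible posture for '%s': MTU length %.4f m below tendon slack length %.4f m",
                 muscle, l, m$params$l_s_t))
  l
}

#' Moment-arm matrix at a posture
#'
#' @param model A \code{planar_model}.
#' @param q Named posture vector, rad.
#' @return nDOF x nMuscles matrix of moment arms, m, with dimnames.
#' @export
moment_arm_matrix <- function(model, q) {
  R <- matrix(0, nrow = length(model$dofs), ncol = length(model$muscles),
              dimnames = list(model$dofs, names(model$muscles)))
  for (mu in names(model$muscles))
    for (dof in names(model$muscles[[mu]]$arms))
      R[dof, mu] <- poly_eval(model$muscles[[mu]]$arms[[dof]], q[[dof]])
  R
}

#' Joint posture at 75\% of the stance phase
#'
#' The documented late-stance configuration of the packaged gait kinematics
#' (hip slightly extended, knee near full extension, ankle dorsiflexed just
#' before push-off). This is the posture at which the fixture's
#' hamstrings-to-gastrocnemius knee flexion moment-arm ratio is calibrated.
#'
#' @return Named numeric posture vector, rad.
#' @export
posture_75_stance <- function() {
  gait_kinematics(0.75 * 0.6)[1, ]
}

#' Optimal-force-weighted hamstrings:gastrocnemius knee moment-arm ratio
#'
#' Averages the knee flexion moment arm within the hamstrings (biceps femoris
#' long and short heads, semitendinosus, semimembranosus) and the
#' gastrocnemius (medial and lateral heads), weighting each muscle by its
#' maximum isometric force, and returns the ratio of the two averages.
#'
#' @param model A \code{planar_model}.
#' @param q Posture at which to evaluate (default: 75\% stance).
#' @return Dimensionless ratio.
#' @export
hams_gastroc_arm_ratio <- function(model, q = posture_75_stance()) {
  wavg <- function(muscles) {
    w <- vapply(muscles, function(mu) model$muscles[[mu]]$params$f_o_m,
                numeric(1))
    r <- vapply(muscles, function(mu)
      moment_arm(model, mu, "knee_flexion", q), numeric(1))
    sum(w * r) / sum(w)
  }
  wavg(model$groups$hamstrings) / wavg(model$groups$gastrocnemius)
}

#' Packaged default lower-limb fixture
#'
#' A 14-muscle sagittal model: iliopsoas, gluteals (lumped), rectus femoris,
#' vastus medialis, vastus lateralis (absorbing vastus intermedius), biceps
#' femoris long and short heads, semitendinosus, semimembranosus, medial and
#' lateral gastrocnemius, soleus, tibialis anterior, and tensor fasciae
#' latae. Hill parameters and moment-arm polynomials are literature-plausible
#' values for a generic adult lower limb (not fitted to any subject). Two
#' construction constraints are imposed exactly: the functional muscle
#' groupings used for contact-force decomposition, and the optimal-force-
#' weighted hamstrings-to-gastrocnemius knee flexion moment-arm ratio at the
#' 75\%-stance posture, set to \code{hams_gastroc_ratio} by a uniform
#' rescaling of the hamstring knee moment arms.
#'
#' Sign convention: hip flexion, knee flexion and ankle plantarflexion
#' positive. Knee extensors (quadriceps, tensor fasciae latae) therefore
#' carry negative knee moment arms.
#'
#' @param bodyweight Bodyweight, N (default 736, a 75 kg adult).
#' @param hams_gastroc_ratio Calibrated knee moment-arm ratio (default 1.7).
#' @param curves Characteristic curves (default \code{default_curves()}).
#' @return A \code{planar_model}.
#' @export
default_model <- function(bodyweight = 736, hams_gastroc_ratio = 1.7,
                          curves = default_curves()) {
  mk <- function(name, f_o, l_o, l_s, al, arms, ka = 0)
    list(params = muscle_params(name, f_o, l_o, l_s, al),
         arms = arms, knee_axial = ka)
  muscles <- list(
    iliopsoas = mk("iliopsoas", 2000, 0.110, 0.100, 0.25,
                   list(hip_flexion = c(0.035, -0.008))),
    glut_max  = mk("glut_max", 2700, 0.150, 0.120, 0.38,
                   list(hip_flexion = c(-0.062))),
    rect_fem  = mk("rect_fem", 1200, 0.076, 0.340, 0.24,
                   list(hip_flexion = c(0.040),
                        knee_flexion = c(-0.042, -0.012, 0.020)), ka = 0.70),
    vas_med   = mk("vas_med", 1500, 0.100, 0.110, 0.42,
                   list(knee_flexion = c(-0.044, -0.012, 0.020)), ka = 0.70),
    vas_lat   = mk("vas_lat", 2800, 0.100, 0.130, 0.32,
                   list(knee_flexion = c(-0.044, -0.012, 0.020)), ka = 0.70),
    bf_long   = mk("bf_long", 1000, 0.110, 0.320, 0.20,
                   list(hip_flexion = c(-0.055),
                        knee_flexion = c(0.028, 0.010, -0.008)), ka = 0.75),
    bf_short  = mk("bf_short", 550, 0.110, 0.100, 0.20,
                   list(knee_flexion = c(0.028, 0.010, -0.008)), ka = 0.75),
    semiten   = mk("semiten", 400, 0.190, 0.240, 0.22,
                   list(hip_flexion = c(-0.050),
                        knee_flexion = c(0.040, 0.008, -0.006)), ka = 0.75),
    semimem   = mk("semimem", 1500, 0.080, 0.340, 0.26,
                   list(hip_flexion = c(-0.052),
                        knee_flexion = c(0.034, 0.008, -0.006)), ka = 0.75),
    gas_med   = mk("gas_med", 1600, 0.059, 0.390, 0.31,
                   list(knee_flexion = c(0.018, 0.006),
                        ankle_plantarflexion = c(0.048, 0.008)), ka = 0.90),
    gas_lat   = mk("gas_lat", 700, 0.063, 0.380, 0.21,
                   list(knee_flexion = c(0.016, 0.006),
                        ankle_plantarflexion = c(0.048, 0.008)), ka = 0.90),
    soleus    = mk("soleus", 3600, 0.044, 0.270, 0.49,
                   list(ankle_plantarflexion = c(0.048, 0.008))),
    tib_ant   = mk("tib_ant", 1000, 0.068, 0.240, 0.17,
                   list(ankle_plantarflexion = c(-0.037))),
    tfl       = mk("tfl", 400, 0.095, 0.430, 0.05,
                   list(hip_flexion = c(0.030),
                        knee_flexion = c(-0.004)), ka = 0.20)
  )
  groups <- list(
    quadriceps = c("vas_med", "vas_lat", "rect_fem"),
    hamstrings = c("bf_long", "bf_short", "semiten", "semimem"),
    gastrocnemius = c("gas_med", "gas_lat"),
    tensor_fascia_latae = "tfl"
  )
  model <- planar_model(muscles, groups, bodyweight, curves)
  # construction constraint: weighted knee moment-arm ratio at 75% stance
  scale <- hams_gastroc_ratio / hams_gastroc_arm_ratio(model)
  for (mu in groups$hamstrings)
    model$muscles[[mu]]$arms$knee_flexion <-
      model$muscles[[mu]]$arms$knee_flexion * scale
  model
}
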