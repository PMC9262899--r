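#' Half-stance peak extraction
#'
#' First peak: maximum over the first 50\% of stance samples; second peak:
#' maximum over the final 50\%. Knee contact force is compressive-positive
#' throughout stance, so both half-stance extrema are maxima.
#'
#' @param series Numeric series on the trial time grid.
#' @param stance_mask Logical stance mask of the same length.
#' @return List with \code{p1}, \code{p2} and their time indices
#'   \code{i1}, \code{i2}.
#' @export
extract_peaks <- function(series, stance_mask) {
  stopifnot(length(series) == length(stance_mask))
  idx <- which(stance_mask)
  if (length(idx) == 0) stop("stance mask selects no samples")
  half <- ceiling(length(idx) / 2)
  first <- idx[seq_len(half)]
  last <- idx[(half + 1):length(idx)]
  if (all(is.na(series[idx]))) stop("series is all NA over stance")
  i1 <- first[which.max(series[first])]
  i2 <- last[which.max(series[last])]
  list(p1 = series[i1], p2 = series[i2], i1 = i1, i2 = i2)
}

#' Knee contact force along the tibia axis
#'
#' Total compressive knee contact force as the intersegmental axial force
#' plus every knee-crossing muscle's force projected onto the tibia's
#' longitudinal axis through its constant axial coefficient, decomposed into
#' the model's functional muscle groups. Superposition is exact: at every
#' frame the group contributions plus the intersegmental force reconstruct
#' the total.
#'
#' @param model A \code{planar_model}.
#' @param solution An \code{activation_solution} for \code{trial}.
#' @param trial The \code{gait_trial} that was solved (supplies the
#'   intersegmental axial force and bodyweight).
#' @return An object of class \code{kcf_result}: time grid, stance mask,
#'   \code{total_n}/\code{total_bw}, \code{interseg_n}/\code{interseg_bw},
#'   \code{group_contribs_n}/\code{_bw} (matrix, one column per group), and
#'   stance peaks \code{p1}, \code{p2} in BW.
#' @export
compute_kcf <- function(model, solution, trial) {
  stopifnot(inherits(model, "planar_model"),
            inherits(solution, "activation_solution"),
            inherits(trial, "gait_trial"))
  if (length(trial$t) != length(solution$t) ||
      any(abs(trial$t - solution$t) > 1e-12))
    stop("solution and trial do not share a time grid")
  if (is.null(trial$interseg_axial))
    stop("trial lacks the intersegmental axial force series")
  groups <- decompose_kcf(model, solution)
  total <- trial$interseg_axial + rowSums(groups)
  bw <- trial$bodyweight
  peaks <- extract_peaks(total / bw, trial$stance_mask)
  structure(
    list(t = trial$t, stance_mask = trial$stance_mask,
         total_n = total, total_bw = total / bw,
         interseg_n = trial$interseg_axial,
         interseg_bw = trial$interseg_axial / bw,
         group_contribs_n = groups, group_contribs_bw = groups / bw,
         bodyweight = bw, p1 = peaks$p1, p2 = peaks$p2,
         p1_index = peaks$i1, p2_index = peaks$i2),
    class = "kcf_result")
}

#' Per-group muscle contributions to knee contact force
#'
#' @param model A \code{planar_model}.
#' @param solution An \code{activation_solution}.
#' @return Matrix (timesteps x groups) of axial force contributions, N.
#' @export
decompose_kcf <- function(model, solution) {
  ka <- vapply(model$muscles, `[[`, numeric(1), "knee_axial")
  crossing <- names(ka)[ka > 0]
  grouped <- unlist(model$groups, use.names = FALSE)
  stray <- setdiff(crossing, grouped)
  if (length(stray) > 0)
    stop("knee-crossing muscles in no group: ", paste(stray, collapse = ", "))
  out <- sapply(model$groups, function(mus) {
    mus <- intersect(mus, colnames(solution$forces))
    as.numeric(solution$forces[, mus, drop = FALSE] %*% ka[mus])
  })
  rownames(out) <- NULL
  out
}
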