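stance_mean <- function(x, mask) mean(x[mask])

group_force_means <- function(model, solution) {
  sapply(model$groups, function(mus) {
    mus <- intersect(mus, colnames(solution$forces))
    stance_mean(rowSums(solution$forces[, mus, drop = FALSE]),
                solution$stance_mask)
  })
}

#' Design simulation: natural vs gastrocnemius-avoidance coordination
#'
#' Solves the same trial kinetics with the natural objective and the
#' gastrocnemius-avoidance objective, computes knee contact force for both,
#' and summarizes the coordination shift: stance-averaged force changes for
#' the soleus, gastrocnemius, hamstrings and iliopsoas, and contact-force
#' peak changes.
#'
#' @param model A \code{planar_model}.
#' @param trial A \code{gait_trial}.
#' @param gastroc_weight Avoidance penalty weight (default 100).
#' @return An object of class \code{comparison_report}: per-condition
#'   solutions and KCF, and a one-row \code{summary} data frame.
#' @export
run_design_simulation <- function(model, trial, gastroc_weight = 100) {
  sol_nat <- solve_trial(model, trial, objective_spec("natural"))
  sol_avd <- solve_trial(model, trial,
                         objective_spec("gastroc_avoidance",
                                        gastroc_weight = gastroc_weight))
  kcf_nat <- compute_kcf(model, sol_nat, trial)
  kcf_avd <- compute_kcf(model, sol_avd, trial)
  sm <- function(sol, mus)
    stance_mean(rowSums(sol$forces[, mus, drop = FALSE]), sol$stance_mask)
  gm <- model$groups$gastrocnemius
  hs <- model$groups$hamstrings
  summary <- data.frame(
    gastroc_force_natural = sm(sol_nat, gm),
    gastroc_force_avoidance = sm(sol_avd, gm),
    soleus_force_natural = sm(sol_nat, "soleus"),
    soleus_force_avoidance = sm(sol_avd, "soleus"),
    hamstrings_force_natural = sm(sol_nat, hs),
    hamstrings_force_avoidance = sm(sol_avd, hs),
    iliopsoas_force_natural = sm(sol_nat, "iliopsoas"),
    iliopsoas_force_avoidance = sm(sol_avd, "iliopsoas"),
    kcf_p1_natural = kcf_nat$p1, kcf_p2_natural = kcf_nat$p2,
    kcf_p1_avoidance = kcf_avd$p1, kcf_p2_avoidance = kcf_avd$p2,
    kcf_p2_delta = kcf_avd$p2 - kcf_nat$p2,
    max_moment_residual = max(abs(sol_nat$moment_residuals),
                              abs(sol_avd$moment_residuals))
  )
  structure(list(natural = list(solution = sol_nat, kcf = kcf_nat),
                 avoidance = list(solution = sol_avd, kcf = kcf_avd),
                 summary = summary),
            class = "comparison_report")
}

emg_condition_solve <- function(model, trial, emg, delay, tolerance, floor) {
  ratio <- ratio_spec_from_emg(trial, emg, delay = delay,
                               tolerance = tolerance, floor = floor)
  sol <- solve_trial(model, trial, objective_spec("natural"), ratio = ratio)
  kcf <- compute_kcf(model, sol, trial)
  enforced <- which(rowSums(ratio$mask) > 0)
  list(solution = sol, kcf = kcf, ratio = ratio,
       max_ratio_residual = if (length(enforced))
         max(sol$ratio_residuals[enforced], na.rm = TRUE) else NA_real_,
       sim_activation_ratio = activation_ratio(
         sol$activations[, "gas_med"], sol$activations[, "soleus"],
         sol$stance_mask))
}

#' EMG-informed evaluation of a coordination change
#'
#' For a baseline and a retention condition (trial plus raw EMG each), runs
#' the EMG-informed static optimization — natural objective with the
#' simulated gastrocnemius-to-soleus activation ratio constrained to the
#' measured (delayed, normalized) EMG ratio within the tolerance — and
#' compares knee contact force between conditions.
#'
#' @param model A \code{planar_model}.
#' @param baseline,retention Lists with \code{trial} and \code{emg} (as
#'   produced by \code{\link{make_cohort}} subjects).
#' @param delay Electromechanical delay, s (default 0.040).
#' @param tolerance Ratio tolerance (default 0.02).
#' @param floor Enforcement floor, fraction of MVC (default 0.01).
#' @return An object of class \code{comparison_report} with per-condition
#'   results and a one-row \code{summary} data frame.
#' @export
run_emg_informed <- function(model, baseline, retention, delay = 0.040,
                             tolerance = 0.02, floor = 0.01) {
  base <- emg_condition_solve(model, baseline$trial, baseline$emg,
                              delay, tolerance, floor)
  ret <- emg_condition_solve(model, retention$trial, retention$emg,
                             delay, tolerance, floor)
  gm_group <- function(cond)
    extract_peaks(cond$kcf$group_contribs_bw[, "gastrocnemius"],
                  cond$kcf$stance_mask)$p2
  summary <- data.frame(
    ratio_baseline = base$sim_activation_ratio,
    ratio_retention = ret$sim_activation_ratio,
    ratio_change = (ret$sim_activation_ratio - base$sim_activation_ratio) /
      base$sim_activation_ratio,
    gastroc_act_baseline = stance_mean(base$solution$activations[, "gas_med"],
                                       base$solution$stance_mask),
    gastroc_act_retention = stance_mean(ret$solution$activations[, "gas_med"],
                                        ret$solution$stance_mask),
    ankle_moment_baseline = stance_mean(
      baseline$trial$M_ID[, "ankle_plantarflexion"],
      baseline$trial$stance_mask),
    ankle_moment_retention = stance_mean(
      retention$trial$M_ID[, "ankle_plantarflexion"],
      retention$trial$stance_mask),
    kcf_p1_baseline = base$kcf$p1, kcf_p2_baseline = base$kcf$p2,
    kcf_p1_retention = ret$kcf$p1, kcf_p2_retention = ret$kcf$p2,
    kcf_p2_delta = ret$kcf$p2 - base$kcf$p2,
    gastroc_p2_contrib_baseline = gm_group(base),
    gastroc_p2_contrib_retention = gm_group(ret),
    max_ratio_residual = max(base$max_ratio_residual,
                             ret$max_ratio_residual)
  )
  structure(list(baseline = base, retention = ret, summary = summary),
            class = "comparison_report")
}

#' Descriptive cohort summary
#'
#' Column-wise mean and standard deviation of the per-subject summary rows.
#' Only descriptive statistics are reported (the cohort is synthetic, so
#' inferential tests would be meaningless).
#'
#' @param reports List of \code{comparison_report}s (one per subject).
#' @return Data frame with rows \code{mean} and \code{sd}.
#' @export
summarize_cohort <- function(reports) {
  stopifnot(length(reports) >= 1)
  rows <- do.call(rbind, lapply(reports, `[[`, "summary"))
  sds <- vapply(rows, function(col)
    if (length(col) > 1) stats::sd(col) else 0, numeric(1))
  out <- rbind(mean = colMeans(rows), sd = sds)
  as.data.frame(out)
}
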