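#!/usr/bin/env Rscript
# Intervention-design simulation: solve identical normative walking kinetics
# with the natural and the gastrocnemius-avoidance objective and compare the
# compensation pattern and knee contact force. Writes per-frame waveforms and
# a summary table under results/design_simulation/.

suppressPackageStartupMessages(library(kneeload))

seed <- 20260926L
out_dir <- file.path("results", "design_simulation")
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

model <- default_model()
gen <- generate_trial(model, trial_config("normative"), seed = seed)
report <- run_design_simulation(model, gen$trial)

for (cond in c("natural", "avoidance")) {
  kcf <- report[[cond]]$kcf
  df <- data.frame(time = kcf$t,
                   stance_pct = ifelse(kcf$stance_mask,
                                       100 * kcf$t / max(kcf$t[kcf$stance_mask]),
                                       NA),
                   total_BW = kcf$total_bw,
                   intersegmental_BW = kcf$interseg_bw,
                   kcf$group_contribs_bw)
  write.csv(df, file.path(out_dir, paste0("kcf_", cond, ".csv")),
            row.names = FALSE)
  write.csv(data.frame(time = kcf$t, report[[cond]]$solution$activations),
            file.path(out_dir, paste0("activations_", cond, ".csv")),
            row.names = FALSE)
}
write.csv(report$summary, file.path(out_dir, "summary.csv"),
          row.names = FALSE)

s <- report$summary
cat("Design simulation on the normative synthetic trial (seed", seed, "):\n")
cat(sprintf("  stance-mean gastrocnemius force: %.0f N -> %.0f N (%.0f%%)\n",
            s$gastroc_force_natural, s$gastroc_force_avoidance,
            100 * (s$gastroc_force_avoidance / s$gastroc_force_natural - 1)))
cat(sprintf("  stance-mean soleus force:        %.0f N -> %.0f N (+%.0f%%)\n",
            s$soleus_force_natural, s$soleus_force_avoidance,
            100 * (s$soleus_force_avoidance / s$soleus_force_natural - 1)))
cat(sprintf("  stance-mean hamstrings force:    %.0f N -> %.0f N\n",
            s$hamstrings_force_natural, s$hamstrings_force_avoidance))
cat(sprintf("  stance-mean iliopsoas force:     %.0f N -> %.0f N\n",
            s$iliopsoas_force_natural, s$iliopsoas_force_avoidance))
cat(sprintf("  KCF P1: %.2f -> %.2f BW;  KCF P2: %.2f -> %.2f BW (delta %.2f BW)\n",
            s$kcf_p1_natural, s$kcf_p1_avoidance,
            s$kcf_p2_natural, s$kcf_p2_avoidance, s$kcf_p2_delta))
cat(sprintf("  worst moment-matching residual: %.1e N m\n",
            s$max_moment_residual))
cat("Avoiding the gastrocnemius shifts plantarflexion to the soleus and knee\n")
cat("flexion to the hamstrings (larger knee moment arm), lowering late-stance KCF.\n")
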