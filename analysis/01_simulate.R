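#!/usr/bin/env Rscript
# Simulate the study cohorts: a child group (ages 6-12, age effects on
# drift, boundary and non-decision time) and an adult group, both doing
# 3-condition motion-coherence discrimination, plus fast-guess contaminants
# in the child group. Writes tidy trial tables and ground-truth parameter
# tables under results/data/.
#
# Scale note: 24 children / 10 adults at 72 trials per condition keep the
# full workflow runnable in minutes; all steps scale to larger cohorts.

library(hbddm)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260924L

child_cfg <- sim_config(n_participants = 24, ages = c(6, 12),
                        n_trials_per_condition = 72, group = "children",
                        group_hyperparams = child_group_truth(),
                        contaminant_prop = 0.08, seed = seed)
adult_cfg <- sim_config(n_participants = 10, ages = c(19, 35),
                        n_trials_per_condition = 72, group = "adults",
                        group_hyperparams = adult_group_truth(),
                        covariate_effects = c(), seed = seed + 1L)

child <- gen_behavior(child_cfg)
child$trials <- gen_contaminants(child$trials, child_cfg$contaminant_prop,
                                 seed = seed + 2L)
adult <- gen_behavior(adult_cfg)

write_behavior(child$trials, file.path(out, "behavior_children.csv"))
write_behavior(adult$trials, file.path(out, "behavior_adults.csv"))
write.csv(child$truth, file.path(out, "truth_children.csv"),
          row.names = FALSE)
write.csv(adult$truth, file.path(out, "truth_adults.csv"),
          row.names = FALSE)
# hidden contaminant flags, kept separately for later screening checks
write.csv(child$trials[c("participant_id", "trial_index", ".contaminant")],
          file.path(out, "contaminant_flags_children.csv"),
          row.names = FALSE)

acc <- function(tr) tapply(tr$correct, tr$coherence_pct, mean)
cat("Child accuracy by coherence:",
    sprintf("%.3f", acc(child$trials)), "\n")
cat("Adult accuracy by coherence:",
    sprintf("%.3f", acc(adult$trials)), "\n")
cat("Child median RT:", sprintf("%.3f s", median(child$trials$rt_s)),
    "| adult:", sprintf("%.3f s", median(adult$trials$rt_s)), "\n")
cat("Wrote", out, "\n")
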