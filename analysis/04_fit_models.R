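#!/usr/bin/env Rscript
# Hierarchical Bayesian diffusion fits. For the children: the no-covariate
# baseline and the age / EEG covariate-regression variants (models 1-12
# where covariates exist). For the adults: the baseline and the EEG models
# (no age effects expected in adults). Posterior summaries, convergence
# diagnostics and deviance traces are written under results/fits/.
#
# Sampler: the desk-scale profile (3 chains x 5,000 sweeps, 1,000 burn-in,
# thin 1 = 4,000 retained per chain). Production-length runs (3 x 54,000,
# thin 5) are available via sampler_settings().

library(hbddm)

ind_s <- "results/screening"
ind_e <- "results/eeg"
out <- "results/fits"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20261001L

fam <- model_family()
model_sets <- list(
  children = c("model1", "model2", "model3", "model4", "model5",
               "model6", "model7", "model8"),
  adults = c("model1", "model6", "model7", "model8"))

for (grp in names(model_sets)) {
  screened <- read_behavior(file.path(ind_s, sprintf("screened_%s.csv",
                                                     grp)))
  covs <- read.csv(file.path(ind_e, sprintf("covariates_%s.csv", grp)))
  fits <- list()
  for (lbl in model_sets[[grp]]) {
    spec <- fam[[lbl]]
    needed <- unique(unlist(spec$covariate_map))
    if (length(needed) && !all(needed %in% names(covs) &
                               !vapply(covs[needed], anyNA, TRUE))) {
      cat(sprintf("%s/%s skipped (covariate unavailable)\n", grp, lbl))
      next
    }
    fit <- sample_posterior(build_model(spec, screened, covs),
                            reduced_settings(seed = seed))
    fits[[lbl]] <- fit
    ps <- posterior_summary(fit)
    write.csv(ps, file.path(out, sprintf("posterior_%s_%s.csv", grp, lbl)),
              row.names = FALSE)
    cat(sprintf("%s/%s: %.0f s, max R-hat %.3f\n", grp, lbl,
                fit$runtime_s, max(ps$rhat)))
  }
  saveRDS(fits, file.path(out, sprintf("fits_%s.rds", grp)))
}
cat("Wrote", out, "\n")
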