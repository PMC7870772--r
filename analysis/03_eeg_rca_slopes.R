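#!/usr/bin/env Rscript
# EEG stage: synthesise response-locked epochs for the screened trials
# (ramping component over centro-parietal-like sites tied to each
# participant's true drift, plus an occipital-like biphasic component),
# run the cleaning pipeline, fit RCA per group, derive the group regression
# windows and extract per-participant ramp slopes as model covariates.
# Writes covariate tables under results/eeg/.
#
# Scale note: 32 electrodes and 24 epochs per participant; the montage and
# epoch counts are configurable in eeg_sim_spec().

library(hbddm)

ind <- "results/screening"
out <- "results/eeg"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20260930L

for (grp in c("children", "adults")) {
  screened <- read_behavior(file.path(ind, sprintf("screened_%s.csv", grp)))
  truth <- read.csv(file.path("results/data",
                              sprintf("truth_%s.csv", grp)))
  ids <- unique(screened$participant_id)
  rows <- do.call(rbind, lapply(split(screened, screened$participant_id),
                                head, 24))
  spec <- eeg_sim_spec(n_electrodes = 32)
  eeg <- gen_eeg(rows, spec, seed = seed, behavior_truth = truth)

  ep <- dc_median_correct(eeg$epochs)
  bad <- flag_outlier_electrodes(ep)
  if (any(bad)) ep <- interpolate_electrodes(ep, bad)
  ep <- censor_transients(ep)
  ep <- rereference_and_baseline(ep)
  dropped <- drop_bad_trials(ep, max_bad_electrodes = round(0.15 * 32))
  ep <- dropped$epochs
  cat(sprintf("%s: %d epochs cleaned, %d dropped, %d electrodes interpolated\n",
              grp, dim(ep$data)[1], sum(!dropped$report$kept), sum(bad)))

  rca <- fit_rca(ep, n_components = 2)
  cat(sprintf("  component reliability fractions: %s\n",
              paste0(sprintf("%.0f%%",
                             100 * rca$explained_reliability_fraction),
                     collapse = ", ")))
  proj <- project_components(ep, rca$weights)
  ga <- apply(proj, c(2, 3), mean, na.rm = TRUE)
  w1 <- window_component1(ep$time_ms, ga[1, ], group = grp)
  w2 <- window_component2(ep$time_ms, ga[2, ], group = grp)
  cat(sprintf("  regression windows: c1 [%.0f, %.0f] ms, c2 [%.0f, %.0f] ms\n",
              w1$start_ms, w1$end_ms, w2$start_ms, w2$end_ms))

  # epochs are in `rows` order, minus dropped trials
  pid_per_epoch <- rows$participant_id[dropped$report$kept]
  slope1 <- slope2 <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    sel <- which(pid_per_epoch == ids[i])
    avg <- apply(proj[sel, , , drop = FALSE], c(2, 3), mean, na.rm = TRUE)
    slope1[i] <- participant_slope(ep$time_ms, avg[1, ], w1)
    slope2[i] <- participant_slope(ep$time_ms, avg[2, ], w2)
  }
  parts <- unique(screened[c("participant_id", "age_years")])
  parts <- parts[match(ids, parts$participant_id), ]
  covs <- covariate_table(parts, slope_c1 = slope1, slope_c2 = slope2)
  tt <- eeg$truth[match(ids, eeg$truth$participant_id), ]
  cat(sprintf("  slope recovery r (c1): %.2f; slope-age r: %.2f\n",
              cor(slope1, tt$slope_c1, use = "complete.obs"),
              if (grp == "children")
                cor(covs$age_years, slope1, use = "complete.obs") else NA))
  write.csv(covs, file.path(out, sprintf("covariates_%s.csv", grp)),
            row.names = FALSE)
  write.csv(data.frame(component = c(1, 2),
                       start_ms = c(w1$start_ms, w2$start_ms),
                       end_ms = c(w1$end_ms, w2$end_ms), group = grp),
            file.path(out, sprintf("windows_%s.csv", grp)),
            row.names = FALSE)
}
cat("Wrote", out, "\n")
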