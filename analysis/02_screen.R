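#!/usr/bin/env Rscript
# Data screening: structural exclusions (catch trials, timeouts, excluded
# hardest condition), EWMA fast-guess filtering per participant, and
# participant-level retention rules. Reports how many injected contaminants
# the EWMA filter caught. Writes screened trial tables and reports under
# results/screening/.

library(hbddm)

ind <- "results/data"
out <- "results/screening"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (grp in c("children", "adults")) {
  trials <- read_behavior(file.path(ind, sprintf("behavior_%s.csv", grp)))
  excl <- apply_basic_exclusions(trials)
  ew <- apply_ewma(excl$dataset)
  sc <- screen_participants(ew$dataset, ew$report)
  cat(sprintf(
    "%s: %d -> %d rows after basic exclusions; EWMA median retention %.1f%%; %d/%d participants kept\n",
    grp, nrow(trials), nrow(excl$dataset),
    100 * median(ew$report$retained_fraction),
    sum(sc$report$decision == "keep"), nrow(sc$report)))
  write_behavior(sc$dataset, file.path(out, sprintf("screened_%s.csv", grp)))
  write.csv(excl$report, file.path(out, sprintf("exclusions_%s.csv", grp)),
            row.names = FALSE)
  write.csv(merge(ew$report,
                  sc$report[c("participant_id", "accuracy", "decision")]),
            file.path(out, sprintf("participants_%s.csv", grp)),
            row.names = FALSE)

  flags_path <- file.path(ind, sprintf("contaminant_flags_%s.csv", grp))
  if (file.exists(flags_path)) {
    flags <- read.csv(flags_path)
    flags <- flags[flags$.contaminant, ]
    if (nrow(flags) > 0) {
      key <- paste(excl$dataset$participant_id, excl$dataset$trial_index)
      bad_key <- paste(flags$participant_id, flags$trial_index)
      present <- key %in% bad_key
      caught <- present & !ew$keep
      cat(sprintf("  EWMA caught %.0f%% of the injected fast guesses\n",
                  100 * sum(caught) / sum(present)))
    }
  }
}
cat("Wrote", out, "\n")
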