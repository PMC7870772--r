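#' Default run configuration
#'
#' A complete, desk-scale configuration for [run_pipeline()]: a child-like
#' synthetic cohort, the screening defaults, a modest EEG montage and the
#' reduced sampler profile. Any entry can be overridden (or loaded from
#' YAML via [read_run_config()]).
#'
#' @return named list of settings.
#' @export
default_run_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    output_dir = "results/run",
    behavior_csv = NULL,            # analyze mode input
    epochs_rds = NULL,              # analyze mode input (optional)
    n_participants = 24,
    ages = c(6, 12),
    group = "children",
    n_trials_per_condition = 72,
    coherences = c(30, 50, 75),
    contaminant_prop = 0.05,
    n_electrodes = 32,
    eeg_trials_per_participant = 30,
    min_retained = 0.6,
    ewma = list(lambda = 0.1, c0 = 0.5, sigma0 = 0.5, L = 1.5),
    models = c("model1", "model4", "model6", "model7"),
    sampler = "reduced"     # "full", or a sampler_settings() object
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Sequences the full analysis: (simulate or load) behaviour -> structural
#' exclusions -> EWMA fast-guess screening -> participant retention ->
#' synthetic EEG -> RCA -> regression windows and participant slopes ->
#' hierarchical model fits -> convergence diagnostics -> DIC comparison.
#' All tables are written as CSV under `config$output_dir` together with a
#' run manifest and a Markdown report; every output is reproducible from
#' the manifest alone.
#'
#' @param config a run-config list (see [default_run_config()]).
#' @return (invisibly) a list with every intermediate object: `screened`
#'   trials, reports, `rca`, `covariates`, `fits`, `comparison`,
#'   `rhat_range`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$output_dir)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  # --- data ---
  if (identical(config$mode, "simulate")) {
    cfg <- sim_config(n_participants = config$n_participants,
                      ages = config$ages,
                      n_trials_per_condition = config$n_trials_per_condition,
                      coherences = config$coherences,
                      group = config$group, seed = config$seed)
    sim <- gen_behavior(cfg)
    trials <- sim$trials
    truth <- sim$truth
    if (config$contaminant_prop > 0)
      trials <- gen_contaminants(trials, config$contaminant_prop,
                                 seed = config$seed + 1L)
    write_behavior(trials, file.path(out, "behavior.csv"))
    write.csv(truth, file.path(out, "truth_participants.csv"),
              row.names = FALSE)
    say("simulated %d participants, %d trials (%.0f%% contaminants)",
        config$n_participants, nrow(trials),
        100 * config$contaminant_prop)
  } else {
    if (is.null(config$behavior_csv)) stop("analyze mode needs behavior_csv")
    trials <- read_behavior(config$behavior_csv)
    truth <- NULL
    say("loaded %d trials from %s", nrow(trials), config$behavior_csv)
  }

  # --- screening ---
  excl <- apply_basic_exclusions(trials)
  say("basic exclusions removed %d rows",
      nrow(trials) - nrow(excl$dataset))
  ew <- apply_ewma(excl$dataset,
                   ewma_config(config$ewma$lambda, config$ewma$c0,
                               config$ewma$sigma0, config$ewma$L))
  say("EWMA retained a median %.1f%% of trials per participant",
      100 * median(ew$report$retained_fraction))
  sc <- screen_participants(ew$dataset, ew$report,
                            min_retained = config$min_retained)
  say("%d participants retained, %d dropped",
      sum(sc$report$decision == "keep"),
      sum(sc$report$decision != "keep"))
  screened <- sc$dataset
  write.csv(excl$report, file.path(out, "exclusion_report.csv"),
            row.names = FALSE)
  write.csv(merge(ew$report, sc$report[c("participant_id", "accuracy",
                                         "decision")]),
            file.path(out, "participant_report.csv"), row.names = FALSE)

  # --- EEG: simulate epochs for a subset of retained trials, fit RCA ---
  covs <- NULL; rca <- NULL; windows <- NULL
  if (identical(config$mode, "simulate")) {
    keep_ids <- unique(screened$participant_id)
    eeg_rows <- do.call(rbind, lapply(keep_ids, function(id) {
      rows <- screened[screened$participant_id == id, ]
      head(rows, config$eeg_trials_per_participant)
    }))
    spec <- eeg_sim_spec(n_electrodes = config$n_electrodes)
    eeg <- gen_eeg(eeg_rows, spec, seed = config$seed + 2L,
                   behavior_truth = truth)
    epochs <- dc_median_correct(eeg$epochs)
    epochs <- rereference_and_baseline(epochs)
    rca <- fit_rca(epochs, n_components = 2)
    say("RCA explained reliability: %s",
        paste0(sprintf("%.0f%%",
                       100 * rca$explained_reliability_fraction),
               collapse = ", "))
    proj <- project_components(epochs, rca$weights)
    ga <- apply(proj, c(2, 3), mean, na.rm = TRUE)
    windows <- list(
      c1 = window_component1(epochs$time_ms, ga[1, ], group = config$group),
      c2 = window_component2(epochs$time_ms, ga[2, ], group = config$group))
    say("regression windows: c1 [%.0f, %.0f] ms, c2 [%.0f, %.0f] ms",
        windows$c1$start_ms, windows$c1$end_ms,
        windows$c2$start_ms, windows$c2$end_ms)
    pidx <- match(eeg_rows$participant_id, keep_ids)
    slope1 <- slope2 <- rep(NA_real_, length(keep_ids))
    for (i in seq_along(keep_ids)) {
      avg <- apply(proj[pidx == i, , , drop = FALSE], c(2, 3), mean,
                   na.rm = TRUE)
      slope1[i] <- participant_slope(epochs$time_ms, avg[1, ], windows$c1)
      slope2[i] <- participant_slope(epochs$time_ms, avg[2, ], windows$c2)
    }
    parts <- unique(screened[c("participant_id", "age_years")])
    parts <- parts[match(keep_ids, parts$participant_id), ]
    covs <- covariate_table(parts, slope_c1 = slope1, slope_c2 = slope2)
    write.csv(covs, file.path(out, "covariates.csv"), row.names = FALSE)
  } else {
    parts <- unique(screened[c("participant_id", "age_years")])
    covs <- covariate_table(parts)
  }

  # --- model fits ---
  specs <- model_family()[config$models]
  settings <- if (inherits(config$sampler, "sampler_settings")) {
    config$sampler
  } else if (identical(config$sampler, "full")) {
    sampler_settings(seed = config$seed + 3L)
  } else {
    reduced_settings(seed = config$seed + 3L)
  }
  fits <- list()
  for (lbl in names(specs)) {
    needed <- unique(unlist(specs[[lbl]]$covariate_map))
    if (length(needed) && (is.null(covs) || !all(needed %in% names(covs) &
        !vapply(covs[needed], anyNA, TRUE)))) {
      say("skipping %s (missing covariates)", lbl)
      next
    }
    fits[[lbl]] <- sample_posterior(build_model(specs[[lbl]], screened,
                                                covs), settings)
    say("fitted %s in %.1f s", lbl, fits[[lbl]]$runtime_s)
  }
  rhats <- unlist(lapply(fits, function(f)
    gelman_rubin(f, pars = grep("\\[", dimnames(f$draws)[[3]],
                                value = TRUE, invert = TRUE))))
  say("R-hat range across models: %.3f - %.3f", min(rhats), max(rhats))
  comparison <- if (length(fits) >= 2) compare_models(fits) else NULL
  if (!is.null(comparison))
    write.csv(comparison, file.path(out, "model_comparison.csv"),
              row.names = FALSE)
  summaries <- lapply(fits, posterior_summary)
  for (lbl in names(summaries))
    write.csv(summaries[[lbl]],
              file.path(out, paste0("posterior_", lbl, ".csv")),
              row.names = FALSE)

  # --- manifest and report ---
  manifest <- list(config = config,
                   package_version = as.character(
                     utils::packageVersion("hbddm")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  } else {
    dput(manifest, file.path(out, "manifest.R"))
  }
  report <- c("# Pipeline report", "", log_lines, "")
  if (!is.null(comparison)) {
    report <- c(report, "## DIC comparison", "",
                paste(utils::capture.output(print(comparison, digits = 5)),
                      collapse = "\n"))
  }
  writeLines(report, file.path(out, "report.md"))

  invisible(list(screened = screened, exclusions = excl$report,
                 ewma_report = ew$report, participant_report = sc$report,
                 rca = rca, windows = windows, covariates = covs,
                 fits = fits, comparison = comparison,
                 rhat_range = range(rhats), truth = truth))
}
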