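#' EWMA filter configuration
#'
#' Settings for the exponentially weighted moving average control chart used
#' to screen out fast guesses: trials are sorted by response time and the
#' EWMA of the accuracy sequence is compared against an upper control limit
#' around the chance-level control process.
#'
#' @param lambda weight given to the current trial, in (0, 1]; default 0.1.
#' @param c0 control-process mean (chance accuracy); default 0.5.
#' @param sigma0 control-process SD (Bernoulli at chance); default 0.5.
#' @param L width of the control limit in control SDs; default 1.5.
#' @return an `ewma_config` object.
#' @export
ewma_config <- function(lambda = 0.1, c0 = 0.5, sigma0 = 0.5, L = 1.5) {
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must be in (0, 1]")
  if (sigma0 <= 0) stop("sigma0 must be > 0")
  if (L <= 0) stop("L must be > 0")
  structure(list(lambda = lambda, c0 = c0, sigma0 = sigma0, L = L),
            class = "ewma_config")
}

#' EWMA fast-guess cutoff for one participant
#'
#' Sorts one participant's trials by response time (ties broken stably by
#' `trial_index`) and runs an EWMA control chart over the accuracy sequence:
#' `c_s = lambda * x_s + (1 - lambda) * c_{s-1}` with `c_0` the control
#' mean, against the upper control limit
#' `UCL_s = c0 + L * sigma0 * sqrt(lambda / (2 - lambda) * (1 - (1 - lambda)^(2s)))`.
#' The cutoff is the first trial (in RT order) at which `c_s > UCL_s`
#' (strict); trials with RTs below that trial's RT are flagged as fast
#' guesses, and the cutoff trial itself is retained. If the statistic never
#' crosses the limit, no trial is retained.
#'
#' @param trials data frame with columns `rt` (seconds) and `correct`
#'   (0/1 or logical); optional `trial_index` used for stable tie-breaks.
#' @param config an [ewma_config()].
#' @return an `ewma_result` list: `sorted_rts`, `c_trace`, `ucl_trace`,
#'   `cutoff_index` (in RT order, `NA` if no crossing), `cutoff_rt`,
#'   `retained_fraction`, and `keep`, a logical vector aligned with the
#'   input rows.
#' @export
#' @examples
#' tr <- data.frame(rt = c(.3, .5, .4, .8), correct = c(1, 1, 1, 1))
#' ewma_cutoff(tr, ewma_config())
ewma_cutoff <- function(trials, config = ewma_config()) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1,
            inherits(config, "ewma_config"))
  x <- trials$correct
  if (is.logical(x)) x <- as.integer(x)
  if (!all(x %in% c(0, 1))) stop("accuracies must be coded 0/1")
  idx <- if ("trial_index" %in% names(trials)) trials$trial_index
         else seq_len(nrow(trials))
  ord <- order(trials$rt, idx)  # stable in rt, ties by trial_index
  rts <- trials$rt[ord]
  xs <- x[ord]
  n <- length(xs)
  lam <- config$lambda
  c_trace <- numeric(n)
  cprev <- config$c0
  for (s in seq_len(n)) {
    cprev <- lam * xs[s] + (1 - lam) * cprev
    c_trace[s] <- cprev
  }
  s_seq <- seq_len(n)
  ucl_trace <- config$c0 + config$L * config$sigma0 *
    sqrt(lam / (2 - lam) * (1 - (1 - lam)^(2 * s_seq)))
  crossing <- which(c_trace > ucl_trace)
  if (length(crossing) == 0) {
    cutoff_index <- NA_integer_
    cutoff_rt <- NA_real_
    keep <- rep(FALSE, n)
  } else {
    cutoff_index <- crossing[1]
    cutoff_rt <- rts[cutoff_index]
    keep_sorted <- rts >= cutoff_rt
    keep <- logical(n)
    keep[ord] <- keep_sorted
  }
  structure(list(sorted_rts = rts, c_trace = c_trace, ucl_trace = ucl_trace,
                 cutoff_index = cutoff_index, cutoff_rt = cutoff_rt,
                 retained_fraction = mean(keep), keep = keep),
            class = "ewma_result")
}

#' Structural trial exclusions
#'
#' Removes catch trials, trials without a valid response within the deadline
#' and all trials at an excluded coherence level (the hardest condition,
#' which the diffusion model is not asked to fit). Coherence values outside
#' the declared set are kept but reported.
#'
#' @param dataset behavioural trial table (see [gen_behavior()] for the
#'   schema).
#' @param excluded_coherence coherence levels (percent) to drop entirely;
#'   default 10.
#' @param rt_max response deadline in seconds; trials with `rt_s >= rt_max`
#'   or missing responses are dropped. Default 2.5.
#' @param known_coherences coherences the design contains; others trigger a
#'   report entry (rows kept). Default `c(10, 30, 50, 75, 100)`.
#' @return list with `dataset` (surviving rows) and `report`, a data frame
#'   of per-participant counts per rule plus an `unknown_coherence` count.
#' @export
apply_basic_exclusions <- function(dataset, excluded_coherence = 10,
                                   rt_max = 2.5,
                                   known_coherences = c(10, 30, 50, 75, 100)) {
  req <- c("participant_id", "coherence_pct", "rt_s", "is_catch")
  if (!all(req %in% names(dataset)))
    stop("dataset misses columns: ", paste(setdiff(req, names(dataset)),
                                           collapse = ", "))
  is_catch <- as.logical(dataset$is_catch)
  timeout <- is.na(dataset$rt_s) | dataset$rt_s >= rt_max
  excl_coh <- dataset$coherence_pct %in% excluded_coherence
  unknown <- !(dataset$coherence_pct %in% known_coherences)
  if (any(unknown))
    warning(sum(unknown), " rows with unknown coherence values (kept)")
  drop <- is_catch | timeout | excl_coh
  per <- function(flag) tapply(flag, dataset$participant_id, sum)
  ids <- sort(unique(dataset$participant_id))
  report <- data.frame(
    participant_id = ids,
    n_catch = as.integer(per(is_catch)[as.character(ids)]),
    n_timeout = as.integer(per(timeout)[as.character(ids)]),
    n_excluded_coherence = as.integer(per(excl_coh)[as.character(ids)]),
    n_unknown_coherence = as.integer(per(unknown)[as.character(ids)]),
    n_removed = as.integer(per(drop)[as.character(ids)]),
    row.names = NULL)
  list(dataset = dataset[!drop, , drop = FALSE], report = report)
}

#' Apply the EWMA filter to every participant
#'
#' Runs [ewma_cutoff()] on each participant's trials (pooled across
#' conditions, as the screening procedure prescribes) and removes flagged
#' fast guesses.
#'
#' @param dataset behavioural trial table with `participant_id`, `rt_s`,
#'   `correct` (or `choice`/`direction` to derive it) and `trial_index`.
#' @param config an [ewma_config()].
#' @return list with `dataset` (retained trials), `report` (per participant:
#'   `n_trials`, `retained_fraction`, `cutoff_rt`) and `keep`, the logical
#'   row mask on the input.
#' @export
apply_ewma <- function(dataset, config = ewma_config()) {
  if (!"correct" %in% names(dataset)) {
    if (!all(c("choice", "direction") %in% names(dataset)))
      stop("need 'correct' or both 'choice' and 'direction'")
    dataset$correct <- as.integer(dataset$choice == dataset$direction)
  }
  ids <- unique(dataset$participant_id)
  keep <- logical(nrow(dataset))
  rep_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- which(dataset$participant_id == ids[i])
    tr <- data.frame(rt = dataset$rt_s[rows],
                     correct = dataset$correct[rows],
                     trial_index = if ("trial_index" %in% names(dataset))
                       dataset$trial_index[rows] else seq_along(rows))
    res <- ewma_cutoff(tr, config)
    keep[rows] <- res$keep
    rep_rows[[i]] <- data.frame(participant_id = ids[i],
                                n_trials = length(rows),
                                retained_fraction = res$retained_fraction,
                                cutoff_rt = res$cutoff_rt)
  }
  list(dataset = dataset[keep, , drop = FALSE],
       report = do.call(rbind, rep_rows), keep = keep)
}

#' Participant-level retention screening
#'
#' Drops participants whose EWMA-retained fraction falls below a minimum and
#' flags participants responding significantly below chance (one-sided exact
#' binomial test of overall accuracy against 0.5), who would otherwise
#' produce negative drift rates.
#'
#' @param dataset trial table after EWMA filtering (must contain `correct`
#'   or `choice`/`direction`).
#' @param ewma_report per-participant report from [apply_ewma()] (columns
#'   `participant_id`, `retained_fraction`).
#' @param min_retained minimum retained fraction; default 0.6.
#' @param alpha significance level of the below-chance test; default 0.05.
#' @return list with `dataset` (surviving participants' trials) and
#'   `report`: per participant retained fraction, accuracy, below-chance
#'   p-value and the decision (`"keep"`, `"low_retention"`,
#'   `"below_chance"`).
#' @export
screen_participants <- function(dataset, ewma_report, min_retained = 0.6,
                                alpha = 0.05) {
  if (!"correct" %in% names(dataset))
    dataset$correct <- as.integer(dataset$choice == dataset$direction)
  ids <- ewma_report$participant_id
  acc <- rep(NA_real_, length(ids))
  pval <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    rows <- dataset$participant_id == ids[i]
    n <- sum(rows)
    if (n > 0) {
      k <- sum(dataset$correct[rows])
      acc[i] <- k / n
      pval[i] <- binom.test(k, n, p = 0.5, alternative = "less")$p.value
    }
  }
  low <- ewma_report$retained_fraction < min_retained
  below <- !is.na(pval) & pval < alpha
  decision <- ifelse(low, "low_retention",
                     ifelse(below, "below_chance", "keep"))
  report <- data.frame(participant_id = ids,
                       retained_fraction = ewma_report$retained_fraction,
                       accuracy = acc, p_below_chance = pval,
                       decision = decision)
  keep_ids <- ids[decision == "keep"]
  list(dataset = dataset[dataset$participant_id %in% keep_ids, ,
                         drop = FALSE],
       report = report)
}
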