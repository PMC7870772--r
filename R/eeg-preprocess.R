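# EEG pre-processing pipeline. Ops are pure (epochs in, epochs out), keep
# trial identity, and only ever add missing values (never silently impute
# except where interpolation is requested).

#' Median DC-offset correction
#'
#' Subtracts each trial x electrode median over time, removing DC offsets
#' robustly. All-missing traces are left missing.
#'
#' @param epochs an [eeg_epochs()] object.
#' @return corrected epochs.
#' @export
dc_median_correct <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  med <- apply(epochs$data, c(1, 2), median, na.rm = TRUE)
  med[!is.finite(med)] <- NA
  epochs$data <- epochs$data - as.vector(med)  # recycles over samples
  epochs
}

#' Flag outlier electrodes by amplitude exceedance
#'
#' Pools the absolute amplitudes of all samples (the participant-level
#' histogram), takes the `pct` percentile as the outlier threshold and marks
#' electrodes whose fraction of samples above it reaches
#' `max_bad_fraction` - per session (across all trials) or per trial.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param pct percentile defining an outlying sample; default 97.5.
#' @param max_bad_fraction electrode flagged when >= this fraction of its
#'   samples exceed the threshold; default 0.15.
#' @param scope `"session"` (one flag per electrode) or `"trial"`
#'   (trials x electrodes mask).
#' @return logical vector (session) or matrix (trial).
#' @export
flag_outlier_electrodes <- function(epochs, pct = 97.5,
                                    max_bad_fraction = 0.15,
                                    scope = c("session", "trial")) {
  scope <- match.arg(scope)
  stopifnot(inherits(epochs, "eeg_epochs"))
  absd <- abs(epochs$data)
  thr <- quantile(absd, pct / 100, na.rm = TRUE, names = FALSE)
  exceed <- absd > thr
  if (scope == "session") {
    frac <- apply(exceed, 2, mean, na.rm = TRUE)
    out <- !is.na(frac) & frac >= max_bad_fraction
    names(out) <- epochs$channel_names
  } else {
    frac <- apply(exceed, c(1, 2), mean, na.rm = TRUE)
    out <- !is.na(frac) & frac >= max_bad_fraction
    colnames(out) <- epochs$channel_names
  }
  out
}

# nearest good neighbours of electrode e, ordered by layout distance
.near_good <- function(epochs, e, good, k) {
  nbs <- epochs$neighbours[[e]]
  nbs <- nbs[good[nbs]]
  if (!length(nbs)) return(integer(0))
  if (!is.null(epochs$positions)) {
    d <- sqrt(rowSums((epochs$positions[nbs, , drop = FALSE] -
                         matrix(epochs$positions[e, ], length(nbs), 2,
                                byrow = TRUE))^2))
    nbs <- nbs[order(d)]
  }
  nbs[seq_len(min(k, length(nbs)))]
}

#' Interpolate flagged electrodes from their neighbours
#'
#' Replaces each flagged electrode's trace with the average of its nearest
#' good neighbouring electrodes: up to 6 for interior electrodes, up to 4
#' for electrodes on the net's perimeter. If every neighbour is also bad,
#' the electrode is set missing with a warning.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param mask logical electrode vector (session scope) or trials x
#'   electrodes matrix (trial scope) from [flag_outlier_electrodes()].
#' @return epochs with flagged electrodes replaced.
#' @export
interpolate_electrodes <- function(epochs, mask) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  Tn <- dim(epochs$data)[1]; E <- dim(epochs$data)[2]
  per_trial <- is.matrix(mask)
  if (!per_trial) mask <- matrix(mask, Tn, E, byrow = TRUE)
  stranded <- 0L
  for (tr in seq_len(Tn)) {
    bad <- which(mask[tr, ])
    if (!length(bad)) next
    good <- !mask[tr, ]
    src <- epochs$data[tr, , , drop = TRUE]  # E x S, pre-interpolation
    for (e in bad) {
      k <- if (epochs$perimeter[e]) 4 else 6
      nbs <- .near_good(epochs, e, good, k)
      if (!length(nbs)) {
        epochs$data[tr, e, ] <- NA
        stranded <- stranded + 1L
      } else {
        epochs$data[tr, e, ] <-
          colMeans(src[nbs, , drop = FALSE], na.rm = TRUE)
      }
    }
  }
  if (stranded > 0)
    warning(stranded,
            " electrode-trials had no good neighbours and were set missing")
  epochs
}

#' Regress electrooculogram out of every electrode
#'
#' Per electrode, ordinary least squares of the channel on an intercept and
#' the horizontal and vertical EOG traces, pooled across all trials and
#' samples; the OLS residual replaces the channel. If the two EOG channels
#' are collinear, the vertical one is dropped with a warning.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param heog,veog trials x samples matrices, time-aligned with the epochs.
#' @return epochs with EOG contributions removed.
#' @export
regress_out_eog <- function(epochs, heog, veog) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (!all(dim(heog) == d[c(1, 3)]) || !all(dim(veog) == d[c(1, 3)]))
    stop("EOG traces must be trials x samples, aligned with the epochs")
  h <- as.vector(t(heog)); v <- as.vector(t(veog))
  cc <- suppressWarnings(stats::cor(h, v))
  X <- if (is.finite(cc) && abs(cc) > 1 - 1e-10) {
    warning("HEOG and VEOG are collinear; dropping VEOG")
    cbind(1, h)
  } else cbind(1, h, v)
  XtXinv <- solve(crossprod(X))
  for (e in seq_len(d[2])) {
    y <- as.vector(t(epochs$data[, e, , drop = TRUE]))
    ok <- !is.na(y)
    if (sum(ok) <= ncol(X)) next
    bhat <- if (all(ok)) XtXinv %*% crossprod(X, y)
            else solve(crossprod(X[ok, , drop = FALSE]),
                       crossprod(X[ok, , drop = FALSE], y[ok]))
    y <- y - drop(X %*% bhat)
    epochs$data[, e, ] <- matrix(y, d[1], d[3], byrow = TRUE)
  }
  epochs
}

#' Censor transient samples
#'
#' Sets to missing every sample lying `k_sd` or more standard deviations
#' from its electrode's mean (mean/SD pooled over trials and samples).
#' Electrodes with zero spread are left untouched.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param k_sd threshold in SDs; default 4. `Inf` disables censoring.
#' @return epochs with transients set to `NA`.
#' @export
censor_transients <- function(epochs, k_sd = 4) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!is.finite(k_sd)) return(epochs)
  E <- dim(epochs$data)[2]
  for (e in seq_len(E)) {
    x <- epochs$data[, e, , drop = TRUE]
    m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) next
    x[abs(x - m) >= k_sd * s] <- NA
    epochs$data[, e, ] <- x
  }
  epochs
}

#' Average reference and baseline correction
#'
#' Converts to the average reference (per trial and sample, subtract the
#' mean over non-missing electrodes) and then baselines each
#' trial x electrode trace to the mean of the baseline window. Both steps
#' are idempotent. Trials whose baseline window is entirely missing are
#' flagged in the attached report.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param baseline_window_ms length-2 window; default the first 100 ms of
#'   the epoch (for stimulus/boil-locked data, pass the last 100 ms of the
#'   pre-stimulus period instead).
#' @return epochs (attribute `"baseline_report"` lists flagged trials).
#' @export
rereference_and_baseline <- function(epochs, baseline_window_ms = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(baseline_window_ms))
    baseline_window_ms <- c(epochs$time_ms[1], epochs$time_ms[1] + 100)
  if (baseline_window_ms[1] < epochs$time_ms[1] ||
      baseline_window_ms[2] > epochs$time_ms[length(epochs$time_ms)])
    stop("baseline window outside the epoch")
  Tn <- dim(epochs$data)[1]
  # average reference
  for (tr in seq_len(Tn)) {
    x <- epochs$data[tr, , , drop = TRUE]
    ref <- colMeans(x, na.rm = TRUE)
    ref[!is.finite(ref)] <- NA
    epochs$data[tr, , ] <- sweep(x, 2, ref, "-")
  }
  # baseline
  sel <- which(epochs$time_ms >= baseline_window_ms[1] &
                 epochs$time_ms <= baseline_window_ms[2])
  flagged <- integer(0)
  for (tr in seq_len(Tn)) {
    x <- epochs$data[tr, , , drop = TRUE]
    base <- rowMeans(x[, sel, drop = FALSE], na.rm = TRUE)
    if (all(!is.finite(base))) flagged <- c(flagged, tr)
    base[!is.finite(base)] <- 0
    epochs$data[tr, , ] <- x - base
  }
  attr(epochs, "baseline_report") <-
    list(flagged_trials = epochs$trial_index[flagged],
         baseline_window_ms = baseline_window_ms)
  epochs
}

#' Drop trials with too many removed electrodes
#'
#' Removes trials in which the number of effectively-removed electrodes
#' (those with at least `bad_fraction` of samples missing) reaches
#' `max_bad_electrodes`.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param max_bad_electrodes threshold count (>= drops the trial); default
#'   19 (15% of a 128-electrode net).
#' @param bad_fraction fraction of missing samples at which an electrode
#'   counts as removed in a trial; default 0.5.
#' @return list with `epochs` (surviving trials) and `report` (per-trial
#'   bad-electrode counts and the decision).
#' @export
drop_bad_trials <- function(epochs, max_bad_electrodes = 19,
                            bad_fraction = 0.5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  miss <- apply(is.na(epochs$data), c(1, 2), mean)
  n_bad <- rowSums(miss >= bad_fraction)
  keep <- n_bad < max_bad_electrodes
  report <- data.frame(trial_index = epochs$trial_index,
                       n_bad_electrodes = n_bad, kept = keep)
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_index <- epochs$trial_index[keep]
  list(epochs = epochs, report = report)
}

#' Re-epoch stimulus-locked data around the response
#'
#' Cuts a fixed window around each trial's response (default 600 ms before
#' to 200 ms after) out of stimulus-locked epochs. Trials whose window
#' would extend beyond the recording are dropped with a warning and counted
#' in the attached report.
#'
#' @param epochs stimulus-locked [eeg_epochs()].
#' @param rts response times in seconds, one per trial (relative to the
#'   stimulus-locked time origin).
#' @param window_ms response-locked window; default `c(-600, 200)`. The
#'   output time axis runs from `window_ms[1]` to `window_ms[2] - step`
#'   (the response sample is t = 0).
#' @return response-locked `eeg_epochs` (attribute `"epoching_report"`).
#' @export
epoch_response_locked <- function(epochs, rts, window_ms = c(-600, 200)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  Tn <- dim(epochs$data)[1]
  if (length(rts) != Tn) stop("need one RT per trial")
  step <- 1000 / epochs$sample_rate
  if (max(abs(window_ms %% step)) > 1e-9 && max(abs(window_ms %% step - step)) > 1e-9)
    stop("window bounds are not multiples of the sample interval ",
         "(sample-rate mismatch)")
  off1 <- round(window_ms[1] / step); off2 <- round(window_ms[2] / step) - 1
  S_out <- off2 - off1 + 1
  resp_idx <- round((rts * 1000 - epochs$time_ms[1]) / step) + 1
  ok <- resp_idx + off1 >= 1 & resp_idx + off2 <= length(epochs$time_ms)
  if (any(!ok))
    warning(sum(!ok), " trials dropped: response window outside recording")
  out <- array(NA_real_, c(sum(ok), dim(epochs$data)[2], S_out))
  kept <- which(ok)
  for (j in seq_along(kept)) {
    tr <- kept[j]
    out[j, , ] <-
      epochs$data[tr, , (resp_idx[tr] + off1):(resp_idx[tr] + off2)]
  }
  res <- eeg_epochs(out, time_ms = seq(window_ms[1], by = step,
                                       length.out = S_out),
                    channel_names = epochs$channel_names,
                    neighbours = epochs$neighbours,
                    sample_rate = epochs$sample_rate,
                    trial_index = epochs$trial_index[kept],
                    positions = epochs$positions,
                    perimeter = epochs$perimeter, locked = "response")
  attr(res, "epoching_report") <-
    list(n_dropped = sum(!ok), dropped_trials = epochs$trial_index[!ok])
  res
}
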