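#' Mid-latency of a waveform peak
#'
#' Peak-latency estimate that is robust to broad peaks: find the extremum of
#' the requested polarity inside the search window, locate the two latencies
#' at which the waveform crosses 90% of the peak amplitude on either side of
#' the peak (linear interpolation between samples), and return their mean.
#'
#' @param time_ms sample latencies (ms), strictly increasing.
#' @param amplitude waveform values, same length as `time_ms`.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum).
#' @param search_window_ms length-2 window restricting the peak search;
#'   default the full waveform.
#' @return list with `mid_latency_ms`, `peak_latency_ms`, `peak_amplitude`
#'   and the two crossing latencies.
#' @export
mid_latency <- function(time_ms, amplitude,
                        polarity = c("positive", "negative"),
                        search_window_ms = range(time_ms)) {
  polarity <- match.arg(polarity)
  stopifnot(length(time_ms) == length(amplitude))
  win <- which(time_ms >= search_window_ms[1] & time_ms <= search_window_ms[2])
  if (length(win) < 3) stop("search window contains fewer than 3 samples")
  aw <- amplitude[win]
  if (max(aw, na.rm = TRUE) == min(aw, na.rm = TRUE))
    stop("flat waveform: no ", polarity, " peak in the search window")
  pk_rel <- if (polarity == "positive") which.max(aw) else which.min(aw)
  pk <- win[pk_rel]
  peak_amp <- amplitude[pk]
  if ((polarity == "positive" && peak_amp <= 0) ||
      (polarity == "negative" && peak_amp >= 0))
    stop("no ", polarity, " extremum in the search window")
  level <- 0.9 * peak_amp

  cross_lat <- function(side) {
    # walk away from the peak until the waveform falls through `level`
    ii <- if (side == "left") seq(pk, win[1]) else seq(pk, win[length(win)])
    below <- if (polarity == "positive") amplitude[ii] < level
             else amplitude[ii] > level
    j <- which(below)[1]
    if (is.na(j))
      stop("no 90% crossing on the ", side, " side within the window")
    i1 <- ii[j - 1]; i2 <- ii[j]  # crossing between these samples
    frac <- (level - amplitude[i1]) / (amplitude[i2] - amplitude[i1])
    time_ms[i1] + frac * (time_ms[i2] - time_ms[i1])
  }
  left <- cross_lat("left")
  right <- cross_lat("right")
  list(mid_latency_ms = (left + right) / 2,
       peak_latency_ms = time_ms[pk], peak_amplitude = peak_amp,
       cross_left_ms = left, cross_right_ms = right)
}

# interpolated waveform value at an arbitrary latency
.interp_at <- function(time_ms, amplitude, t0) {
  stats::approx(time_ms, amplitude, xout = t0)$y
}

#' Regression window for the centro-parietal (component 1) waveform
#'
#' The end of the window is the mid-latency of the positive peak of the
#' grand-average waveform; the start is the latest pre-end latency at which
#' the waveform crosses 30% of the waveform's amplitude at the mid-latency.
#' Both thresholds are relative, so the window is invariant to positive
#' rescaling of the waveform.
#'
#' @param time_ms,amplitude grand-average component waveform.
#' @param group optional group label stored with the window.
#' @param search_window_ms peak-search window; default the full epoch.
#' @return a `regression_window` list: `start_ms`, `end_ms`,
#'   `component = 1`, `group` and `provenance` (peak/crossing details).
#' @export
window_component1 <- function(time_ms, amplitude, group = NA_character_,
                              search_window_ms = range(time_ms)) {
  ml <- mid_latency(time_ms, amplitude, "positive", search_window_ms)
  end_ms <- ml$mid_latency_ms
  amp_end <- .interp_at(time_ms, amplitude, end_ms)
  thr <- 0.3 * amp_end
  # latest crossing of thr before end_ms (nearest the window end)
  pre <- which(time_ms < end_ms)
  if (length(pre) < 2) stop("no samples before the window end")
  a <- amplitude[pre]; t <- time_ms[pre]
  # append the interpolated end point so a crossing adjacent to it is seen
  a <- c(a, amp_end); t <- c(t, end_ms)
  crosses <- which(diff(a >= thr) != 0)
  if (length(crosses) == 0)
    stop("no 30% crossing before the window end")
  j <- crosses[length(crosses)]
  frac <- (thr - a[j]) / (a[j + 1] - a[j])
  start_ms <- t[j] + frac * (t[j + 1] - t[j])
  structure(list(start_ms = start_ms, end_ms = end_ms, component = 1L,
                 group = group,
                 provenance = list(mid_latency = ml, threshold = thr,
                                   amp_at_end = amp_end)),
            class = "regression_window")
}

#' Regression window for the biphasic (component 2) waveform
#'
#' Component 2 shows a negative trough followed by a positive peak near the
#' response. The window runs from the mid-latency of the negative peak to
#' the mid-latency of the positive peak, both searched within
#' `search_window_ms` (peaks beyond +100 ms are post-response and excluded
#' by default).
#'
#' @param time_ms,amplitude grand-average component waveform.
#' @param group optional group label.
#' @param search_window_ms peak-search window; default c(-600, 100) ms.
#' @return a `regression_window` with `component = 2`.
#' @export
window_component2 <- function(time_ms, amplitude, group = NA_character_,
                              search_window_ms = c(-600, 100)) {
  neg <- mid_latency(time_ms, amplitude, "negative", search_window_ms)
  pos <- mid_latency(time_ms, amplitude, "positive", search_window_ms)
  if (neg$mid_latency_ms >= pos$mid_latency_ms)
    stop("peaks out of order: negative peak must precede the positive peak")
  structure(list(start_ms = neg$mid_latency_ms, end_ms = pos$mid_latency_ms,
                 component = 2L, group = group,
                 provenance = list(negative = neg, positive = pos)),
            class = "regression_window")
}

#' Ramp slope of a participant's average waveform
#'
#' Ordinary least-squares slope of amplitude on time within the group
#' regression window, expressed in microvolts per second.
#'
#' @param time_ms,amplitude the participant's average component waveform.
#' @param window a `regression_window` from [window_component1()] or
#'   [window_component2()].
#' @return slope in uV/s (`NA` with a warning if fewer than 3 non-missing
#'   samples fall in the window).
#' @export
participant_slope <- function(time_ms, amplitude, window) {
  stopifnot(inherits(window, "regression_window"))
  sel <- which(time_ms >= window$start_ms & time_ms <= window$end_ms &
                 !is.na(amplitude))
  if (length(sel) < 3) {
    warning("fewer than 3 usable samples in the regression window")
    return(NA_real_)
  }
  t_s <- time_ms[sel] / 1000
  unname(coef(lm(amplitude[sel] ~ t_s))[2])
}

#' z-standardise a covariate
#'
#' Centre to mean 0 and scale to SD 1 (denominator n - 1), as required for
#' standardized regression weights.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return standardized vector.
#' @export
#' @examples
#' zstandardize(c(1, 2, 3))
zstandardize <- function(values) {
  if (length(unique(values[!is.na(values)])) < 2)
    stop("need at least 2 distinct values to standardize")
  s <- sd(values, na.rm = TRUE)
  if (s == 0) stop("zero variance")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Build the covariate table for the hierarchical model
#'
#' Combines per-participant age and component ramp slopes into the
#' standardized covariate table the covariate-regression models expect.
#'
#' @param participants data frame with `participant_id`, `age_years`.
#' @param slope_c1,slope_c2 per-participant slopes (uV/s), aligned with
#'   `participants`; either may be `NULL`.
#' @return data frame with raw and z-standardized columns (`z_age`,
#'   `z_slope_c1`, `z_slope_c2` as available).
#' @export
covariate_table <- function(participants, slope_c1 = NULL, slope_c2 = NULL) {
  zsafe <- function(x, what) {
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate '", what, "' has no variation; z-score set to NA")
      return(rep(NA_real_, length(x)))
    }
    zstandardize(x)
  }
  out <- data.frame(participant_id = participants$participant_id,
                    age_years = participants$age_years)
  out$z_age <- zsafe(out$age_years, "age")
  if (!is.null(slope_c1)) {
    out$slope_c1 <- slope_c1
    out$z_slope_c1 <- zsafe(slope_c1, "slope_c1")
  }
  if (!is.null(slope_c2)) {
    out$slope_c2 <- slope_c2
    out$z_slope_c2 <- zsafe(slope_c2, "slope_c2")
  }
  out
}
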