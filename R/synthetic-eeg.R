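#' EEG simulation specification
#'
#' Describes the synthetic EEG: a response-locked ramping component over
#' centro-parietal-like electrodes (component 1) plus a biphasic
#' occipital-like component (component 2), embedded in spatially correlated
#' noise. Each participant's component-1 ramp slope is tied linearly to
#' their mean drift rate, so the slope covariate genuinely carries drift
#' information; defaults are calibrated so the slope-age correlation in the
#' default child cohort is about 0.3.
#'
#' @param n_electrodes electrode count; default 128.
#' @param sample_rate Hz; default 500.
#' @param epoch_window_ms response-locked window; default c(-600, 200).
#' @param topographies optional electrodes x 2 matrix of unit-norm
#'   component topographies; default two smooth blobs on the synthetic
#'   layout (midline posterior and occipital pole).
#' @param slope_intercept,slope_per_drift component-1 ramp slope (uV/s) =
#'   intercept + per_drift x mean drift + noise.
#' @param slope_noise_sd SD of the participant slope noise (uV/s).
#' @param slope2_intercept,slope2_per_drift,slope2_noise_sd same linear map
#'   for the (much weaker) component-2 slope.
#' @param onset_range_ms per-participant ramp onset drawn uniformly in this
#'   range (ms before the response).
#' @param decay_ms post-response linear decay duration.
#' @param trial_jitter_sd multiplicative per-trial amplitude jitter SD.
#' @param noise_sd spatially correlated noise scale (uV).
#' @param spatial_noise_rank rank of the spatial noise field.
#' @param white_noise_sd additional sensor white noise (uV).
#' @return an `eeg_sim_spec` object.
#' @export
eeg_sim_spec <- function(n_electrodes = 128, sample_rate = 500,
                         epoch_window_ms = c(-600, 200),
                         topographies = NULL,
                         slope_intercept = 8, slope_per_drift = 6,
                         slope_noise_sd = 7,
                         slope2_intercept = 6, slope2_per_drift = 1.5,
                         slope2_noise_sd = 6,
                         onset_range_ms = c(-450, -250), decay_ms = 150,
                         trial_jitter_sd = 0.2,
                         noise_sd = 3, spatial_noise_rank = 8,
                         white_noise_sd = 1) {
  if (!(epoch_window_ms[1] < 0 && 0 < epoch_window_ms[2]))
    stop("epoch window must contain the response (start < 0 < end)")
  if (!is.null(topographies)) {
    topographies <- as.matrix(topographies)
    nrm <- sqrt(colSums(topographies^2))
    if (any(abs(nrm - 1) > 1e-8))
      stop("topography vectors must be unit norm")
  }
  structure(list(n_electrodes = n_electrodes, sample_rate = sample_rate,
                 epoch_window_ms = epoch_window_ms,
                 topographies = topographies,
                 slope_intercept = slope_intercept,
                 slope_per_drift = slope_per_drift,
                 slope_noise_sd = slope_noise_sd,
                 slope2_intercept = slope2_intercept,
                 slope2_per_drift = slope2_per_drift,
                 slope2_noise_sd = slope2_noise_sd,
                 onset_range_ms = onset_range_ms, decay_ms = decay_ms,
                 trial_jitter_sd = trial_jitter_sd, noise_sd = noise_sd,
                 spatial_noise_rank = spatial_noise_rank,
                 white_noise_sd = white_noise_sd),
            class = "eeg_sim_spec")
}

# default unit-norm topographies on a layout: two gaussian blobs (midline
# posterior and occipital pole), orthogonalised so the components are
# spatially separable
.default_topographies <- function(layout) {
  blob <- function(center, width) {
    d2 <- rowSums(sweep(layout$positions, 2, center, "-")^2)
    v <- exp(-d2 / (2 * width^2))
    v / sqrt(sum(v^2))
  }
  t1 <- blob(c(0, -0.25), 0.35)
  t2 <- blob(c(0, -0.85), 0.25)
  t2 <- t2 - sum(t1 * t2) * t1
  t2 <- t2 / sqrt(sum(t2^2))
  cbind(comp1 = t1, comp2 = t2)
}

#' Per-participant ground-truth ramp slopes
#'
#' Draws the component ramp slopes from their linear maps on mean drift
#' rate. Exposed separately so the slope-age link can be studied without
#' generating full epoch arrays.
#'
#' @param truth per-participant truth table from [gen_behavior()] (needs
#'   `participant_id`, `delta_mean`).
#' @param spec an [eeg_sim_spec()].
#' @param seed integer seed.
#' @return data frame: `participant_id`, `slope_c1`, `slope_c2`,
#'   `onset_ms` (uV/s and ms).
#' @export
gen_participant_slopes <- function(truth, spec = eeg_sim_spec(), seed = 1L) {
  set.seed(as.integer(seed))
  P <- nrow(truth)
  s1 <- spec$slope_intercept + spec$slope_per_drift * truth$delta_mean +
    rnorm(P, 0, spec$slope_noise_sd)
  s1 <- pmax(s1, 0.5)  # ramps are positive-going
  s2 <- spec$slope2_intercept + spec$slope2_per_drift * truth$delta_mean +
    rnorm(P, 0, spec$slope2_noise_sd)
  s2 <- pmax(s2, 0.5)
  onset <- runif(P, spec$onset_range_ms[1], spec$onset_range_ms[2])
  data.frame(participant_id = truth$participant_id, slope_c1 = s1,
             slope_c2 = s2, onset_ms = onset)
}

# component time courses (uV) on a ms grid, response at t = 0
.ramp_c1 <- function(t_ms, slope, onset_ms, decay_ms) {
  peak <- slope * (-onset_ms) / 1000
  ifelse(t_ms < onset_ms, 0,
         ifelse(t_ms <= 0, slope * (t_ms - onset_ms) / 1000,
                pmax(peak * (1 - t_ms / decay_ms), 0)))
}

.ramp_c2 <- function(t_ms, slope, decay_ms) {
  # biphasic: trough at -200 ms, peak at 0, rising limb slope = `slope`
  A <- slope * 0.1  # rise from -A to +A over 200 ms
  ifelse(t_ms < -400, 0,
         ifelse(t_ms < -200, -A * (t_ms + 400) / 200,
                ifelse(t_ms <= 0, -A + slope * (t_ms + 200) / 1000,
                       pmax(A * (1 - t_ms / decay_ms), 0))))
}

#' Generate synthetic EEG epochs for a behavioural dataset
#'
#' Emits one epoch per trial: the two component topographies times their
#' participant-specific time courses (time-locked to the response), plus
#' low-rank spatially correlated Gaussian noise and sensor white noise.
#' With `locked = "stimulus"` the components are positioned at each trial's
#' response time inside a long stimulus-locked window instead (for testing
#' response re-epoching).
#'
#' @param dataset behavioural trial table with `participant_id` and `rt_s`.
#' @param spec an [eeg_sim_spec()].
#' @param seed integer seed.
#' @param behavior_truth optional truth table from [gen_behavior()]; if
#'   given, each participant's ramp slope is tied to their true mean drift
#'   (otherwise a common drift of 2 is assumed for the slope map).
#' @param locked `"response"` (default) or `"stimulus"`.
#' @param stimulus_window_ms window for stimulus-locked output.
#' @return list with `epochs` (an [eeg_epochs()]), `truth` (per-participant
#'   slopes and onsets; topographies attached as attribute `"topographies"`).
#' @export
gen_eeg <- function(dataset, spec = eeg_sim_spec(), seed = 1L,
                    behavior_truth = NULL,
                    locked = c("response", "stimulus"),
                    stimulus_window_ms = c(0, 2800)) {
  locked <- match.arg(locked)
  stopifnot(inherits(spec, "eeg_sim_spec"))
  if (spec$epoch_window_ms[1] > spec$onset_range_ms[1])
    stop("epoch window shorter than the ramp support: window must start ",
         "at or before the earliest ramp onset (", spec$onset_range_ms[1],
         " ms)")
  ids <- unique(dataset$participant_id)
  delta_mean <- if (!is.null(behavior_truth)) {
    m <- match(ids, behavior_truth$participant_id)
    if (anyNA(m)) stop("behavior_truth misses some participants")
    behavior_truth$delta_mean[m]
  } else NULL

  layout <- make_net_layout(spec$n_electrodes)
  topo <- if (is.null(spec$topographies)) .default_topographies(layout)
          else spec$topographies

  # participant truth (slopes tied to mean drift where available)
  pseudo_truth <- data.frame(
    participant_id = ids,
    delta_mean = if (is.null(delta_mean)) rep(2, length(ids))
                 else as.numeric(delta_mean))
  truth <- gen_participant_slopes(pseudo_truth, spec, seed = seed)
  attr(truth, "topographies") <- topo

  step <- 1000 / spec$sample_rate
  if (locked == "response") {
    time_ms <- seq(spec$epoch_window_ms[1],
                   spec$epoch_window_ms[2] - step, by = step)
  } else {
    time_ms <- seq(stimulus_window_ms[1], stimulus_window_ms[2] - step,
                   by = step)
  }
  Tn <- nrow(dataset); E <- spec$n_electrodes; S <- length(time_ms)
  data <- array(0, c(Tn, E, S))
  B <- matrix(rnorm(E * spec$spatial_noise_rank), E)
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  pidx <- match(dataset$participant_id, ids)
  for (tr in seq_len(Tn)) {
    p <- pidx[tr]
    t_rel <- if (locked == "response") time_ms
             else time_ms - dataset$rt_s[tr] * 1000
    c1 <- .ramp_c1(t_rel, truth$slope_c1[p], truth$onset_ms[p],
                   spec$decay_ms)
    c2 <- .ramp_c2(t_rel, truth$slope_c2[p], spec$decay_ms)
    j1 <- 1 + if (spec$trial_jitter_sd > 0) rnorm(1, 0, spec$trial_jitter_sd)
              else 0
    j2 <- 1 + if (spec$trial_jitter_sd > 0) rnorm(1, 0, spec$trial_jitter_sd)
              else 0
    sig <- topo[, 1] %o% (j1 * c1) + topo[, 2] %o% (j2 * c2)
    noise <- 0
    if (spec$noise_sd > 0)
      noise <- spec$noise_sd *
        (B %*% matrix(rnorm(spec$spatial_noise_rank * S), ncol = S))
    if (spec$white_noise_sd > 0)
      noise <- noise + matrix(rnorm(E * S, 0, spec$white_noise_sd), E)
    data[tr, , ] <- sig + noise
  }
  epochs <- eeg_epochs(data, time_ms = time_ms,
                       channel_names = layout$channel_names,
                       neighbours = layout$neighbours,
                       sample_rate = spec$sample_rate,
                       trial_index = if ("trial_index" %in% names(dataset))
                         dataset$trial_index else seq_len(Tn),
                       positions = layout$positions,
                       perimeter = layout$perimeter, locked = locked)
  list(epochs = epochs, truth = truth)
}
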