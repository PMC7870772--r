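test_that("median DC correction zeroes medians and ignores offsets", {
  set.seed(1)
  x <- array(rnorm(4 * 8 * 50), c(4, 8, 50))
  ep <- toy_epochs(x)
  out <- dc_median_correct(ep)
  med <- apply(out$data, c(1, 2), median)
  expect_equal(max(abs(med)), 0, tolerance = 1e-12)
  # constant channel -> zeros
  x2 <- x; x2[1, 3, ] <- 7
  out2 <- dc_median_correct(toy_epochs(x2))
  expect_equal(unname(out2$data[1, 3, ]), rep(0, 50))
  # translation invariance
  out3 <- dc_median_correct(toy_epochs(x + 100))
  expect_equal(out3$data, out$data, tolerance = 1e-10)
})

test_that("outlier-electrode flagging targets gross amplitude excess only", {
  set.seed(2)
  flagged_fracs <- sapply(1:10, function(i) {
    x <- array(rnorm(6 * 16 * 40), c(6, 16, 40))
    mean(flag_outlier_electrodes(toy_epochs(x)))
  })
  expect_lt(mean(flagged_fracs), 0.01)
  x <- array(rnorm(6 * 16 * 40), c(6, 16, 40))
  x[, 5, ] <- x[, 5, ] * 50
  mask <- flag_outlier_electrodes(toy_epochs(x))
  expect_true(mask[5])
  expect_false(any(mask[-5]))
  expect_false(any(flag_outlier_electrodes(toy_epochs(x), pct = 100)))
  # per-trial scope flags only the affected trial
  x2 <- array(rnorm(6 * 16 * 40), c(6, 16, 40))
  x2[2, 7, ] <- x2[2, 7, ] * 80
  m2 <- flag_outlier_electrodes(toy_epochs(x2), scope = "trial")
  expect_true(m2[2, 7])
  expect_lt(mean(m2[-2, ]), 0.02)
})

test_that("interpolation averages the nearest good neighbours", {
  set.seed(3)
  x <- array(rnorm(3 * 16 * 30), c(3, 16, 30))
  ep <- toy_epochs(x)
  e <- which(!ep$perimeter)[1]
  mask <- rep(FALSE, 16); mask[e] <- TRUE
  out <- interpolate_electrodes(ep, mask)
  # brute-force oracle: mean over the 6 nearest good neighbours by distance
  nbs <- ep$neighbours[[e]]
  d <- sqrt(rowSums((ep$positions[nbs, , drop = FALSE] -
                       matrix(ep$positions[e, ], length(nbs), 2,
                              byrow = TRUE))^2))
  pick <- nbs[order(d)][seq_len(min(6, length(nbs)))]
  for (tr in 1:3)
    expect_equal(out$data[tr, e, ],
                 colMeans(x[tr, pick, , drop = TRUE]), tolerance = 1e-12)
  # fixed point: electrode already equal to its neighbour mean
  x2 <- x
  for (tr in 1:3) x2[tr, e, ] <- colMeans(x[tr, pick, , drop = TRUE])
  out2 <- interpolate_electrodes(toy_epochs(x2), mask)
  expect_equal(out2$data[, e, ], x2[, e, ], tolerance = 1e-12)
  # all neighbours bad -> missing with warning
  mask_all <- rep(TRUE, 16)
  expect_warning(out3 <- interpolate_electrodes(ep, mask_all), "neighbour")
  expect_true(all(is.na(out3$data)))
})

test_that("EOG regression removes exactly the EOG contribution", {
  set.seed(4)
  Tn <- 5; S <- 60; E <- 8
  heog <- matrix(rnorm(Tn * S), Tn)
  veog <- matrix(rnorm(Tn * S), Tn)
  x <- array(rnorm(Tn * E * S), c(Tn, E, S))
  x[, 1, ] <- 0.5 * heog                     # pure HEOG leakage
  # electrode 2: orthogonal to both EOGs by construction (regression residual)
  y <- as.vector(t(x[, 2, ]))
  X <- cbind(1, as.vector(t(heog)), as.vector(t(veog)))
  x[, 2, ] <- matrix(y - X %*% solve(crossprod(X), crossprod(X, y)),
                     Tn, S, byrow = TRUE)
  ep <- regress_out_eog(toy_epochs(x), heog, veog)
  expect_lt(max(abs(ep$data[, 1, ])), 1e-10)
  expect_equal(ep$data[, 2, ], x[, 2, ], tolerance = 1e-10)
  # residuals uncorrelated with both EOG channels (covariance scale, so
  # electrodes whose residual is numerically zero do not produce noise)
  for (e in seq_len(E)) {
    r <- as.vector(t(ep$data[, e, ]))
    expect_lt(abs(cov(r, as.vector(t(heog)))), 1e-10)
    expect_lt(abs(cov(r, as.vector(t(veog)))), 1e-10)
  }
  expect_warning(regress_out_eog(toy_epochs(x), heog, heog), "collinear")
})

test_that("transient censoring removes isolated spikes only", {
  set.seed(5)
  x <- array(rnorm(4 * 8 * 100), c(4, 8, 100))
  m <- mean(x[, 3, ]); s <- sd(x[, 3, ])
  x[2, 3, 50] <- m + 10 * s
  out <- censor_transients(toy_epochs(x))
  expect_true(is.na(out$data[2, 3, 50]))
  expect_lt(sum(is.na(out$data)) / length(out$data), 0.005)
  # k = Inf -> identity; constant trace untouched
  expect_identical(censor_transients(toy_epochs(x), Inf)$data, x)
  x2 <- x; x2[, 4, ] <- 3
  expect_equal(censor_transients(toy_epochs(x2))$data[, 4, ],
               x2[, 4, ])
  # missing count never decreases
  expect_gte(sum(is.na(censor_transients(toy_epochs(x))$data)),
             sum(is.na(x)))
})

test_that("average reference and baseline are correct and idempotent", {
  set.seed(6)
  x <- array(rnorm(3 * 10 * 80, mean = 5), c(3, 10, 80))
  ep <- rereference_and_baseline(toy_epochs(x))
  # spatial mean zero at every sample
  sm <- apply(ep$data, c(1, 3), mean)
  expect_lt(max(abs(sm)), 1e-10)
  # baseline-window mean zero per trace (first 100 ms)
  sel <- which(ep$time_ms <= ep$time_ms[1] + 100)
  bm <- apply(ep$data[, , sel], c(1, 2), mean)
  expect_lt(max(abs(bm)), 1e-10)
  ep2 <- rereference_and_baseline(ep)
  expect_equal(ep2$data, ep$data, tolerance = 1e-10)
  expect_error(rereference_and_baseline(toy_epochs(x),
                                        baseline_window_ms = c(-900, -800)),
               "outside")
})

test_that("trials with too many removed electrodes are dropped", {
  x <- array(rnorm(3 * 20 * 30), c(3, 20, 30))
  x[1, 1:19, ] <- NA   # 19 bad -> dropped
  x[2, 1:18, ] <- NA   # 18 bad -> kept
  res <- drop_bad_trials(toy_epochs(x), max_bad_electrodes = 19)
  expect_identical(res$report$kept, c(FALSE, TRUE, TRUE))
  expect_equal(dim(res$epochs$data)[1], 2)
  expect_identical(res$epochs$trial_index, c(2L, 3L))
  clean <- drop_bad_trials(toy_epochs(array(rnorm(3 * 20 * 30),
                                            c(3, 20, 30))))
  expect_true(all(clean$report$kept))
})

test_that("response-locked re-epoching aligns windows to the response", {
  # stimulus-locked: 1500 samples at 500 Hz (0..2998 ms), ramp peaking at rt
  cfg <- data.frame(participant_id = "P1", rt_s = c(1.0, 1.4, 0.4),
                    trial_index = 1:3)
  spec <- eeg_sim_spec(n_electrodes = 8, noise_sd = 0, white_noise_sd = 0,
                       trial_jitter_sd = 0, slope_noise_sd = 0,
                       slope2_noise_sd = 0)
  eeg <- gen_eeg(cfg, spec, seed = 1, locked = "stimulus",
                 stimulus_window_ms = c(0, 3000))
  expect_warning(
    out <- epoch_response_locked(eeg$epochs, cfg$rt_s),
    "dropped")                              # rt = 0.4 s window underruns
  expect_equal(dim(out$data)[3], 400)
  expect_equal(out$time_ms, seq(-600, 198, by = 2))
  expect_identical(out$trial_index, 1:2)
  # the component-1 ramp peaks at the response in every surviving trial
  topo <- attr(eeg$truth, "topographies")
  proj <- project_components(out, topo[, 1, drop = FALSE])
  for (tr in 1:2) {
    pk <- out$time_ms[which.max(proj[tr, 1, ])]
    expect_lt(abs(pk), 4 + 1e-9)            # within two samples of t = 0
  }
  expect_error(epoch_response_locked(eeg$epochs, c(1, 1)), "one RT")
})

test_that("the pipeline preserves trial identity and is near-identity on artefact-free data", {
  # artefact-free homogeneous data: no electrode is flagged, censoring at
  # infinity and trial dropping change nothing, and the only alteration is
  # the median DC shift
  set.seed(2)
  x <- array(rnorm(4 * 12 * 80, mean = 3), c(4, 12, 80))
  ep0 <- toy_epochs(x)
  ep0$trial_index <- 11:14
  ep <- dc_median_correct(ep0)
  ep <- censor_transients(ep, k_sd = Inf)
  mask <- flag_outlier_electrodes(ep)
  expect_false(any(mask))
  res <- drop_bad_trials(ep)
  expect_identical(res$epochs$trial_index, 11:14)
  med <- apply(x, c(1, 2), median)
  expect_equal(res$epochs$data, x - as.vector(med), tolerance = 1e-10)
  # trial identity also survives response re-epoching of signal data
  cfg <- data.frame(participant_id = "P1", rt_s = rep(0.9, 4),
                    trial_index = 11:14)
  eeg <- gen_eeg(cfg, eeg_sim_spec(n_electrodes = 12), seed = 2,
                 locked = "stimulus", stimulus_window_ms = c(0, 2000))
  out <- epoch_response_locked(eeg$epochs, cfg$rt_s)
  expect_identical(out$trial_index, 11:14)
})
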