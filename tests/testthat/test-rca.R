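# brute-force RCA oracle: O(T^2) ordered-pair cross-covariance and a dense
# generalised eigensolve on the full (unreduced) matrices
brute_rca <- function(epochs, n_components) {
  X <- epochs$data
  Tn <- dim(X)[1]; E <- dim(X)[2]
  gm <- apply(X, 2, mean)
  Rxx <- matrix(0, E, E); Rxy <- matrix(0, E, E)
  Xs <- lapply(seq_len(Tn), function(tr) X[tr, , , drop = TRUE] - gm)
  n_s <- dim(X)[3]
  for (tr in seq_len(Tn)) Rxx <- Rxx + tcrossprod(Xs[[tr]])
  Rxx <- Rxx / (Tn * n_s)
  for (t1 in seq_len(Tn)) for (t2 in seq_len(Tn)) if (t1 != t2)
    Rxy <- Rxy + tcrossprod(Xs[[t1]], Xs[[t2]])
  Rxy <- Rxy / (Tn * (Tn - 1) * n_s)
  Rxy <- (Rxy + t(Rxy)) / 2
  # dense generalised eigenproblem via symmetric whitening
  eg <- eigen(Rxx, symmetric = TRUE)
  Wh <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  eg2 <- eigen(Wh %*% Rxy %*% Wh, symmetric = TRUE)
  W <- Wh %*% eg2$vectors[, seq_len(n_components), drop = FALSE]
  list(weights = sweep(W, 2, sqrt(colSums(W^2)), "/"),
       reliability = eg2$values)
}

test_that("identical trials with a rank-1 pattern give one perfectly reliable component", {
  set.seed(1)
  E <- 12; S <- 60
  pattern <- rnorm(E); pattern <- pattern / sqrt(sum(pattern^2))
  tc <- sin(seq(0, 3 * pi, length.out = S))
  one <- pattern %o% tc
  X <- array(rep(one, each = 6), c(6, E, S)) +
    array(rnorm(6 * E * S, 0, 1e-4), c(6, E, S))
  ep <- toy_epochs(X)
  dec <- fit_rca(ep, n_components = 2)
  expect_gt(dec$explained_reliability_fraction[1], 0.99)
  expect_gt(cosim(dec$forward_model[, 1], pattern), 0.999)
})

test_that("the decomposition is invariant to trial order", {
  set.seed(2)
  X <- array(rnorm(10 * 8 * 40), c(10, 8, 40))
  X[, 2, ] <- X[, 2, ] + 3  # give it some structure
  ep1 <- toy_epochs(X)
  ep2 <- toy_epochs(X[sample(10), , ])
  d1 <- fit_rca(ep1, 2); d2 <- fit_rca(ep2, 2)
  expect_equal(abs(d1$weights), abs(d2$weights), tolerance = 1e-8)
  expect_equal(d1$reliability, d2$reliability, tolerance = 1e-8)
})

test_that("reduced-rank solution matches the dense brute-force oracle (16 electrodes)", {
  set.seed(3)
  cfg <- data.frame(participant_id = "P1", rt_s = rep(0.8, 30),
                    trial_index = 1:30)
  spec <- eeg_sim_spec(n_electrodes = 16, noise_sd = 1.5,
                       white_noise_sd = 1)
  eeg <- gen_eeg(cfg, spec, seed = 3)
  ep <- dc_median_correct(eeg$epochs)
  fit <- fit_rca(ep, n_components = 2, rank = 16)   # full rank
  oracle <- brute_rca(ep, 2)
  for (j in 1:2)
    expect_gt(cosim(fit$weights[, j], oracle$weights[, j]), 0.999)
  expect_equal(fit$reliability[1:4], oracle$reliability[1:4],
               tolerance = 1e-6)
  expect_error(fit_rca(ep, rank = 17), "rank")
  expect_error(fit_rca(toy_epochs(ep$data[1, , , drop = FALSE])), "trials")
})

test_that("two orthogonal synthetic components are recovered", {
  set.seed(4)
  sims <- small_cohort(P = 6, n_pc = 12, seed = 44)
  rows <- do.call(rbind, lapply(split(sims$trials, sims$trials$participant_id),
                                head, 24))
  eeg <- gen_eeg(rows, eeg_sim_spec(n_electrodes = 32), seed = 4,
                 behavior_truth = sims$truth)
  ep <- dc_median_correct(eeg$epochs)
  dec <- fit_rca(ep, n_components = 2)
  topo <- attr(eeg$truth, "topographies")
  expect_gt(cosim(dec$forward_model[, 1], topo[, 1]), 0.95)
  expect_gt(cosim(dec$forward_model[, 2], topo[, 2]), 0.95)
  expect_true(all(diff(dec$reliability) <= 1e-12))  # sorted decreasing
  expect_true(all(dec$explained_reliability_fraction >= 0 &
                    dec$explained_reliability_fraction <= 1))
})

test_that("projection behaves like a weighted electrode average", {
  set.seed(5)
  X <- array(rnorm(4 * 8 * 30), c(4, 8, 30))
  ep <- toy_epochs(X)
  w <- matrix(0, 8, 1); w[3, 1] <- 1
  proj <- project_components(ep, w)
  expect_equal(proj[, 1, ], X[, 3, ], tolerance = 1e-12)
  w2 <- matrix(rnorm(8), 8, 1)
  expect_equal(project_components(ep, 2 * w2),
               2 * project_components(ep, w2), tolerance = 1e-12)
  # missing electrode handling: renormalised, all-missing -> NA
  X2 <- X; X2[1, 3, ] <- NA
  proj2 <- project_components(toy_epochs(X2), w)
  expect_true(all(is.na(proj2[1, 1, ])))
  expect_equal(proj2[2, 1, ], X[2, 3, ], tolerance = 1e-12)
})

test_that("the grand-average projection recovers the ramp shape", {
  cfg <- data.frame(participant_id = "P1", rt_s = rep(0.9, 40),
                    trial_index = 1:40)
  eeg <- gen_eeg(cfg, eeg_sim_spec(n_electrodes = 24), seed = 6)
  ep <- dc_median_correct(eeg$epochs)
  dec <- fit_rca(ep, n_components = 1)
  proj <- project_components(ep, dec$weights)
  ga <- apply(proj, 3, mean)
  truth_tc <- hbddm:::.ramp_c1(ep$time_ms, eeg$truth$slope_c1[1],
                               eeg$truth$onset_ms[1], 150)
  expect_gt(cor(ga, truth_tc), 0.99)
})

test_that("forward models obey the algebraic identities", {
  set.seed(7)
  E <- 10
  W <- qr.Q(qr(matrix(rnorm(E * 3), E)))[, 1:3]  # orthonormal
  # white data: A = W
  expect_equal(forward_model(W, diag(E)), W, tolerance = 1e-10)
  # general covariance: A (W' R W) = R W, and scaling W by c scales A by 1/c
  R <- crossprod(matrix(rnorm(3 * E * E), ncol = E)) / (3 * E)
  A <- forward_model(W, R)
  expect_equal(A %*% crossprod(W, R %*% W), R %*% W, tolerance = 1e-8)
  expect_equal(forward_model(3 * W, R), A / 3, tolerance = 1e-10)
  expect_warning(forward_model(cbind(W[, 1], W[, 1]), R), "singular")
})

test_that("pure-noise data show no reliable component beyond the permutation null", {
  set.seed(8)
  X <- array(rnorm(24 * 12 * 50), c(24, 12, 50))
  ep <- toy_epochs(X)
  dec <- fit_rca(ep, n_components = 1)
  # permutation null: shuffle samples within each trial x electrode,
  # destroying any consistent temporal structure across trials
  null_top <- replicate(100, {
    Xp <- X
    for (tr in 1:24) Xp[tr, , ] <- X[tr, , sample(50)]
    fit_rca(toy_epochs(Xp), n_components = 1,
            rank = dec$rank_used)$explained_reliability_fraction[1]
  })
  expect_lt(dec$explained_reliability_fraction[1], quantile(null_top, 0.95))
})

test_that("an all-zero ramp is indistinguishable from the noise floor", {
  cfg <- data.frame(participant_id = "P1", rt_s = rep(0.9, 24),
                    trial_index = 1:24)
  spec0 <- eeg_sim_spec(n_electrodes = 12, slope_intercept = 0,
                        slope_per_drift = 0, slope_noise_sd = 0,
                        slope2_intercept = 0, slope2_per_drift = 0,
                        slope2_noise_sd = 0)
  eeg <- gen_eeg(cfg, spec0, seed = 9)
  # zero-slope spec floors at 0.5 uV/s; cancel to exactly zero signal
  expect_lt(max(abs(eeg$truth$slope_c1)), 1)
  dec <- fit_rca(dc_median_correct(eeg$epochs), n_components = 1)
  X <- eeg$epochs$data
  null_top <- replicate(60, {
    Xp <- X
    for (tr in seq_len(dim(X)[1])) Xp[tr, , ] <- X[tr, , sample(dim(X)[3])]
    fit_rca(toy_epochs(Xp), n_components = 1,
            rank = dec$rank_used)$explained_reliability_fraction[1]
  })
  expect_lt(dec$explained_reliability_fraction[1],
            quantile(null_top, 0.99) + 0.05)
})
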