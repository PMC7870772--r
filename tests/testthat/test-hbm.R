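test_that("sum-to-zero design is orthonormal with zero column sums", {
  for (k in 2:5) {
    Q <- sum_to_zero_design(k)
    expect_equal(dim(Q), c(k, k - 1))
    expect_equal(colSums(Q), rep(0, k - 1), tolerance = 1e-12)
    expect_equal(crossprod(Q), diag(k - 1), tolerance = 1e-12)
    expect_equal(drop(Q %*% rep(0, k - 1)), rep(0, k), tolerance = 1e-15)
    theta <- rnorm(k - 1)
    expect_equal(sum(Q %*% theta), 0, tolerance = 1e-12)
  }
  expect_error(sum_to_zero_design(1), "k must be")
})

test_that("build_model assembles the expected graph and validates covariates", {
  sim <- small_cohort(P = 5, n_pc = 6, seed = 21)
  m <- build_model(model_spec("model1"), sim$trials)
  expect_equal(m$P, 5); expect_equal(m$k, 3)
  # parameter count: 8 hyper + (k-1) theta + g + 3P + Pk
  expect_length(hbddm:::.hbm_par_names(m), 8 + 2 + 1 + 15 + 15)
  covs <- covariate_table(unique(sim$trials[c("participant_id",
                                              "age_years")]))
  spec3 <- model_spec("model3", delta = "z_age")
  m3 <- build_model(spec3, sim$trials, covs)
  expect_equal(m3$n_weights[["delta"]], 1L)
  expect_error(build_model(spec3, sim$trials), "covariates")
  expect_error(build_model(spec3, sim$trials, covs[-2, ]), "missing")
  expect_error(build_model(model_spec("x", delta = "z_nope"), sim$trials,
                           covs), "misses")
})

test_that("prior-predictive draws respect the truncation bounds", {
  sim <- small_cohort(P = 4, n_pc = 4, seed = 22)
  m <- build_model(model_spec("model1"), sim$trials)
  set.seed(1)
  pp <- prior_predict(m, n = 300)
  expect_true(all(pp$alpha >= 0.2 & pp$alpha <= 4))
  expect_true(all(pp$beta >= 0.001 & pp$beta <= 0.999))
  expect_true(all(pp$tau >= 0.1 & pp$tau <= 2))
  expect_true(all(pp$delta >= 0 & pp$delta <= 8))
})

test_that("a fixed covariate weight shifts prior-predictive drift at the stated scale", {
  sim <- small_cohort(P = 30, n_pc = 2, seed = 23)
  covs <- covariate_table(unique(sim$trials[c("participant_id",
                                              "age_years")]))
  m <- build_model(model_spec("model3", delta = "z_age"), sim$trials, covs)
  # hold the group level fixed far from the truncation bounds so the
  # covariate effect on the mean is not attenuated
  gh <- group_hyperparams(1.5, 0.3, 0.5, 0.05, 0.4, 0.1,
                          mu_delta = 4, sigma_eps = 0.9,
                          theta = c(0, 0))
  set.seed(2)
  pp <- prior_predict(m, n = 4000, b_fixed = list(delta = 0.45),
                      hyper_fixed = gh)
  ids <- m$participant_ids
  z <- covs$z_age[match(ids, covs$participant_id)]
  mean_delta <- colMeans(apply(pp$delta, c(1, 2), mean))
  slope <- coef(lm(mean_delta ~ z))[2]
  expect_equal(unname(slope), 0.45 * 0.9, tolerance = 0.05)
})

test_that("the MH kernel reproduces a conjugate normal posterior", {
  set.seed(3)
  y <- rnorm(50, 1.3, 1)
  prior_sd <- 10
  post_var <- 1 / (length(y) + 1 / prior_sd^2)
  post_mean <- sum(y) * post_var
  lp <- function(mu) sum(dnorm(y, mu, 1, log = TRUE)) +
    dnorm(mu, 0, prior_sd, log = TRUE)
  set.seed(4)
  ch <- hbddm:::.amwg_chain_cpp(lp, init = 0, n_samples = 6000,
                                n_burnin = 1000)
  expect_equal(mean(ch), post_mean, tolerance = 0.2 * sqrt(post_var))
  expect_equal(sd(ch), sqrt(post_var), tolerance = 0.15 * sqrt(post_var))
})

test_that("posterior sampling is seed-deterministic and respects bounds", {
  sim <- small_cohort(P = 4, n_pc = 10, seed = 24)
  m <- build_model(model_spec("model1"), sim$trials)
  st <- sampler_settings(n_chains = 2, n_samples = 400, n_burnin = 150,
                         thin = 2, seed = 7)
  f1 <- sample_posterior(m, st)
  f2 <- sample_posterior(m, st)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  expect_equal(dim(f1$draws)[2], (400 - 150) %/% 2)
  nm <- dimnames(f1$draws)[[3]]
  rng <- function(pat) range(f1$draws[, , grep(pat, nm)])
  expect_true(all(rng("^alpha\\[") >= 0.2 & rng("^alpha\\[") <= 4))
  expect_true(all(rng("^beta\\[") >= 0.001 & rng("^beta\\[") <= 0.999))
  expect_true(all(rng("^tau\\[") >= 0.1 & rng("^tau\\[") <= 2))
  expect_true(all(rng("^delta\\[") >= 0 & rng("^delta\\[") <= 8))
})

test_that("Gelman-Rubin diagnostic behaves at its analytic reference points", {
  # exact copies -> R-hat <= 1 + 1e-12
  set.seed(5)
  x <- rnorm(500)
  copies <- array(rep(x, each = 3), c(3, 500, 1),
                  dimnames = list(NULL, NULL, "p"))
  for (ch in 1:3) copies[ch, , 1] <- x
  expect_lte(gelman_rubin(copies)[["p"]], 1 + 1e-12)
  # chains at means 0 and 10 -> R-hat >> 1.1
  far <- array(c(rnorm(1000, 0), rnorm(1000, 10)), c(2, 1000, 1),
               dimnames = list(NULL, NULL, "p"))
  far[1, , 1] <- rnorm(1000, 0); far[2, , 1] <- rnorm(1000, 10)
  expect_gt(gelman_rubin(far)[["p"]], 3)
  expect_error(gelman_rubin(far[1, , , drop = FALSE]), "2 chains")
})

test_that("i.i.d. chains give R-hat in [0.99, 1.02] almost always", {
  set.seed(6)
  rh <- replicate(100, {
    a <- array(rnorm(3 * 500), c(3, 500, 1),
               dimnames = list(NULL, NULL, "p"))
    gelman_rubin(a)[["p"]]
  })
  expect_gte(mean(rh >= 0.99 & rh <= 1.02), 0.95)
})

test_that("DIC is zero-spread at a point-mass posterior and positive otherwise", {
  sim <- small_cohort(P = 4, n_pc = 10, seed = 25)
  m <- build_model(model_spec("model1"), sim$trials)
  fit <- sample_posterior(m, sampler_settings(n_chains = 2, n_samples = 400,
                                              n_burnin = 200, thin = 1,
                                              seed = 9))
  d <- compute_dic(fit)
  expect_gt(d$p_d, 0)
  expect_equal(d$dic, d$mean_deviance + d$p_d, tolerance = 1e-9)
  # collapse the posterior onto a single draw: p_D must be 0 exactly
  pt <- fit
  one <- fit$draws[1, 1, ]
  for (ch in seq_len(dim(pt$draws)[1]))
    pt$draws[ch, , ] <- matrix(one, dim(pt$draws)[2], length(one),
                               byrow = TRUE)
  pm <- hbddm:::.participant_means(pt)
  dev_at <- hbddm:::.hbm_deviance_cpp(m$trial$rt, m$trial$upper,
                                      m$trial$sign, m$trial$p, m$trial$c,
                                      pm$alpha, pm$beta, pm$tau, pm$delta)
  pt$deviance[, ] <- dev_at
  dpt <- compute_dic(pt)
  expect_equal(dpt$p_d, 0, tolerance = 1e-8)
  expect_equal(dpt$dic, dev_at, tolerance = 1e-8)
})

test_that("posterior predictives are calibrated on self-generated data", {
  sim <- small_cohort(P = 6, n_pc = 30, seed = 26, dt = 2e-4)
  m <- build_model(model_spec("model1"), sim$trials)
  fit <- sample_posterior(m, sampler_settings(n_chains = 2,
                                              n_samples = 1200,
                                              n_burnin = 400, thin = 1,
                                              seed = 10))
  pp <- posterior_predictive(fit, n_rep = 80, seed = 11)
  inside <- sapply(seq_len(ncol(pp$observed)), function(j) {
    lo <- apply(pp$replicated[, , j], 2, quantile, 0.025)
    hi <- apply(pp$replicated[, , j], 2, quantile, 0.975)
    mean(pp$observed[, j] >= lo & pp$observed[, j] <= hi)
  })
  expect_gte(mean(inside), 0.9)
  # predictive accuracy ordering follows the condition drift ordering
  conds <- pp$cells$coherence_pct
  ord_ok <- apply(pp$replicated[, , "accuracy"], 1, function(acc) {
    m3 <- tapply(acc, conds, mean)
    all(diff(m3) > -0.05)   # monotone up to finite-trial sampling noise
  })
  expect_gte(mean(ord_ok), 0.9)
  # theory behind it: absorption probability is monotone in drift
  probs <- sapply(c(0.5, 1, 2, 3), function(v)
    absorption_prob_upper(diffusion_params(1.5, 0.5, 0.3, v)))
  expect_true(all(diff(probs) > 0))
})

test_that("starting-point posteriors cluster near 0.5 on balanced data", {
  sim <- small_cohort(P = 6, n_pc = 20, seed = 27)
  m <- build_model(model_spec("model1"), sim$trials)
  fit <- sample_posterior(m, sampler_settings(n_chains = 2, n_samples = 800,
                                              n_burnin = 300, thin = 1,
                                              seed = 12))
  expect_lt(abs(mean(fit$draws[, , "mu_beta"]) - 0.5), 0.05)
})

test_that("model comparison tables are coherent", {
  sim <- small_cohort(P = 5, n_pc = 12, seed = 28)
  covs <- covariate_table(unique(sim$trials[c("participant_id",
                                              "age_years")]))
  st <- sampler_settings(n_chains = 2, n_samples = 500, n_burnin = 200,
                         thin = 1, seed = 13)
  f1 <- sample_posterior(build_model(model_spec("model1"), sim$trials), st)
  f3 <- sample_posterior(build_model(model_spec("model3", delta = "z_age"),
                                     sim$trials, covs), st)
  tab <- compare_models(list(f1, f3))
  expect_equal(tab$delta_dic[1], 0)
  expect_true(all(tab$delta_dic >= 0))
  expect_true(!is.unsorted(tab$dic))
  # identical fits -> both deltas zero
  tab2 <- compare_models(list(f1, f1))
  expect_equal(tab2$delta_dic, c(0, 0), tolerance = 1e-9)
  # different data -> error
  sim2 <- small_cohort(P = 5, n_pc = 12, seed = 29)
  f1b <- sample_posterior(build_model(model_spec("model1"), sim2$trials),
                          st)
  expect_error(compare_models(list(f1, f1b)), "identical")
})

test_that("the model family matches the published covariate maps", {
  fam <- model_family()
  expect_length(fam, 12)
  expect_identical(fam$model4$covariate_map,
                   list(delta = "z_age", alpha = "z_age",
                        tau = character()))
  expect_identical(fam$model7$covariate_map$delta, "z_slope_c2")
  expect_identical(fam$model12$covariate_map,
                   list(delta = c("z_age", "z_slope_c2"), alpha = "z_age",
                        tau = character()))
  expect_true(all(vapply(fam, function(s) inherits(s, "hbm_model_spec"),
                         TRUE)))
})
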