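test_that("density vanishes at and before the non-decision time", {
  p <- diffusion_params(1, 0.5, 0.3, 0)
  expect_identical(wfpt_density(0.25, p, "upper"), 0)
  expect_identical(wfpt_density(0.3, p, "lower"), 0)
  expect_error(wfpt_density(-0.1, p), "negative")
  expect_error(wfpt_density(NaN, p), "non-finite")
})

test_that("reflection symmetry holds exactly on a parameter grid", {
  set.seed(11)
  for (i in 1:100) {
    a <- runif(1, 0.3, 3); w <- runif(1, 0.05, 0.95)
    tau <- runif(1, 0, 0.5); v <- runif(1, -4, 4)
    t <- tau + runif(1, 0.01, 2)
    d_up <- wfpt_density(t, diffusion_params(a, w, tau, v), "upper")
    d_lo <- wfpt_density(t, diffusion_params(a, 1 - w, tau, -v), "lower")
    expect_identical(d_up, d_lo)
  }
})

test_that("density is nonnegative and continuous at the expansion switch", {
  p <- diffusion_params(1.3, 0.4, 0.2, 1.5)
  tt <- seq(0.201, 4, by = 0.0005)
  d_small <- wfpt_density(tt, p, "upper", method = "small")
  d_large <- wfpt_density(tt, p, "upper", method = "large")
  d_auto <- wfpt_density(tt, p, "upper")
  expect_true(all(d_auto >= 0))
  # locate the switch: the first point where auto follows the large-time
  # branch; both expansions must agree there (each within its own bound)
  uses_large <- abs(d_auto - d_large) <= abs(d_auto - d_small)
  sw <- which(uses_large)[1]
  expect_false(is.na(sw)); expect_gt(sw, 1)
  for (i in c(sw - 1, sw)) {
    rel <- abs(d_small[i] - d_large[i]) / d_auto[i]
    expect_lt(rel, 1e-6)
  }
  # and the auto density itself has no visible jump across the switch
  jump <- abs(d_auto[sw] - d_auto[sw - 1]) / d_auto[sw]
  local_step <- abs(d_auto[sw + 1] - d_auto[sw]) / d_auto[sw]
  expect_lt(jump, 10 * local_step + 1e-6)
})

test_that("density integrates to 1 over both boundaries", {
  set.seed(21)
  for (i in 1:5) {
    p <- diffusion_params(runif(1, 0.5, 2.5), runif(1, 0.2, 0.8),
                          runif(1, 0.1, 0.5), runif(1, -3, 3))
    total <- integrate(function(t) wfpt_density(t, p, "upper"), p$tau, Inf,
                       rel.tol = 1e-9)$value +
             integrate(function(t) wfpt_density(t, p, "lower"), p$tau, Inf,
                       rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-4)
  }
})

test_that("upper-boundary mass matches the closed-form absorption probability", {
  p <- diffusion_params(1, 0.5, 0.3, 1)
  expect_equal(absorption_prob_upper(p), (1 - exp(-1)) / (1 - exp(-2)),
               tolerance = 1e-12)
  expect_equal(absorption_prob_upper(diffusion_params(1, 0.5, 0.3, 0)), 0.5)
  # monotone in beta toward 1
  probs <- sapply(seq(0.1, 0.95, by = 0.05), function(b)
    absorption_prob_upper(diffusion_params(1, b, 0.3, 0.5)))
  expect_true(all(diff(probs) > 0))
  expect_gt(absorption_prob_upper(diffusion_params(1, 0.99, 0.3, 0.5)), 0.98)
  # density mass at the upper boundary equals the closed form
  mass <- integrate(function(t) wfpt_density(t, p, "upper"), p$tau, Inf,
                    rel.tol = 1e-9)$value
  expect_equal(mass, absorption_prob_upper(p), tolerance = 1e-6)
})

test_that("simulated choices and RT quantiles match the analytic density", {
  p <- diffusion_params(1.2, 0.45, 0.25, 1.4)
  set.seed(5)
  n <- 20000
  sim <- simulate_fpt(p, n)
  expect_true(all(sim$rt > p$tau))
  pu <- absorption_prob_upper(p)
  se <- sqrt(pu * (1 - pu) / n)
  expect_lt(abs(mean(sim$choice == "up") - pu), 3 * se)
  # RT quantiles of upper-boundary responses vs numerically integrated CDF
  up <- sim$rt[sim$choice == "up"]
  qs <- quantile(up, c(0.1, 0.3, 0.5, 0.7, 0.9))
  Fu <- function(t) integrate(function(s) wfpt_density(s, p, "upper"),
                              p$tau, t, rel.tol = 1e-9)$value / pu
  Fq <- sapply(qs, Fu)
  # binomial SE of the empirical CDF at each quantile
  se_q <- sqrt(c(.1, .3, .5, .7, .9) * (1 - c(.1, .3, .5, .7, .9)) /
                 length(up))
  expect_true(all(abs(Fq - c(.1, .3, .5, .7, .9)) < 3 * se_q))
})

test_that("zero-drift mean decision time matches alpha^2 beta (1 - beta)", {
  p <- diffusion_params(1, 0.5, 0.3, 0)
  set.seed(6)
  sim <- simulate_fpt(p, 30000)
  dt_mean <- mean(sim$rt) - p$tau
  se <- sd(sim$rt) / sqrt(nrow(sim))
  expect_lt(abs(dt_mean - p$alpha^2 * p$beta * (1 - p$beta)), 3 * se)
})

test_that("log-likelihood is additive and respects the coding convention", {
  p <- diffusion_params(1, 0.5, 0.3, 2)
  tr <- data.frame(rt = c(0.5, 0.8, 1.1), choice = c("up", "down", "up"))
  ll <- wiener_loglik(tr, p)
  expect_equal(wiener_loglik(rbind(tr, tr), p), 2 * ll)
  manual <- sum(log(c(wfpt_density(0.5, p, "upper"),
                      wfpt_density(0.8, p, "lower"),
                      wfpt_density(1.1, p, "upper"))))
  expect_equal(ll, manual)
  expect_identical(wiener_loglik(data.frame(rt = 0.2, choice = "up"), p),
                   -Inf)
  expect_error(wiener_loglik(tr[0, ], p), "empty")
})

test_that("grid maximum of the likelihood lies near the generating values", {
  truth <- diffusion_params(1.2, 0.5, 0.3, 1.5)
  set.seed(8)
  sim <- simulate_fpt(truth, 10000)
  grid <- expand.grid(alpha = seq(0.96, 1.44, length.out = 5),
                      beta = seq(0.4, 0.6, length.out = 5),
                      tau = seq(0.24, 0.36, length.out = 5),
                      delta = seq(1.2, 1.8, length.out = 5))
  ll <- apply(grid, 1, function(g)
    wiener_loglik(sim, diffusion_params(g[1], g[2], g[3], g[4])))
  best <- grid[which.max(ll), ]
  expect_lt(abs(best$alpha - truth$alpha) / truth$alpha, 0.05 + 1e-9)
  expect_lt(abs(best$beta - truth$beta) / truth$beta, 0.05 + 1e-9)
  expect_lt(abs(best$tau - truth$tau) / truth$tau, 0.05 + 1e-9)
  expect_lt(abs(best$delta - truth$delta) / truth$delta, 0.05 + 1e-9)
})

test_that("trial simulation is deterministic under a seed and validates dt", {
  p <- diffusion_params(1, 0.5, 0.3, 1)
  set.seed(3); s1 <- simulate_fpt(p, 50)
  set.seed(3); s2 <- simulate_fpt(p, 50)
  expect_identical(s1, s2)
  expect_error(simulate_fpt(p, 10, dt = 0), "dt")
  expect_error(simulate_fpt(p, 0), "n must be")
})
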