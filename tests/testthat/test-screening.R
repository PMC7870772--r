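# hand-computed EWMA recursion for the all-correct sequence at defaults
# (lambda = .1, c0 = .5, sigma0 = .5, L = 1.5), verified independently:
#   c:   0.55, 0.595, 0.6355, ...
#   UCL: 0.575, 0.600902, 0.617779, ...
# first strict crossing at s = 3.
test_that("EWMA statistic and control limit match the hand-computed recursion", {
  tr <- data.frame(rt = seq(0.3, by = 0.1, length.out = 6),
                   correct = rep(1, 6))
  res <- ewma_cutoff(tr, ewma_config())
  expect_equal(res$c_trace[1:3], c(0.55, 0.595, 0.6355), tolerance = 1e-12)
  expect_equal(res$ucl_trace[1:3], c(0.575, 0.6009018, 0.6177787),
               tolerance = 1e-6)
  expect_identical(res$cutoff_index, 3L)
  expect_equal(res$cutoff_rt, 0.5)
  # cutoff trial itself retained; faster trials excluded
  expect_identical(res$keep, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(res$retained_fraction, 4 / 6)
})

test_that("all-incorrect sequences never cross and retain nothing", {
  tr <- data.frame(rt = seq(0.3, 1, length.out = 8), correct = rep(0, 8))
  res <- ewma_cutoff(tr)
  expect_true(all(diff(res$c_trace) < 0))
  expect_true(all(res$c_trace < 0.5))
  expect_true(is.na(res$cutoff_index))
  expect_equal(res$retained_fraction, 0)
})

test_that("lambda = 1 disables the filter (UCL stays above any accuracy)", {
  tr <- data.frame(rt = seq(0.3, 1, length.out = 10), correct = rep(1, 10))
  res <- ewma_cutoff(tr, ewma_config(lambda = 1))
  expect_equal(res$c_trace, rep(1, 10))
  expect_equal(res$ucl_trace, rep(1.25, 10), tolerance = 1e-12)
  expect_true(is.na(res$cutoff_index))
})

test_that("EWMA cutoff is invariant to input row order and UCL is nondecreasing", {
  set.seed(4)
  tr <- data.frame(rt = runif(40, 0.2, 1.5),
                   correct = rbinom(40, 1, 0.8),
                   trial_index = 1:40)
  res1 <- ewma_cutoff(tr)
  perm <- sample(40)
  res2 <- ewma_cutoff(tr[perm, ])
  expect_equal(res1$cutoff_rt, res2$cutoff_rt)
  expect_equal(res1$keep[perm], res2$keep)
  expect_true(all(diff(res1$ucl_trace) >= 0))
  expect_error(ewma_cutoff(data.frame(rt = 1, correct = 2)), "0/1")
})

test_that("basic exclusions count catch, timeout and excluded-coherence rows", {
  d <- data.frame(
    participant_id = "P1",
    coherence_pct = c(100, 100, 30, 10, 10, 10, 50, 75, 30, 50),
    rt_s = c(0.5, 0.6, 2.6, 0.5, 0.7, 0.4, 0.8, 0.9, 0.7, 0.6),
    is_catch = c(TRUE, TRUE, rep(FALSE, 8)))
  # rows: 2 catch, 1 timeout (2.6 s), 3 at 10% -> 4 survive
  res <- apply_basic_exclusions(d)
  expect_equal(nrow(res$dataset), 4)
  expect_equal(res$report$n_catch, 2)
  expect_equal(res$report$n_timeout, 1)
  expect_equal(res$report$n_excluded_coherence, 3)
  # nothing to exclude -> identity
  clean <- d[d$coherence_pct %in% c(30, 50, 75) & d$rt_s < 2.5 &
               !d$is_catch, ]
  expect_identical(apply_basic_exclusions(clean)$dataset, clean)
  # unknown coherence kept with a warning
  d2 <- d; d2$coherence_pct[7] <- 42
  expect_warning(res2 <- apply_basic_exclusions(d2), "unknown")
  expect_true(42 %in% res2$dataset$coherence_pct)
})

test_that("participant screening applies retention and below-chance rules", {
  rep_tab <- data.frame(participant_id = c("A", "B", "C"),
                        retained_fraction = c(0.59, 0.95, 0.9))
  set.seed(2)
  mk <- function(id, n, p_correct) data.frame(
    participant_id = id, rt_s = runif(n, 0.4, 1),
    correct = rbinom(n, 1, p_correct))
  d <- rbind(mk("A", 100, 0.9), mk("B", 200, 0.2), mk("C", 100, 0.85))
  res <- screen_participants(d, rep_tab)
  dec <- setNames(res$report$decision, res$report$participant_id)
  expect_identical(unname(dec["A"]), "low_retention")  # 59% < 60%
  expect_identical(unname(dec["B"]), "below_chance")
  expect_identical(unname(dec["C"]), "keep")
  # below-chance oracle: exact binomial tail
  kB <- sum(d$correct[d$participant_id == "B"])
  expect_lt(pbinom(kB, 200, 0.5), 0.05)
  expect_true(all(res$dataset$participant_id == "C"))
})

test_that("contaminant injection flags exactly the requested fraction", {
  sim <- small_cohort(P = 4, n_pc = 25, seed = 9)   # 75 trials/participant
  out0 <- gen_contaminants(sim$trials, 0)
  expect_identical(out0[names(sim$trials)], sim$trials)
  expect_false(any(out0$.contaminant))
  out <- gen_contaminants(sim$trials, 0.2, seed = 1)
  per <- tapply(out$.contaminant, out$participant_id, sum)
  expect_true(all(per == 15))  # round(0.2 * 75)
  expect_error(gen_contaminants(sim$trials, 0.5), "prop")
})

test_that("EWMA removes the majority of injected fast guesses", {
  # measured behaviour of the first-crossing rule at 20% contamination and
  # 120 trials: mean capture ~0.67 (the 1.5-sigma control limit false-alarms
  # inside long guess runs, so capture is far above chance but not total;
  # see the methods vignette)
  set.seed(31)
  rates <- replicate(20, {
    p <- diffusion_params(1.5, 0.5, 0.45, 1.8)
    sim <- simulate_fpt(p, 120, dt = 1e-3)
    tr <- data.frame(participant_id = "P1", rt_s = sim$rt,
                     direction = "up", choice = sim$choice,
                     correct = as.integer(sim$choice == "up"),
                     trial_index = 1:120)
    tr <- gen_contaminants(tr, 0.2, seed = sample.int(1e6, 1))
    res <- ewma_cutoff(data.frame(rt = tr$rt_s, correct = tr$correct,
                                  trial_index = tr$trial_index))
    mean(!res$keep[tr$.contaminant])
  })
  expect_gt(mean(rates), 0.55)
  expect_gt(median(rates), 0.7)  # typical replicate loses most guesses
})

test_that("contaminant-free simulated data keep almost everything", {
  sim <- small_cohort(P = 6, n_pc = 30, seed = 12)
  ew <- apply_ewma(sim$trials)
  expect_gte(median(ew$report$retained_fraction), 0.95)
  sc <- screen_participants(ew$dataset, ew$report)
  expect_true(all(sc$report$decision == "keep"))
})
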