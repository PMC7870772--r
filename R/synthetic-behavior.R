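# Truncation bounds used throughout the hierarchy (boundary separation,
# starting point, non-decision time, drift rate).
.hbm_bounds <- list(alpha = c(0.2, 4), beta = c(0.001, 0.999),
                    tau = c(0.1, 2), delta = c(0, 8))

# truncated-normal draws by inverse CDF (vectorised, seed-deterministic)
.rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  u <- runif(n, plo, phi)
  pmin(pmax(qnorm(u) * sd + mean, lo), hi)
}

#' Group-level hyperparameters (truth or estimates)
#'
#' Bundles the group means and SDs of the participant-level diffusion
#' parameters, the drift residual SD and the standardized condition effects.
#' Condition effects are `k - 1` free standardized effect sizes mapped to
#' `k` sum-to-zero condition offsets through [sum_to_zero_design()]; the
#' drift mean for condition `c` is
#' `mu_delta + sigma_eps * (Q theta)_c` (plus any covariate terms).
#'
#' @param mu_alpha,sigma_alpha group mean/SD of boundary separation.
#' @param mu_beta,sigma_beta group mean/SD of the starting point.
#' @param mu_tau,sigma_tau group mean/SD of non-decision time (s).
#' @param mu_delta group mean drift rate.
#' @param sigma_eps drift residual SD (also scales condition effects).
#' @param theta standardized condition effects, length `k - 1`.
#' @return a `group_hyperparams` object.
#' @export
group_hyperparams <- function(mu_alpha, sigma_alpha, mu_beta, sigma_beta,
                              mu_tau, sigma_tau, mu_delta, sigma_eps,
                              theta) {
  stopifnot(sigma_alpha > 0, sigma_beta > 0, sigma_tau > 0, sigma_eps > 0)
  ck <- function(x, b, nm) {
    if (x < b[1] || x > b[2])
      stop("group mean ", nm, " = ", x, " outside truncation bounds [",
           b[1], ", ", b[2], "]")
  }
  ck(mu_alpha, .hbm_bounds$alpha, "mu_alpha")
  ck(mu_beta, .hbm_bounds$beta, "mu_beta")
  ck(mu_tau, .hbm_bounds$tau, "mu_tau")
  ck(mu_delta, .hbm_bounds$delta, "mu_delta")
  structure(list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 mu_tau = mu_tau, sigma_tau = sigma_tau,
                 mu_delta = mu_delta, sigma_eps = sigma_eps,
                 theta = theta),
            class = "group_hyperparams")
}

#' Default child-group truth
#'
#' Ground-truth hyperparameters emulating a 6-12-year-old cohort doing
#' motion-coherence discrimination: moderate drift rising steeply with
#' coherence, wide boundaries, long non-decision time. With the default
#' condition effects the per-condition drift means are about
#' (0.8, 1.7, 2.6) for 30/50/75% coherence.
#'
#' @return a [group_hyperparams()] object.
#' @export
child_group_truth <- function() {
  # theta chosen so sigma_eps * Q theta = (-0.9, 0, 0.9) for k = 3
  Q <- sum_to_zero_design(3)
  theta <- drop(crossprod(Q, c(-1, 0, 1)))
  group_hyperparams(mu_alpha = 1.6, sigma_alpha = 0.3,
                    mu_beta = 0.5, sigma_beta = 0.06,
                    mu_tau = 0.45, sigma_tau = 0.10,
                    mu_delta = 1.7, sigma_eps = 0.9, theta = theta)
}

#' Default adult-group truth
#'
#' Adult analogue of [child_group_truth()]: higher drift, narrower
#' boundaries, shorter non-decision time (per-condition drift means about
#' (2.3, 3.2, 4.1)).
#'
#' @return a [group_hyperparams()] object.
#' @export
adult_group_truth <- function() {
  Q <- sum_to_zero_design(3)
  theta <- drop(crossprod(Q, c(-1, 0, 1)))
  group_hyperparams(mu_alpha = 1.2, sigma_alpha = 0.2,
                    mu_beta = 0.5, sigma_beta = 0.04,
                    mu_tau = 0.32, sigma_tau = 0.06,
                    mu_delta = 3.2, sigma_eps = 0.9, theta = theta)
}

#' Simulation configuration
#'
#' Describes a synthetic cohort: its size, age range, trial counts,
#' coherence conditions, ground-truth group hyperparameters and standardized
#' covariate effects of age on the diffusion parameters. The defaults mirror
#' the study design the package targets: 9 blocks x 4 repetitions x 2
#' directions = 72 trials per coherence condition at coherences 30/50/75%.
#'
#' @param n_participants cohort size.
#' @param ages length-2 age range in years (uniformly sampled) or a single
#'   value for a fixed-age cohort.
#' @param n_trials_per_condition trials per coherence condition (split
#'   evenly between up/down directions); default 72.
#' @param coherences coherence levels in percent, strictly increasing;
#'   default `c(30, 50, 75)`.
#' @param group_hyperparams ground truth, a [group_hyperparams()] object.
#' @param covariate_effects named standardized weights of z(age) on the
#'   participant-level parameters: `age_delta`, `age_alpha`, `age_tau`
#'   (any subset; missing = 0).
#' @param contaminant_prop fraction of trials later replaced by fast
#'   guesses via [gen_contaminants()]; must be < 0.5. Default 0.
#' @param group group label stored in the trial table.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_participants = 96, ages = c(6, 12),
                       n_trials_per_condition = 72,
                       coherences = c(30, 50, 75),
                       group_hyperparams = child_group_truth(),
                       covariate_effects = c(age_delta = 0.45,
                                             age_alpha = -0.10,
                                             age_tau = -0.10),
                       contaminant_prop = 0, group = "children",
                       seed = 1L) {
  if (is.unsorted(coherences, strictly = TRUE))
    stop("coherences must be strictly increasing")
  if (contaminant_prop < 0 || contaminant_prop >= 0.5)
    stop("contaminant_prop must be in [0, 0.5)")
  if (length(group_hyperparams$theta) != length(coherences) - 1)
    stop("theta must have length k - 1 = ", length(coherences) - 1)
  stopifnot(inherits(group_hyperparams, "group_hyperparams"),
            n_participants >= 2, n_trials_per_condition >= 2)
  known <- c("age_delta", "age_alpha", "age_tau")
  if (length(covariate_effects) && is.null(names(covariate_effects)))
    stop("covariate_effects must be named")
  bad <- setdiff(names(covariate_effects), known)
  if (length(bad)) stop("unknown covariate effects: ",
                        paste(bad, collapse = ", "))
  structure(list(n_participants = n_participants, ages = ages,
                 n_trials_per_condition = n_trials_per_condition,
                 coherences = coherences,
                 group_hyperparams = group_hyperparams,
                 covariate_effects = covariate_effects,
                 contaminant_prop = contaminant_prop,
                 group = group, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic behavioural dataset with ground truth
#'
#' Draws per-participant diffusion parameters from the truncated-normal
#' hierarchy (with age entering the participant-level means as standardized
#' covariate effects scaled by the relevant group SD), then simulates every
#' trial from the diffusion model's first-passage-time distribution via
#' [simulate_fpt()]. Stimulus direction is counterbalanced within
#' condition; on "down" trials the drift is toward the lower boundary
#' (sign-flipped), so choices are coded up = upper boundary throughout.
#'
#' @param config a [sim_config()].
#' @param dt Euler step for the trial simulator; default 1e-4 s.
#' @return list with `trials` (tidy trial table: `participant_id`, `group`,
#'   `age_years`, `coherence_pct`, `direction`, `choice`, `rt_s`,
#'   `is_catch`, `trial_index`, `correct`) and `truth` (per-participant true
#'   parameters, wide; the config and hyper truth are attached as
#'   attributes).
#' @export
gen_behavior <- function(config, dt = 1e-4) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  P <- config$n_participants
  k <- length(config$coherences)
  gh <- config$group_hyperparams
  eff <- function(nm) {
    v <- config$covariate_effects[nm]
    if (length(v) == 0 || is.na(v)) 0 else unname(v)
  }

  ages <- if (length(config$ages) == 2)
    runif(P, config$ages[1], config$ages[2]) else rep(config$ages[1], P)
  z_age <- if (length(unique(ages)) > 1) zstandardize(ages) else rep(0, P)

  alpha_p <- .rtnorm(P, gh$mu_alpha + gh$sigma_alpha * eff("age_alpha") * z_age,
                     gh$sigma_alpha, .hbm_bounds$alpha[1], .hbm_bounds$alpha[2])
  beta_p <- .rtnorm(P, gh$mu_beta, gh$sigma_beta,
                    .hbm_bounds$beta[1], .hbm_bounds$beta[2])
  tau_p <- .rtnorm(P, gh$mu_tau + gh$sigma_tau * eff("age_tau") * z_age,
                   gh$sigma_tau, .hbm_bounds$tau[1], .hbm_bounds$tau[2])
  qtheta <- drop(sum_to_zero_design(k) %*% gh$theta)
  delta_pc <- matrix(NA_real_, P, k)
  for (cc in seq_len(k)) {
    m <- gh$mu_delta + gh$sigma_eps * (qtheta[cc] + eff("age_delta") * z_age)
    delta_pc[, cc] <- .rtnorm(P, m, gh$sigma_eps,
                              .hbm_bounds$delta[1], .hbm_bounds$delta[2])
  }

  n_pc <- config$n_trials_per_condition
  n_up <- ceiling(n_pc / 2)
  rows <- vector("list", P * k)
  ri <- 0
  for (p in seq_len(P)) {
    for (cc in seq_len(k)) {
      dirs <- rep(c("up", "down"), c(n_up, n_pc - n_up))
      drift <- ifelse(dirs == "up", delta_pc[p, cc], -delta_pc[p, cc])
      # one simulate_fpt call per direction keeps the RNG stream compact
      sim_up <- simulate_fpt(diffusion_params(alpha_p[p], beta_p[p],
                                              tau_p[p], delta_pc[p, cc]),
                             n_up, dt = dt)
      sim_dn <- simulate_fpt(diffusion_params(alpha_p[p], beta_p[p],
                                              tau_p[p], -delta_pc[p, cc]),
                             n_pc - n_up, dt = dt)
      sim <- rbind(sim_up, sim_dn)
      ri <- ri + 1
      rows[[ri]] <- data.frame(
        participant_id = sprintf("P%03d", p), group = config$group,
        age_years = ages[p], coherence_pct = config$coherences[cc],
        direction = dirs, choice = sim$choice, rt_s = sim$rt,
        is_catch = FALSE, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  # shuffle within participant to mimic randomised presentation order
  ord <- order(trials$participant_id, stats::ave(trials$rt_s,
               trials$participant_id, FUN = function(x) sample.int(length(x))))
  trials <- trials[ord, , drop = FALSE]
  trials$trial_index <- stats::ave(seq_len(nrow(trials)),
                                   trials$participant_id, FUN = seq_along)
  trials$correct <- as.integer(trials$choice == trials$direction)
  rownames(trials) <- NULL

  truth <- data.frame(participant_id = sprintf("P%03d", seq_len(P)),
                      group = config$group, age_years = ages, z_age = z_age,
                      alpha = alpha_p, beta = beta_p, tau = tau_p)
  for (cc in seq_len(k))
    truth[[paste0("delta_", config$coherences[cc])]] <- delta_pc[, cc]
  truth$delta_mean <- rowMeans(delta_pc)
  attr(truth, "hyperparams") <- gh
  attr(truth, "config") <- config
  list(trials = trials, truth = truth)
}

#' Inject fast-guess contaminant trials
#'
#' Replaces a fixed proportion of each participant's trials with fast
#' guesses: response times uniform between `guess_rt_min` and the
#' participant's 10th RT percentile, and a random (chance-accurate) choice.
#' Contaminated rows are flagged in a hidden truth column `.contaminant`.
#'
#' @param dataset behavioural trial table (from [gen_behavior()]).
#' @param prop fraction of trials to contaminate per participant, in
#'   `[0, 0.5)`.
#' @param guess_rt_min lower bound of the guess RT distribution (s);
#'   default 0.15.
#' @param seed integer seed.
#' @return the dataset with `rt_s`, `choice`, `correct` overwritten on
#'   contaminated rows and a logical `.contaminant` column appended.
#' @export
gen_contaminants <- function(dataset, prop, guess_rt_min = 0.15, seed = 1L) {
  if (prop < 0 || prop >= 0.5) stop("prop must be in [0, 0.5)")
  set.seed(as.integer(seed))
  flag <- rep(FALSE, nrow(dataset))
  if (prop > 0) {
    for (id in unique(dataset$participant_id)) {
      rows <- which(dataset$participant_id == id)
      n_bad <- round(prop * length(rows))
      if (n_bad == 0) next
      pick <- sample(rows, n_bad)
      p10 <- unname(quantile(dataset$rt_s[rows], 0.10, type = 7))
      hi <- max(p10, guess_rt_min + 0.01)
      dataset$rt_s[pick] <- runif(n_bad, guess_rt_min, hi)
      guess_up <- runif(n_bad) < 0.5
      dataset$choice[pick] <- ifelse(guess_up, "up", "down")
      flag[pick] <- TRUE
    }
    if ("correct" %in% names(dataset))
      dataset$correct <- as.integer(dataset$choice == dataset$direction)
  }
  dataset$.contaminant <- flag
  dataset
}
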