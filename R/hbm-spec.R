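#' Sum-to-zero projection for fixed condition effects
#'
#' Maps `k - 1` free standardized effect sizes to `k` condition offsets that
#' sum to zero, using orthonormal (normalized Helmert) contrast columns, in
#' the style of fixed-effect parameterisations for Bayesian ANOVA. This
#' removes the redundancy between the grand mean and the condition effects.
#'
#' @param k number of conditions, >= 2.
#' @return a `k x (k - 1)` matrix `Q` with orthonormal columns, each
#'   summing to zero; offsets are `Q %*% theta`.
#' @export
#' @examples
#' Q <- sum_to_zero_design(3)
#' colSums(Q)          # ~0
#' crossprod(Q)        # identity
sum_to_zero_design <- function(k) {
  if (k < 2) stop("k must be >= 2")
  H <- stats::contr.helmert(k)  # k x (k-1), orthogonal, column sums 0
  Q <- sweep(H, 2, sqrt(colSums(H^2)), "/")
  dimnames(Q) <- NULL
  Q
}

#' Prior settings for the hierarchical diffusion model
#'
#' Defaults are informative priors centred on typical values from surveys of
#' fitted diffusion parameters: normal priors on the group means (truncated
#' to each parameter's bounds) and half-normal priors on the group SDs.
#' Regression weights carry a Zellner-Siow style mixture of g-priors:
#' `b_j ~ N(0, g)` with `g ~ Inverse-Gamma(1/2, 1/2)` (covariates are
#' z-standardized, so the unit-information scale is 1).
#'
#' @param mu_alpha_prior,mu_beta_prior,mu_tau_prior,mu_delta_prior length-2
#'   `c(mean, sd)` of the truncated-normal priors on the group means.
#' @param sigma_alpha_scale,sigma_beta_scale,sigma_tau_scale,sigma_eps_scale
#'   half-normal scales for the group SDs.
#' @param theta_prior_sd SD of the normal prior on the standardized
#'   condition effects.
#' @return an `hbm_priors` object.
#' @export
hbm_priors <- function(mu_alpha_prior = c(1.0, 0.5),
                       mu_beta_prior = c(0.5, 0.125),
                       mu_tau_prior = c(0.4, 0.3),
                       mu_delta_prior = c(2.0, 1.5),
                       sigma_alpha_scale = 0.5,
                       sigma_beta_scale = 0.125,
                       sigma_tau_scale = 0.3,
                       sigma_eps_scale = 1.0,
                       theta_prior_sd = 1.0) {
  structure(list(mu_alpha_prior = mu_alpha_prior,
                 mu_beta_prior = mu_beta_prior,
                 mu_tau_prior = mu_tau_prior,
                 mu_delta_prior = mu_delta_prior,
                 sigma_alpha_scale = sigma_alpha_scale,
                 sigma_beta_scale = sigma_beta_scale,
                 sigma_tau_scale = sigma_tau_scale,
                 sigma_eps_scale = sigma_eps_scale,
                 theta_prior_sd = theta_prior_sd),
            class = "hbm_priors")
}

#' Model specification: which covariates act on which parameter
#'
#' A model is defined by the sets of standardized covariates regressed on
#' the participant-level means of drift rate, boundary separation and
#' non-decision time. Drift always carries the fixed condition effects.
#'
#' @param label model label (e.g. `"model4"`).
#' @param delta,alpha,tau character vectors of covariate names (columns of
#'   the covariate table, e.g. `"z_age"`, `"z_slope_c1"`); empty = none.
#' @param priors an [hbm_priors()] object.
#' @return an `hbm_model_spec` object.
#' @export
model_spec <- function(label, delta = character(), alpha = character(),
                       tau = character(), priors = hbm_priors()) {
  structure(list(label = label,
                 covariate_map = list(delta = delta, alpha = alpha,
                                      tau = tau),
                 bounds = .hbm_bounds, priors = priors),
            class = "hbm_model_spec")
}

#' The standard model family (models 1-12)
#'
#' The twelve covariate-regression variants compared in the analysis:
#' a no-covariate baseline; age acting on drift, boundary and/or
#' non-decision time; EEG component slopes acting on drift; and combined
#' age + EEG models.
#'
#' @param priors an [hbm_priors()] shared by all specs.
#' @return named list of [model_spec()]s, `model1` .. `model12`.
#' @export
model_family <- function(priors = hbm_priors()) {
  ms <- function(lbl, d = character(), a = character(), t = character())
    model_spec(lbl, delta = d, alpha = a, tau = t, priors = priors)
  list(
    model1 = ms("model1"),
    model2 = ms("model2", d = "z_age", a = "z_age", t = "z_age"),
    model3 = ms("model3", d = "z_age"),
    model4 = ms("model4", d = "z_age", a = "z_age"),
    model5 = ms("model5", d = "z_age", t = "z_age"),
    model6 = ms("model6", d = "z_slope_c1"),
    model7 = ms("model7", d = "z_slope_c2"),
    model8 = ms("model8", d = c("z_slope_c1", "z_slope_c2")),
    model9 = ms("model9", d = c("z_age", "z_slope_c1", "z_slope_c2")),
    model10 = ms("model10", d = c("z_age", "z_slope_c1", "z_slope_c2"),
                 a = "z_age"),
    model11 = ms("model11", d = c("z_age", "z_slope_c1"), a = "z_age"),
    model12 = ms("model12", d = c("z_age", "z_slope_c2"), a = "z_age")
  )
}

#' Sampler settings
#'
#' MCMC run lengths. The full profile mirrors long production runs
#' (3 chains x 54,000 samples, 4,000 burn-in, thin 5 = 10,000 retained per
#' chain); [reduced_settings()] is the desk-scale profile used by the test
#' suite and recovery studies.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_samples total post-initialisation sweeps per chain.
#' @param n_burnin sweeps discarded (and used for proposal adaptation).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed.
#' @return a `sampler_settings` object.
#' @export
sampler_settings <- function(n_chains = 3, n_samples = 54000,
                             n_burnin = 4000, thin = 5, seed = 1L) {
  if (n_samples <= n_burnin) stop("n_samples must exceed n_burnin")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_settings")
}

#' @rdname sampler_settings
#' @export
reduced_settings <- function(seed = 1L) {
  sampler_settings(n_chains = 3, n_samples = 5000, n_burnin = 1000,
                   thin = 1, seed = seed)
}

#' Assemble the hierarchical model graph
#'
#' Binds a [model_spec()] to screened behavioural data and a standardized
#' covariate table, producing the index structures the sampler consumes:
#' trial-level response/RT/condition/participant indices, the per-trial
#' drift sign (stimulus direction), the sum-to-zero condition design and
#' per-parameter covariate matrices. The generative structure is:
#' participant-level `alpha_p, beta_p, tau_p` truncated-normal around group
#' means (shifted by `sigma * sum_j b_j z_j(p)` for covariates on that
#' parameter), condition-level drift
#' `delta_pc ~ TN(mu_delta + sigma_eps * ((Q theta)_c + sum_j b_j z_j(p)), sigma_eps)`,
#' and the Wiener first-passage likelihood on each trial.
#'
#' @param spec an [model_spec()].
#' @param data screened trial table (`participant_id`, `coherence_pct`,
#'   `direction`, `choice`, `rt_s`).
#' @param covariates covariate table with `participant_id` and the columns
#'   named in the model spec (z-standardized).
#' @return an `hbm_model` object.
#' @export
build_model <- function(spec, data, covariates = NULL) {
  stopifnot(inherits(spec, "hbm_model_spec"))
  req <- c("participant_id", "coherence_pct", "direction", "choice", "rt_s")
  if (!all(req %in% names(data)))
    stop("data misses columns: ", paste(setdiff(req, names(data)),
                                        collapse = ", "))
  ids <- sort(unique(data$participant_id))
  conds <- sort(unique(data$coherence_pct))
  P <- length(ids); k <- length(conds)
  if (k < 2) stop("need at least 2 conditions")

  needed <- unique(unlist(spec$covariate_map))
  Z <- list(delta = NULL, alpha = NULL, tau = NULL)
  if (length(needed)) {
    if (is.null(covariates)) stop("spec names covariates but none supplied")
    if (!all(needed %in% names(covariates)))
      stop("covariate table misses: ",
           paste(setdiff(needed, names(covariates)), collapse = ", "))
    m <- match(ids, covariates$participant_id)
    if (anyNA(m))
      stop("covariates missing for participants: ",
           paste(ids[is.na(m)], collapse = ", "))
    cov_aligned <- covariates[m, , drop = FALSE]
    if (anyNA(cov_aligned[needed]))
      stop("NA covariate values for participants: ",
           paste(cov_aligned$participant_id[
             !complete.cases(cov_aligned[needed])], collapse = ", "))
    for (par in names(spec$covariate_map)) {
      nm <- spec$covariate_map[[par]]
      if (length(nm))
        Z[[par]] <- as.matrix(cov_aligned[nm])
    }
  }

  structure(list(
    spec = spec, participant_ids = ids, conditions = conds,
    P = P, k = k,
    Q = sum_to_zero_design(k),
    trial = list(
      p = match(data$participant_id, ids),
      c = match(data$coherence_pct, conds),
      upper = as.integer(data$choice == "up"),
      sign = ifelse(data$direction == "up", 1, -1),
      rt = as.numeric(data$rt_s)),
    Z = Z,
    n_weights = vapply(spec$covariate_map, length, 1L),
    data_fingerprint = sum(as.numeric(data$rt_s)) + nrow(data) +
      1e-3 * sum(data$choice == "up")
  ), class = "hbm_model")
}

#' Prior-predictive draws from a model
#'
#' Samples hyperparameters from their priors, participant-level parameters
#' from the hierarchy (with regression weights at `b` if supplied, else from
#' the g-prior) and returns the implied participant-level parameter draws.
#' Used to check truncation bounds and the covariate entry scale.
#'
#' @param model an `hbm_model` from [build_model()].
#' @param n number of prior draws.
#' @param b_fixed optional named list of fixed regression-weight vectors per
#'   parameter (`delta`, `alpha`, `tau`).
#' @param hyper_fixed optional [group_hyperparams()] to hold the group level
#'   fixed while drawing participant-level parameters.
#' @return list of arrays: `alpha`, `beta`, `tau` (`n x P`) and `delta`
#'   (`n x P x k`).
#' @export
prior_predict <- function(model, n = 1000, b_fixed = NULL,
                          hyper_fixed = NULL) {
  stopifnot(inherits(model, "hbm_model"))
  pr <- model$spec$priors
  bd <- model$spec$bounds
  P <- model$P; k <- model$k
  alpha <- beta <- tau <- matrix(NA_real_, n, P)
  delta <- array(NA_real_, c(n, P, k))
  for (i in seq_len(n)) {
    if (is.null(hyper_fixed)) {
      mu_a <- .rtnorm(1, pr$mu_alpha_prior[1], pr$mu_alpha_prior[2],
                      bd$alpha[1], bd$alpha[2])
      mu_b <- .rtnorm(1, pr$mu_beta_prior[1], pr$mu_beta_prior[2],
                      bd$beta[1], bd$beta[2])
      mu_t <- .rtnorm(1, pr$mu_tau_prior[1], pr$mu_tau_prior[2],
                      bd$tau[1], bd$tau[2])
      mu_d <- .rtnorm(1, pr$mu_delta_prior[1], pr$mu_delta_prior[2],
                      bd$delta[1], bd$delta[2])
      sg_a <- abs(rnorm(1, 0, pr$sigma_alpha_scale))
      sg_b <- abs(rnorm(1, 0, pr$sigma_beta_scale))
      sg_t <- abs(rnorm(1, 0, pr$sigma_tau_scale))
      sg_e <- abs(rnorm(1, 0, pr$sigma_eps_scale))
      theta <- rnorm(k - 1, 0, pr$theta_prior_sd)
    } else {
      gh <- hyper_fixed
      mu_a <- gh$mu_alpha; sg_a <- gh$sigma_alpha
      mu_b <- gh$mu_beta; sg_b <- gh$sigma_beta
      mu_t <- gh$mu_tau; sg_t <- gh$sigma_tau
      mu_d <- gh$mu_delta; sg_e <- gh$sigma_eps
      theta <- gh$theta
    }
    g <- 1 / rgamma(1, 0.5, rate = 0.5)
    bw <- function(par) {
      J <- model$n_weights[[par]]
      if (J == 0) return(numeric(0))
      if (!is.null(b_fixed[[par]])) b_fixed[[par]] else rnorm(J, 0, sqrt(g))
    }
    xd <- if (model$n_weights[["delta"]] > 0)
      drop(model$Z$delta %*% bw("delta")) else rep(0, P)
    xa <- if (model$n_weights[["alpha"]] > 0)
      drop(model$Z$alpha %*% bw("alpha")) else rep(0, P)
    xt <- if (model$n_weights[["tau"]] > 0)
      drop(model$Z$tau %*% bw("tau")) else rep(0, P)
    alpha[i, ] <- .rtnorm(P, mu_a + sg_a * xa, sg_a, bd$alpha[1], bd$alpha[2])
    beta[i, ] <- .rtnorm(P, mu_b, sg_b, bd$beta[1], bd$beta[2])
    tau[i, ] <- .rtnorm(P, mu_t + sg_t * xt, sg_t, bd$tau[1], bd$tau[2])
    qtheta <- drop(model$Q %*% theta)
    for (cc in seq_len(k))
      delta[i, , cc] <- .rtnorm(P, mu_d + sg_e * (qtheta[cc] + xd),
                                sg_e, bd$delta[1], bd$delta[2])
  }
  list(alpha = alpha, beta = beta, tau = tau, delta = delta)
}
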