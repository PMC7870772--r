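# parameter-name vector matching the sampler's column layout
.hbm_par_names <- function(model) {
  ids <- model$participant_ids
  conds <- model$conditions
  nm <- c("mu_alpha", "sigma_alpha", "mu_beta", "sigma_beta",
          "mu_tau", "sigma_tau", "mu_delta", "sigma_eps")
  if (model$k > 1) nm <- c(nm, paste0("theta", seq_len(model$k - 1)))
  cm <- model$spec$covariate_map
  if (length(cm$delta)) nm <- c(nm, paste0("b_delta_", cm$delta))
  if (length(cm$alpha)) nm <- c(nm, paste0("b_alpha_", cm$alpha))
  if (length(cm$tau)) nm <- c(nm, paste0("b_tau_", cm$tau))
  nm <- c(nm, "g",
          paste0("alpha[", ids, "]"), paste0("beta[", ids, "]"),
          paste0("tau[", ids, "]"),
          as.vector(outer(ids, conds,
                          function(i, c) paste0("delta[", i, ",", c, "]"))))
  nm
}

#' Sample from the posterior of a hierarchical diffusion model
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler (random-walk proposals
#' per scalar, step sizes tuned toward 0.44 acceptance during burn-in and
#' frozen afterwards; conjugate inverse-gamma Gibbs step for the g-prior
#' scale). Starting values are drawn uniformly over admissible parameter
#' ranges. The deviance (-2 x trial log-likelihood at the current
#' participant-level parameters) is recorded at every retained draw.
#' Deterministic given `settings$seed`.
#'
#' @param model an `hbm_model` from [build_model()].
#' @param settings a [sampler_settings()]; use [reduced_settings()] for
#'   desk-scale runs.
#' @return an `hbm_fit` object: `draws` (chains x retained draws x named
#'   parameters), `deviance` (chains x retained draws), `model`, `settings`,
#'   `runtime_s`.
#' @export
sample_posterior <- function(model, settings = reduced_settings()) {
  stopifnot(inherits(model, "hbm_model"),
            inherits(settings, "sampler_settings"))
  nm <- .hbm_par_names(model)
  n_retain <- (settings$n_samples - settings$n_burnin) %/% settings$thin
  draws <- array(NA_real_,
                 c(settings$n_chains, n_retain, length(nm)),
                 dimnames = list(NULL, NULL, nm))
  deviance <- matrix(NA_real_, settings$n_chains, n_retain)
  zero_mat <- function(Zi) {
    if (is.null(Zi)) matrix(0, model$P, 0) else Zi
  }
  t0 <- proc.time()[3]
  set.seed(settings$seed)
  for (ch in seq_len(settings$n_chains)) {
    res <- .hbm_sample_chain_cpp(
      model$trial$rt, model$trial$upper, model$trial$sign,
      model$trial$p, model$trial$c, model$P, model$k, model$Q,
      zero_mat(model$Z$delta), zero_mat(model$Z$alpha),
      zero_mat(model$Z$tau), unclass(model$spec$priors),
      unlist(model$spec$bounds, use.names = FALSE),
      settings$n_samples, settings$n_burnin, settings$thin)
    draws[ch, , ] <- res$draws
    deviance[ch, ] <- res$deviance
  }
  structure(list(draws = draws, deviance = deviance, model = model,
                 settings = settings,
                 runtime_s = unname(proc.time()[3] - t0)),
            class = "hbm_fit")
}

#' @export
print.hbm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical diffusion fit '%s': %d chains x %d draws, %d params (%.1f s)\n",
    x$model$spec$label, dim(x$draws)[1], dim(x$draws)[2], dim(x$draws)[3],
    x$runtime_s))
  invisible(x)
}

#' Posterior summary table
#'
#' @param fit an `hbm_fit`.
#' @param pars parameter names (default: hyperparameters and regression
#'   weights, i.e. everything that is not participant-level).
#' @param probs credible-interval probabilities.
#' @return data frame with mean, sd, quantiles and split-free Rhat.
#' @export
posterior_summary <- function(fit, pars = NULL, probs = c(0.025, 0.975)) {
  stopifnot(inherits(fit, "hbm_fit"))
  nm <- dimnames(fit$draws)[[3]]
  if (is.null(pars)) pars <- nm[!grepl("\\[", nm)]
  rh <- gelman_rubin(fit, pars = pars)
  out <- lapply(pars, function(pn) {
    x <- as.vector(fit$draws[, , pn])
    q <- quantile(x, probs)
    data.frame(parameter = pn, mean = mean(x), sd = sd(x),
               t(as.matrix(q)), rhat = rh[pn], check.names = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Classic (split-free) potential scale reduction factor: the square root of
#' the weighted between/within chain variance ratio.
#'
#' @param fit an `hbm_fit`, or a 3-d array chains x draws x parameters.
#' @param pars subset of parameter names (default all).
#' @return named vector of R-hat values.
#' @export
gelman_rubin <- function(fit, pars = NULL) {
  draws <- if (inherits(fit, "hbm_fit")) fit$draws else fit
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[1] < 2) stop("need at least 2 chains")
  nm <- dimnames(draws)[[3]]
  if (is.null(nm)) nm <- as.character(seq_len(dim(draws)[3]))
  if (is.null(pars)) pars <- nm
  n <- dim(draws)[2]
  out <- vapply(pars, function(pn) {
    x <- draws[, , match(pn, nm), drop = TRUE]  # chains x draws
    means <- rowMeans(x)
    W <- mean(apply(x, 1, var))
    B_over_n <- var(means)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(out) <- pars
  out
}

# posterior means of the participant-level parameters, as plug-in values
.participant_means <- function(fit) {
  model <- fit$model
  nm <- dimnames(fit$draws)[[3]]
  pull <- function(pat) {
    sel <- grep(pat, nm, fixed = FALSE)
    apply(fit$draws[, , sel, drop = FALSE], 3, mean)
  }
  ids <- model$participant_ids
  alpha <- pull("^alpha\\[")
  beta <- pull("^beta\\[")
  tau <- pull("^tau\\[")
  delta <- matrix(pull("^delta\\["), model$P, model$k)
  list(alpha = unname(alpha), beta = unname(beta), tau = unname(tau),
       delta = delta, ids = ids)
}

#' Deviance information criterion
#'
#' `p_D = mean(deviance) - deviance(at the posterior means of the
#' participant-level parameters)`; `DIC = mean(deviance) + p_D`. The
#' plug-in deviance is focused at the participant level (the level whose
#' parameters enter the likelihood), matching common practice for
#' hierarchical response-time models.
#'
#' @param fit an `hbm_fit` (must carry a deviance trace).
#' @return list with `dic`, `p_d` and `mean_deviance`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "hbm_fit"))
  if (is.null(fit$deviance) || !length(fit$deviance))
    stop("fit carries no deviance trace")
  dbar <- mean(fit$deviance)
  pm <- .participant_means(fit)
  dhat <- .hbm_deviance_cpp(fit$model$trial$rt, fit$model$trial$upper,
                            fit$model$trial$sign, fit$model$trial$p,
                            fit$model$trial$c, pm$alpha, pm$beta, pm$tau,
                            pm$delta)
  list(dic = dbar + (dbar - dhat), p_d = dbar - dhat, mean_deviance = dbar)
}

#' Posterior predictive datasets and quantile summaries
#'
#' Draws parameter vectors from the posterior, simulates replicated datasets
#' with [simulate_fpt()] (same trial counts and directions per
#' participant x condition cell as observed) and summarises accuracy and RT
#' quantiles per cell against the observed data.
#'
#' @param fit an `hbm_fit`.
#' @param n_rep number of replicated datasets.
#' @param dt Euler step for the replicate simulator (coarser than the
#'   default generator step; predictive bands are insensitive to it).
#' @param probs RT quantiles to summarise.
#' @param seed integer seed.
#' @return list with `observed` (per-cell accuracy and RT quantiles) and
#'   `replicated` (n_rep x cell x statistic array).
#' @export
posterior_predictive <- function(fit, n_rep = 100, dt = 1e-3,
                                 probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 seed = 1L) {
  stopifnot(inherits(fit, "hbm_fit"))
  set.seed(seed)
  model <- fit$model
  tr <- model$trial
  cells <- unique(data.frame(p = tr$p, c = tr$c))
  cells <- cells[order(cells$p, cells$c), ]
  stat_names <- c("accuracy", paste0("q", probs * 100))
  obs <- matrix(NA_real_, nrow(cells), length(stat_names),
                dimnames = list(NULL, stat_names))
  cell_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rows <- which(tr$p == cells$p[i] & tr$c == cells$c[i])
    cell_rows[[i]] <- rows
    correct_obs <- tr$upper[rows] == (tr$sign[rows] == 1)
    obs[i, ] <- c(mean(correct_obs), quantile(tr$rt[rows], probs))
  }
  n_ch <- dim(fit$draws)[1]; n_dr <- dim(fit$draws)[2]
  nm <- dimnames(fit$draws)[[3]]
  rep_arr <- array(NA_real_, c(n_rep, nrow(cells), length(stat_names)),
                   dimnames = list(NULL, NULL, stat_names))
  for (r in seq_len(n_rep)) {
    ch <- sample.int(n_ch, 1); dr <- sample.int(n_dr, 1)
    dv <- fit$draws[ch, dr, ]
    for (i in seq_len(nrow(cells))) {
      p <- cells$p[i]; cc <- cells$c[i]
      rows <- cell_rows[[i]]
      id <- model$participant_ids[p]; cond <- model$conditions[cc]
      pars_up <- diffusion_params(
        dv[paste0("alpha[", id, "]")], dv[paste0("beta[", id, "]")],
        dv[paste0("tau[", id, "]")], dv[paste0("delta[", id, ",", cond, "]")])
      n_up <- sum(tr$sign[rows] == 1); n_dn <- sum(tr$sign[rows] == -1)
      sims <- list()
      if (n_up > 0) {
        s <- simulate_fpt(pars_up, n_up, dt = dt)
        sims$up <- data.frame(rt = s$rt, correct = s$choice == "up")
      }
      if (n_dn > 0) {
        pars_dn <- pars_up; pars_dn$delta <- -pars_dn$delta
        s <- simulate_fpt(pars_dn, n_dn, dt = dt)
        sims$dn <- data.frame(rt = s$rt, correct = s$choice == "down")
      }
      sim <- do.call(rbind, sims)
      rep_arr[r, i, ] <- c(mean(sim$correct), quantile(sim$rt, probs))
    }
  }
  list(cells = data.frame(
         participant_id = model$participant_ids[cells$p],
         coherence_pct = model$conditions[cells$c]),
       observed = obs, replicated = rep_arr, probs = probs)
}

#' DIC model-comparison table
#'
#' Tabulates DIC, effective parameter count and the DIC difference from the
#' best model, for a set of fits of different model specs to the same data.
#' Also reports the residual regression variances (posterior mean of the
#' squared group SD of each regressed parameter).
#'
#' @param fits list of `hbm_fit` objects (>= 2) fitted to identical data.
#' @return data frame sorted by DIC (best first) with columns `model`,
#'   `covariates`, `dic`, `delta_dic`, `p_d`, `mean_deviance`,
#'   `resid_var_delta`, `resid_var_alpha`, `resid_var_tau`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  fp <- vapply(fits, function(f) f$model$data_fingerprint, numeric(1))
  if (max(abs(fp - fp[1])) > 1e-8)
    stop("fits were not computed on identical datasets")
  rows <- lapply(fits, function(f) {
    dic <- compute_dic(f)
    cm <- f$model$spec$covariate_map
    covs <- paste(vapply(names(cm), function(par) {
      if (length(cm[[par]]))
        paste0(par, ": ", paste(cm[[par]], collapse = "+")) else ""
    }, character(1)), collapse = " ")
    covs <- trimws(gsub("\\s+", " ", covs))
    if (covs == "") covs <- "none"
    pm2 <- function(pn) mean(as.vector(f$draws[, , pn])^2)
    data.frame(model = f$model$spec$label, covariates = covs,
               dic = dic$dic, p_d = dic$p_d,
               mean_deviance = dic$mean_deviance,
               resid_var_delta = pm2("sigma_eps"),
               resid_var_alpha = pm2("sigma_alpha"),
               resid_var_tau = pm2("sigma_tau"))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$dic), ]
  tab$delta_dic <- tab$dic - tab$dic[1]
  rownames(tab) <- NULL
  tab[, c("model", "covariates", "dic", "delta_dic", "p_d",
          "mean_deviance", "resid_var_delta", "resid_var_alpha",
          "resid_var_tau")]
}
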