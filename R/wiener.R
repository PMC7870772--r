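#' Diffusion model parameter set
#'
#' Bundles the four parameters of the simplified diffusion model: boundary
#' separation `alpha` (evidence units), relative starting point `beta`
#' (fraction of the boundary separation), non-decision time `tau` (seconds)
#' and drift rate `delta` (evidence units per second). The diffusion
#' coefficient is fixed at 1. Core density/simulation functions accept any
#' `alpha > 0`, `0 < beta < 1`, `tau >= 0` and real `delta`; the narrower
#' bounds used by the hierarchical model are enforced there, not here.
#'
#' @param alpha boundary separation, > 0.
#' @param beta relative starting point, in (0, 1).
#' @param tau non-decision time in seconds, >= 0.
#' @param delta drift rate (may be negative in core functions).
#' @return An object of class `diffusion_params` (a named list).
#' @export
#' @examples
#' diffusion_params(alpha = 1, beta = 0.5, tau = 0.3, delta = 2)
diffusion_params <- function(alpha, beta, tau, delta) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(tau),
            is.finite(delta))
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  if (tau < 0) stop("tau must be >= 0")
  structure(list(alpha = alpha, beta = beta, tau = tau, delta = delta),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf(
    "Diffusion parameters: alpha = %.3f, beta = %.3f, tau = %.3f, delta = %.3f\n",
    x$alpha, x$beta, x$tau, x$delta))
  invisible(x)
}

#' Wiener first-passage-time density
#'
#' Density of the response time `t` for responses terminating at the named
#' boundary, under the 4-parameter diffusion model. Implemented with both
#' the small-time and large-time series expansions of the first-passage
#' density; by default the expansion requiring fewer terms at an absolute
#' term tolerance of 1e-29 is used. Returns 0 for `t <= tau`.
#'
#' @param t response times in seconds (vectorised); must be non-negative.
#' @param params a [diffusion_params()] object.
#' @param boundary `"upper"` or `"lower"`: which boundary the response hit.
#' @param log return the log density?
#' @param method `"auto"` (default) switches between expansions by the
#'   number of terms required; `"small"` / `"large"` force one expansion
#'   (used to verify continuity at the switch point).
#' @return numeric vector of densities (1/seconds).
#' @export
#' @examples
#' p <- diffusion_params(1, 0.5, 0.3, 2)
#' wfpt_density(c(0.4, 0.6, 1), p, boundary = "upper")
wfpt_density <- function(t, params, boundary = c("upper", "lower"),
                         log = FALSE, method = c("auto", "small", "large")) {
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  stopifnot(inherits(params, "diffusion_params"))
  if (any(!is.finite(t))) stop("non-finite response times")
  if (any(t < 0)) stop("negative response times")
  m <- match(method, c("auto", "small", "large")) - 1L
  .wfpt_density_cpp(t, params$alpha, params$beta, params$tau, params$delta,
                    boundary == "upper", m, log)
}

#' Joint log-likelihood of a trial set under the diffusion model
#'
#' Sums the log first-passage density over trials, with "up" responses coded
#' as hitting the upper boundary and "down" responses the lower boundary.
#' Any trial with `rt <= tau` contributes zero density, so the result is
#' `-Inf`.
#'
#' @param trials a data frame with columns `rt` (seconds) and `choice`
#'   (`"up"`/`"down"`), one row per trial.
#' @param params a [diffusion_params()] object; `params$delta` may be a
#'   vector with one drift per trial (condition-specific drifts).
#' @return scalar log-likelihood.
#' @export
wiener_loglik <- function(trials, params) {
  stopifnot(is.data.frame(trials), inherits(params, "diffusion_params"))
  if (nrow(trials) == 0) stop("empty trial list")
  if (!all(c("rt", "choice") %in% names(trials)))
    stop("trials needs columns 'rt' and 'choice'")
  if (!all(trials$choice %in% c("up", "down")))
    stop("choice must be 'up' or 'down'")
  delta <- rep_len(params$delta, nrow(trials))
  .wiener_loglik_cpp(as.numeric(trials$rt),
                     as.integer(trials$choice == "up"),
                     params$alpha, params$beta, params$tau, delta)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form probability that the diffusion terminates at the upper
#' boundary: `(1 - exp(-2 v a w)) / (1 - exp(-2 v a))` with the zero-drift
#' limit equal to `beta`. Used as an analytic oracle for the simulator.
#'
#' @param params a [diffusion_params()] object.
#' @return probability in (0, 1).
#' @export
#' @examples
#' absorption_prob_upper(diffusion_params(1, 0.5, 0.3, 1)) # ~0.7311
absorption_prob_upper <- function(params) {
  stopifnot(inherits(params, "diffusion_params"))
  a <- params$alpha; w <- params$beta; v <- params$delta
  if (abs(v) < 1e-10) return(w)
  expm1(-2 * v * a * w) / expm1(-2 * v * a)
}

#' Simulate diffusion-model trials (Euler-Maruyama)
#'
#' Simulates first-passage times of the diffusion process with absorbing
#' boundaries at 0 and `alpha`, start `beta * alpha`, drift `delta` and unit
#' diffusion coefficient, by Euler-Maruyama discretisation at step `dt`.
#' Response time is the decision time plus `tau`. Deterministic under
#' `set.seed()`. Plain Euler misses boundary crossings between grid points,
#' biasing first-passage times upward by O(sqrt(dt)); with
#' `bridge = TRUE` (default) a Brownian-bridge crossing test is applied on
#' each step, reducing the bias to O(dt).
#'
#' @param params a [diffusion_params()] object.
#' @param n number of trials, >= 1.
#' @param dt Euler time step in seconds, > 0.
#' @param max_t simulation horizon in seconds; trials not absorbed by then
#'   (vanishingly rare at sane parameters) are censored to the nearer
#'   boundary.
#' @param bridge apply the Brownian-bridge interval-crossing correction?
#' @return data frame with columns `rt` (seconds) and `choice`
#'   (`"up"`/`"down"`).
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_fpt(diffusion_params(1, 0.5, 0.3, 2), n = 100)
#' mean(sim$choice == "up")
simulate_fpt <- function(params, n, dt = 1e-4, max_t = 20, bridge = TRUE) {
  stopifnot(inherits(params, "diffusion_params"))
  if (n < 1) stop("n must be >= 1")
  if (dt <= 0) stop("dt must be > 0")
  sim <- .simulate_fpt_cpp(as.integer(n), params$alpha, params$beta,
                           params$tau, params$delta, dt, max_t, bridge)
  data.frame(rt = sim$rt, choice = ifelse(sim$upper == 1L, "up", "down"),
             stringsAsFactors = FALSE)
}
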