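#' Reliable components analysis
#'
#' Finds electrode weightings that maximise trial-to-trial reliability: the
#' generalised eigenvectors of the across-trial cross-covariance `R_xy`
#' (averaged over all ordered trial pairs and symmetrised) against the
#' pooled within-trial covariance `R_xx`. The pair average is computed in
#' O(trials) through the identity
#' `sum_{t != u} X_t X_u' = (sum_t X_t)(sum_t X_t)' - sum_t X_t X_t'`,
#' with missing samples handled by pairwise-complete normalisation. The
#' eigenproblem is regularised by projecting onto the leading principal
#' components of `R_xx` (by default the smallest rank capturing 99% of its
#' variance). Components are oriented so the grand-average time course is
#' positive at the response (t = 0).
#'
#' @param epochs an [eeg_epochs()] object (>= 2 trials).
#' @param n_components number of components to keep.
#' @param rank subspace rank; `NULL` = smallest rank capturing
#'   `rank_var_goal` of `R_xx` variance.
#' @param rank_var_goal variance fraction the automatic rank must capture.
#' @return an `rca_decomposition`: `weights` (electrodes x components),
#'   `forward_model`, `reliability` (generalised eigenvalues, decreasing),
#'   `explained_reliability_fraction` (per component, normalised by the sum
#'   of positive eigenvalues), `rank_used`, `Rxx`, `Rxy`.
#' @export
fit_rca <- function(epochs, n_components = 3, rank = NULL,
                    rank_var_goal = 0.99) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  Tn <- dim(epochs$data)[1]; E <- dim(epochs$data)[2]
  if (Tn < 2) stop("need at least 2 trials")
  if (!is.null(rank) && rank > E) stop("rank cannot exceed electrode count")

  # center by the per-electrode grand mean
  gm <- apply(epochs$data, 2, mean, na.rm = TRUE)
  S1 <- matrix(0, E, dim(epochs$data)[3])
  SS <- matrix(0, E, E); N1 <- S1; NN <- SS
  for (tr in seq_len(Tn)) {
    X <- epochs$data[tr, , , drop = TRUE] - gm
    M <- !is.na(X)
    X[!M] <- 0
    S1 <- S1 + X; N1 <- N1 + M
    SS <- SS + tcrossprod(X); NN <- NN + tcrossprod(M * 1)
  }
  Rxx <- SS / pmax(NN, 1)
  num <- tcrossprod(S1) - SS
  cnt <- tcrossprod(N1) - NN
  Rxy <- num / pmax(cnt, 1)
  Rxy <- (Rxy + t(Rxy)) / 2

  eg <- eigen(Rxx, symmetric = TRUE)
  if (is.null(rank)) {
    cum <- cumsum(pmax(eg$values, 0)) / sum(pmax(eg$values, 0))
    rank <- which(cum >= rank_var_goal)[1]
  }
  rank <- max(rank, n_components)
  V <- eg$vectors[, seq_len(rank), drop = FALSE]
  dhalf <- 1 / sqrt(pmax(eg$values[seq_len(rank)], 1e-12))
  Vw <- sweep(V, 2, dhalf, "*")                  # whitening basis
  M <- crossprod(Vw, Rxy %*% Vw)
  M <- (M + t(M)) / 2
  eg2 <- eigen(M, symmetric = TRUE)              # values decreasing
  n_components <- min(n_components, rank)
  W <- Vw %*% eg2$vectors[, seq_len(n_components), drop = FALSE]
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")      # unit-norm weights
  rho <- eg2$values
  expl <- pmax(rho, 0) / sum(pmax(rho, 0))

  # sign convention: grand-average component value at t = 0 positive
  proj <- project_components(epochs, W)
  ga <- apply(proj, c(2, 3), mean, na.rm = TRUE)  # components x samples
  t0 <- which.min(abs(epochs$time_ms))
  for (j in seq_len(n_components)) {
    ref <- ga[j, t0]
    if (!is.finite(ref) || ref == 0) ref <- ga[j, which.max(abs(ga[j, ]))]
    if (is.finite(ref) && ref < 0) W[, j] <- -W[, j]
  }
  fm <- forward_model(W, Rxx)
  structure(list(weights = W, forward_model = fm, reliability = rho,
                 explained_reliability_fraction = expl[seq_len(n_components)],
                 rank_used = rank, Rxx = Rxx, Rxy = Rxy,
                 channel_names = epochs$channel_names),
            class = "rca_decomposition")
}

#' @export
print.rca_decomposition <- function(x, ...) {
  cat(sprintf("RCA decomposition: %d components (rank %d)\n",
              ncol(x$weights), x$rank_used))
  cat("  explained reliability:",
      paste0(sprintf("%.1f%%", 100 * x$explained_reliability_fraction),
             collapse = ", "), "\n")
  invisible(x)
}

#' Project epochs through component weights
#'
#' Per-sample weighted sum over electrodes. Where electrodes are missing,
#' the remaining weights are renormalised (by total absolute weight) so the
#' projection scale is preserved; samples with no usable electrode are
#' missing in the output.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param weights electrodes x components matrix.
#' @return trials x components x samples array.
#' @export
project_components <- function(epochs, weights) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  weights <- as.matrix(weights)
  E <- dim(epochs$data)[2]
  if (nrow(weights) != E) stop("weights must have one row per electrode")
  Tn <- dim(epochs$data)[1]; S <- dim(epochs$data)[3]
  C <- ncol(weights)
  out <- array(NA_real_, c(Tn, C, S))
  wa <- abs(weights)
  tot <- colSums(wa)
  for (tr in seq_len(Tn)) {
    X <- epochs$data[tr, , , drop = TRUE]
    M <- !is.na(X)
    if (all(M)) {
      out[tr, , ] <- crossprod(weights, X)
    } else {
      Xz <- X; Xz[!M] <- 0
      num <- crossprod(weights, Xz)              # C x S
      present <- crossprod(wa, M * 1)            # C x S absolute weight present
      fac <- ifelse(present > 0, tot / present, NA)
      out[tr, , ] <- num * fac
    }
  }
  out
}

#' Forward-model projection of spatial weights
#'
#' Converts spatial filter weights into interpretable activation
#' topographies: `A = R_xx W (W' R_xx W)^{-1}`. If `W' R_xx W` is singular,
#' a pseudo-inverse is used with a warning.
#'
#' @param weights electrodes x components matrix.
#' @param pooled_covariance the electrodes x electrodes data covariance
#'   (`R_xx` from [fit_rca()]).
#' @return electrodes x components topography matrix.
#' @export
forward_model <- function(weights, pooled_covariance) {
  weights <- as.matrix(weights)
  RW <- pooled_covariance %*% weights
  G <- crossprod(weights, RW)
  Ginv <- tryCatch(solve(G), error = function(e) {
    warning("W' R W is singular; using a pseudo-inverse")
    sv <- svd(G)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  RW %*% Ginv
}
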