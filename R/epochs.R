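#' EEG epoch container
#'
#' A trials x electrodes x samples array with latency, channel and
#' electrode-adjacency metadata. Missing values (censored samples, removed
#' electrodes) are encoded as `NA` throughout.
#'
#' @param data numeric array, trials x electrodes x samples (microvolts).
#' @param time_ms per-sample latency in ms (relative to the lock event),
#'   strictly increasing and uniform at `sample_rate`.
#' @param channel_names electrode labels.
#' @param neighbours named list: for each electrode, the integer indices of
#'   its adjacent electrodes; must be symmetric.
#' @param sample_rate sampling rate in Hz.
#' @param trial_index identifier per trial (survives every preprocessing
#'   op).
#' @param positions optional electrodes x 2 matrix of layout coordinates
#'   (used to order neighbours by distance during interpolation).
#' @param perimeter logical per electrode: on the net's perimeter?
#' @param locked `"response"` or `"stimulus"`.
#' @return an `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, time_ms, channel_names, neighbours,
                       sample_rate, trial_index = seq_len(dim(data)[1]),
                       positions = NULL,
                       perimeter = rep(FALSE, dim(data)[2]),
                       locked = c("response", "stimulus")) {
  locked <- match.arg(locked)
  stopifnot(length(dim(data)) == 3)
  E <- dim(data)[2]; S <- dim(data)[3]
  if (length(time_ms) != S) stop("time_ms length must match sample count")
  step <- diff(time_ms)
  if (any(step <= 0)) stop("time axis must be strictly increasing")
  if (max(abs(step - 1000 / sample_rate)) > 1e-6)
    stop("time axis not uniform at the stated sample rate")
  if (length(channel_names) != E) stop("channel_names length mismatch")
  if (length(neighbours) != E) stop("neighbours length mismatch")
  for (e in seq_len(E))
    for (nb in neighbours[[e]])
      if (!(e %in% neighbours[[nb]]))
        stop("neighbour adjacency is not symmetric (", e, " -> ", nb, ")")
  if (length(trial_index) != dim(data)[1]) stop("trial_index length mismatch")
  structure(list(data = data, time_ms = time_ms,
                 channel_names = channel_names, neighbours = neighbours,
                 sample_rate = sample_rate, trial_index = trial_index,
                 positions = positions, perimeter = perimeter,
                 locked = locked),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "EEG epochs: %d trials x %d electrodes x %d samples (%g Hz, %s-locked, %.1f..%.1f ms)\n",
    d[1], d[2], d[3], x$sample_rate, x$locked, min(x$time_ms),
    max(x$time_ms)))
  cat(sprintf("  missing: %.2f%% of samples\n", 100 * mean(is.na(x$data))))
  invisible(x)
}

#' Synthetic sensor-net layout
#'
#' Places electrodes on a sunflower-spiral disc and derives a symmetric
#' nearest-neighbour adjacency (an idealised stand-in for a geodesic net's
#' neighbour metadata; real nets should supply their own adjacency).
#' Electrodes in the outer radius band are marked as perimeter electrodes.
#'
#' @param n_electrodes number of electrodes.
#' @param n_neighbours neighbours per interior electrode before
#'   symmetrisation; default 6.
#' @return list with `positions` (n x 2), `neighbours`, `perimeter`,
#'   `channel_names`.
#' @export
make_net_layout <- function(n_electrodes, n_neighbours = 6) {
  i <- seq_len(n_electrodes)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_electrodes)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  perim <- r > stats::quantile(r, 0.85)
  D <- as.matrix(dist(pos))
  diag(D) <- Inf
  nb <- lapply(seq_len(n_electrodes), function(e) {
    kk <- if (perim[e]) 4 else n_neighbours
    order(D[e, ])[seq_len(kk)]
  })
  # symmetrise
  for (e in seq_len(n_electrodes))
    for (j in nb[[e]])
      if (!(e %in% nb[[j]])) nb[[j]] <- sort(c(nb[[j]], e))
  list(positions = pos, neighbours = nb, perimeter = perim,
       channel_names = sprintf("E%03d", i))
}

#' Write / read an epoch container
#'
#' Serialisation of the epoch container (and any fitted decomposition) uses
#' R-native serialisation; all tabular outputs elsewhere in the package are
#' plain CSV.
#'
#' @param epochs an `eeg_epochs` object.
#' @param path file path.
#' @return `read_epochs` returns the `eeg_epochs` object.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "eeg_epochs")) stop("file does not contain eeg_epochs")
  x
}
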