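#' Down-scale an epoch array to a declared channel subset
#'
#' Keeps only the channels of the declared subset of size `k`, in subset
#' order, leaving the data values untouched.  `k = 64` returns the input
#' unchanged (in montage order).
#'
#' @param epochs an [epoch_array] whose labels cover the montage.
#' @param montage a [build_montage()] result.
#' @param k target channel count: 64 or one of the declared subset sizes.
#' @return An [epoch_array] with `k` channels.
#' @export
select_channels <- function(epochs, montage, k) {
  stopifnot(inherits(epochs, "epoch_array"))
  labels <- montage_subset(montage, k)
  idx <- match(labels, epochs$labels)
  if (anyNA(idx)) stop("epoch array lacks channels: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  epoch_array(epochs$data[, , idx, drop = FALSE], fs = epochs$fs,
              t0 = epochs$t0, labels = labels)
}

#' Interpolation weights from a channel subset to the full montage
#'
#' For each channel of the full montage that is missing from the subset, the
#' weight row is an inverse geodesic-distance weighted average over the
#' `n_neighbors` nearest retained channels (weights sum to 1); retained
#' channels map to themselves.
#'
#' @param montage a [build_montage()] result.
#' @param subset_labels labels of the retained channels.
#' @param n_neighbors number of retained neighbours per missing channel.
#' @return A (full channels) x (subset channels) weight matrix.
#' @export
interp_weights <- function(montage, subset_labels, n_neighbors = 4) {
  stopifnot(inherits(montage, "sensor_montage"))
  subset_labels <- as.character(subset_labels)
  if (!length(subset_labels)) stop("subset must not be empty")
  if (!all(subset_labels %in% montage$labels)) {
    stop("subset labels must be part of the montage")
  }
  if (n_neighbors > length(subset_labels)) {
    stop("n_neighbors exceeds the subset size")
  }
  full <- montage$labels
  W <- matrix(0, length(full), length(subset_labels),
              dimnames = list(full, subset_labels))
  dist <- geodesic_dist(montage$positions,
                        montage$positions[subset_labels, , drop = FALSE])
  for (i in seq_along(full)) {
    j <- match(full[i], subset_labels)
    if (!is.na(j)) {
      W[i, j] <- 1
    } else {
      nb <- order(dist[i, ])[seq_len(n_neighbors)]
      w <- 1 / dist[i, nb]
      W[i, nb] <- w / sum(w)
    }
  }
  W
}

#' Interpolate a channel subset back to the full montage (LR data)
#'
#' Retained channels pass through unchanged; each missing channel is the
#' inverse-geodesic-distance weighted average of its nearest retained
#' channels.  This interpolated 64-channel signal is both the conventional
#' low-resolution baseline and the input of the super-resolution network.
#'
#' @param subset_epochs an [epoch_array] on a subset of montage channels.
#' @param montage a [build_montage()] result.
#' @param n_neighbors retained neighbours per missing channel; default 4,
#'   reduced automatically to the subset size when the subset is smaller.
#' @return An [epoch_array] with the full montage's channels, in montage
#'   order.
#' @export
interpolate_lr <- function(subset_epochs, montage, n_neighbors = 4) {
  stopifnot(inherits(subset_epochs, "epoch_array"))
  n_neighbors <- min(n_neighbors, length(subset_epochs$labels))
  W <- interp_weights(montage, subset_epochs$labels, n_neighbors)
  d <- dim(subset_epochs$data)
  flat <- matrix(subset_epochs$data, d[1L] * d[2L], d[3L])
  out <- flat %*% t(W)
  epoch_array(array(out, c(d[1L], d[2L], nrow(W))), fs = subset_epochs$fs,
              t0 = subset_epochs$t0, labels = montage$labels)
}
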