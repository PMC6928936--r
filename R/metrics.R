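#' Per-trial mean squared error against a reference
#'
#' Mean over time samples of the squared difference, averaged over channels,
#' giving one value per trial.  (The per-channel breakdown is available via
#' `by_channel = TRUE`.)
#'
#' @param reference,estimate [epoch_array]s of identical shape.
#' @param by_channel return a trials x channels matrix instead of the
#'   channel-averaged per-trial vector.
#' @return numeric vector (one MSE per trial), or a matrix.
#' @export
mse_epochs <- function(reference, estimate, by_channel = FALSE) {
  stopifnot(inherits(reference, "epoch_array"), inherits(estimate, "epoch_array"))
  if (!identical(dim(reference$data), dim(estimate$data))) {
    stop("epoch arrays must have identical shape")
  }
  sq <- (reference$data - estimate$data)^2
  m <- apply(sq, c(1L, 3L), mean)          # trials x channels
  if (by_channel) m else rowMeans(m)
}

#' Per-trial Pearson correlation against a reference
#'
#' Pearson coefficient between the reference and estimate with time and
#' channel samples pooled, one value per trial.
#'
#' @param reference,estimate [epoch_array]s of identical shape; each trial
#'   must be non-constant.
#' @return numeric vector in `[-1, 1]`, one value per trial.
#' @export
pearson_epochs <- function(reference, estimate) {
  stopifnot(inherits(reference, "epoch_array"), inherits(estimate, "epoch_array"))
  if (!identical(dim(reference$data), dim(estimate$data))) {
    stop("epoch arrays must have identical shape")
  }
  n_tr <- dim(reference$data)[1L]
  vapply(seq_len(n_tr), function(tr) {
    a <- as.vector(reference$data[tr, , ])
    b <- as.vector(estimate$data[tr, , ])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      stop("constant trial: correlation undefined")
    }
    stats::cor(a, b)
  }, numeric(1))
}

# voxels of `map` within roi_mm of a point (mm)
roi_voxels <- function(map, centre_mm, roi_mm) {
  d2 <- rowSums(sweep(map$grid$positions_mm, 2L, centre_mm, "-")^2)
  which(d2 <= roi_mm^2)
}

#' Source amplitude error between two normalized maps
#'
#' For each region of interest (a sphere around each reference peak, or
#' around supplied true source positions) the error is the absolute
#' difference of the maximum normalized power of the two maps inside the
#' region; the result is averaged over regions.
#'
#' @param map_ref,map_est normalized `source_map`s on the same grid.
#' @param roi_centres_mm optional matrix of region centres (defaults to the
#'   reference map's detected peaks).
#' @param roi_mm region radius in millimetres.
#' @return mean absolute amplitude error over regions.
#' @export
amplitude_error <- function(map_ref, map_est, roi_centres_mm = NULL,
                            roi_mm = 20) {
  stopifnot(inherits(map_ref, "source_map"), inherits(map_est, "source_map"))
  if (!map_ref$normalized || !map_est$normalized) {
    stop("maps must be normalized first (normalize_threshold_detect)")
  }
  if (is.null(roi_centres_mm)) {
    if (is.null(map_ref$peaks) || !nrow(map_ref$peaks$positions_mm)) {
      stop("reference map has no peaks and no roi_centres_mm given")
    }
    roi_centres_mm <- map_ref$peaks$positions_mm
  }
  roi_centres_mm <- matrix(roi_centres_mm, ncol = 3L)
  errs <- apply(roi_centres_mm, 1L, function(ctr) {
    vox <- roi_voxels(map_ref, ctr, roi_mm)
    if (!length(vox)) stop("empty region of interest")
    abs(max(map_ref$power[vox]) - max(map_est$power[vox]))
  })
  mean(errs)
}

#' Localization error between two source maps
#'
#' Euclidean distance (mm) between maximum-power voxel positions; with
#' several peaks the reference peaks are matched greedily (strongest first)
#' to the nearest unused estimate peak, and the matched distances are
#' averaged.
#'
#' @param map_ref,map_est `source_map`s with at least one detected peak each.
#' @return mean distance in millimetres.
#' @export
localization_error <- function(map_ref, map_est) {
  stopifnot(inherits(map_ref, "source_map"), inherits(map_est, "source_map"))
  pr <- map_ref$peaks; pe <- map_est$peaks
  if (is.null(pr) || !nrow(pr$positions_mm)) stop("reference map has no peaks")
  if (is.null(pe) || !nrow(pe$positions_mm)) stop("estimate map has no peaks")
  ref <- pr$positions_mm[order(pr$power, decreasing = TRUE), , drop = FALSE]
  est <- pe$positions_mm
  used <- rep(FALSE, nrow(est))
  dists <- numeric(0)
  for (i in seq_len(nrow(ref))) {
    if (all(used)) break
    dd <- sqrt(rowSums((est - matrix(ref[i, ], nrow(est), 3L, byrow = TRUE))^2))
    dd[used] <- Inf
    j <- which.min(dd)
    dists <- c(dists, dd[j])
    used[j] <- TRUE
  }
  mean(dists)
}

#' Focality of a thresholded source map
#'
#' Reciprocal of the number of voxels whose normalized power exceeds the
#' threshold; 1 means a single active voxel, smaller values mean more
#' smeared localization.
#'
#' @param map a normalized, thresholded `source_map`.
#' @return `1 / |active set|`.
#' @export
focality <- function(map) {
  stopifnot(inherits(map, "source_map"))
  if (is.null(map$active)) stop("map has not been thresholded")
  n <- sum(map$active)
  if (n == 0L) stop("no voxel exceeds the threshold; focality undefined")
  1 / n
}

#' Evoked-component specification
#'
#' @param name component name, `"N1"` or `"P2"`.
#' @param window search window in seconds post-stimulus; defaults are
#'   0.040-0.110 s for N1 and 0.110-0.220 s for P2.
#' @param polarity `"negative"` (N1) or `"positive"` (P2).
#' @return list of class `erp_component`.
#' @export
erp_component <- function(name = c("N1", "P2"), window = NULL,
                          polarity = NULL) {
  name <- match.arg(name)
  if (is.null(window)) window <- if (name == "N1") c(0.040, 0.110) else c(0.110, 0.220)
  if (is.null(polarity)) polarity <- if (name == "N1") "negative" else "positive"
  stopifnot(polarity %in% c("negative", "positive"), window[2L] > window[1L])
  structure(list(name = name, window = window, polarity = polarity),
            class = "erp_component")
}

#' Extract an evoked-component amplitude and latency
#'
#' On a trial-averaged epoch array, finds the extremum of the requested
#' polarity inside the component's search window at one channel.  Amplitude
#' is reported as a magnitude; latency in milliseconds post-stimulus.  A flat
#' zero signal yields amplitude 0 with latency at the window start.
#'
#' @param average a single-trial [epoch_array] (see [epoch_average()]).
#' @param component an [erp_component()].
#' @param channel channel label.
#' @return list with `amplitude`, `latency_ms`, `channel`, `name`.
#' @export
extract_erp <- function(average, component = erp_component("N1"),
                        channel = "CPz") {
  stopifnot(inherits(average, "epoch_array"), inherits(component, "erp_component"))
  if (dim(average$data)[1L] != 1L) {
    stop("'average' must be a single-trial (trial-averaged) epoch array")
  }
  ci <- match(channel, average$labels)
  if (is.na(ci)) stop("unknown channel ", channel)
  tt <- epoch_times(average)
  keep <- which(tt >= component$window[1L] & tt <= component$window[2L])
  if (!length(keep)) stop("component window lies outside the epoch")
  y <- average$data[1L, keep, ci]
  i <- if (component$polarity == "negative") which.min(y) else which.max(y)
  amp <- if (component$polarity == "negative") -y[i] else y[i]
  if (amp <= 0) {                       # no deflection of the right polarity
    amp <- max(amp, 0)
    i <- 1L
  }
  list(name = component$name, channel = channel, amplitude = amp,
       latency_ms = tt[keep[i]] * 1000)
}

#' Sensor-level component errors between two evoked responses
#'
#' Sums of absolute amplitude differences and of absolute latency
#' differences over the N1 and P2 components.
#'
#' @param hr_erp,d_erp lists with elements `N1` and `P2`, each an
#'   [extract_erp()] result.
#' @return list with `amplitude_error` and `latency_error_ms`.
#' @export
sensor_component_errors <- function(hr_erp, d_erp) {
  for (k in c("N1", "P2")) {
    if (is.null(hr_erp[[k]]) || is.null(d_erp[[k]])) {
      stop("both inputs must contain N1 and P2 components")
    }
  }
  amp <- sum(vapply(c("N1", "P2"), function(k)
    abs(hr_erp[[k]]$amplitude - d_erp[[k]]$amplitude), numeric(1)))
  lat <- sum(vapply(c("N1", "P2"), function(k)
    abs(hr_erp[[k]]$latency_ms - d_erp[[k]]$latency_ms), numeric(1)))
  list(amplitude_error = amp, latency_error_ms = lat)
}

#' Count mismatching detected sources between two maps
#'
#' A reference peak with no estimate peak within `match_mm` counts as one
#' error source, and vice versa; peaks are matched one-to-one with the
#' maximum-cardinality matching under the distance threshold (computed
#' exactly - peak sets are small).
#'
#' @param peaks_ref,peaks_est matrices of peak positions (mm), or
#'   `source_map`s whose peaks are used.
#' @param match_mm matching radius in millimetres.
#' @return integer error-source count.
#' @export
error_source_count <- function(peaks_ref, peaks_est, match_mm = 20) {
  get_pos <- function(p) {
    if (inherits(p, "source_map")) p$peaks$positions_mm
    else matrix(p, ncol = 3L)
  }
  a <- get_pos(peaks_ref); b <- get_pos(peaks_est)
  if (is.null(a)) a <- matrix(numeric(0), 0L, 3L)
  if (is.null(b)) b <- matrix(numeric(0), 0L, 3L)
  if (!nrow(a)) return(nrow(b))
  if (!nrow(b)) return(nrow(a))
  d <- sqrt(outer(rowSums(a^2), rep(1, nrow(b))) -
              2 * tcrossprod(a, b) + outer(rep(1, nrow(a)), rowSums(b^2)))
  ok <- d <= match_mm
  # maximum matching by exhaustive recursion over the reference peaks
  best <- function(i, used) {
    if (i > nrow(a)) return(0L)
    m <- best(i + 1L, used)                 # leave peak i unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      m <- max(m, 1L + best(i + 1L, used))
      used[j] <- FALSE
    }
    m
  }
  m <- best(1L, rep(FALSE, nrow(b)))
  (nrow(a) - m) + (nrow(b) - m)
}

#' Pointwise paired t-test between two epoch arrays
#'
#' Down-samples time by keeping every `downsample`-th sample, then runs a
#' paired t-test per kept sample and channel across trials, flagging
#' uncorrected p-values below `alpha`.  Sample pairs with zero within-pair
#' variance are flagged as degenerate and never significant.
#'
#' @param paired_a,paired_b [epoch_array]s with identical shape (paired
#'   trials).
#' @param downsample temporal down-sampling factor (default 8; a 666-sample
#'   epoch yields `ceiling(666 / 8) = 84` tested points).
#' @param alpha significance level (uncorrected; default 0.01).
#' @return list with `significant` (time x channel logical), `p` (matrix),
#'   `times` (s), `degenerate` (logical matrix).
#' @export
pointwise_ttest <- function(paired_a, paired_b, downsample = 8, alpha = 0.01) {
  stopifnot(inherits(paired_a, "epoch_array"), inherits(paired_b, "epoch_array"))
  if (!identical(dim(paired_a$data), dim(paired_b$data))) {
    stop("paired epoch arrays must have identical shape")
  }
  stopifnot(downsample >= 1)
  d <- dim(paired_a$data)
  keep <- seq(1L, d[2L], by = downsample)
  diffs <- paired_a$data[, keep, , drop = FALSE] -
    paired_b$data[, keep, , drop = FALSE]
  n <- d[1L]
  if (n < 2L) stop("need at least 2 trial pairs")
  mu <- apply(diffs, c(2L, 3L), mean)
  s <- apply(diffs, c(2L, 3L), stats::sd)
  degenerate <- s == 0
  tstat <- mu / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  p[degenerate] <- 1
  list(significant = p < alpha, p = p,
       times = epoch_times(paired_a)[keep], degenerate = degenerate)
}
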