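#' Regular scanning grid inside the brain shell
#'
#' Builds a regular lattice with the requested spacing (in millimetres),
#' centred on the head centre and restricted to voxels strictly inside the
#' brain shell.
#'
#' @param head a [head_model()]; the brain radius in mm is
#'   `shell_radii[1] * scalp_radius_mm`.
#' @param spacing_mm lattice spacing in millimetres (default 5).
#' @return An object of class `source_grid`: list with `positions_mm`
#'   (voxels x 3), `positions` (scalp-normalized units), `spacing_mm` and the
#'   integer lattice coordinates `ijk`.
#' @export
build_source_grid <- function(head = head_model(), spacing_mm = 5) {
  stopifnot(spacing_mm > 0)
  r_mm <- head$shell_radii[1L] * head$scalp_radius_mm
  if (spacing_mm > 2 * r_mm) stop("spacing exceeds the brain diameter")
  n <- floor(r_mm / spacing_mm)
  ax <- (-n):n
  g <- as.matrix(expand.grid(i = ax, j = ax, k = ax))
  pos_mm <- g * spacing_mm
  keep <- sqrt(rowSums(pos_mm^2)) < r_mm
  structure(list(positions_mm = pos_mm[keep, , drop = FALSE],
                 positions = pos_mm[keep, , drop = FALSE] / head$scalp_radius_mm,
                 ijk = g[keep, , drop = FALSE],
                 spacing_mm = spacing_mm, brain_radius_mm = r_mm),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d voxels, %g mm spacing, brain radius %g mm\n",
              nrow(x$positions_mm), x$spacing_mm, x$brain_radius_mm))
  invisible(x)
}

#' Sensor covariance with diagonal loading
#'
#' Sample covariance of the channels over a time window, pooled over trials,
#' plus diagonal loading of `loading * trace / n_channels` to keep the matrix
#' well conditioned for single-trial beamforming.
#'
#' @param epochs an [epoch_array].
#' @param window numeric `c(from, to)` in seconds (inclusive), or NULL for
#'   the whole epoch.
#' @param loading diagonal loading fraction (default 1e-3).
#' @param trials trial indices to pool over (default all).
#' @return channels x channels symmetric positive-definite matrix.
#' @export
compute_covariance <- function(epochs, window = NULL, loading = 1e-3,
                               trials = NULL) {
  stopifnot(inherits(epochs, "epoch_array"))
  tt <- epoch_times(epochs)
  keep <- if (is.null(window)) seq_along(tt)
          else which(tt >= window[1L] & tt <= window[2L])
  if (length(keep) < 2L) stop("covariance window must contain at least 2 samples")
  if (is.null(trials)) trials <- seq_len(dim(epochs$data)[1L])
  n_ch <- dim(epochs$data)[3L]
  x <- epochs$data[trials, keep, , drop = FALSE]
  x <- matrix(x, length(trials) * length(keep), n_ch)
  x <- sweep(x, 2L, colMeans(x), "-")
  C <- crossprod(x) / (nrow(x) - 1L)
  C + diag(loading * sum(diag(C)) / n_ch, n_ch)
}

# Smallest eigenvalue of many symmetric 3x3 matrices, vectorized
# (trigonometric closed form for the characteristic cubic).
sym3_min_eigen <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2 / 6, 0))
  out <- numeric(length(a11))
  nd <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(!nd)) out[!nd] <- q[!nd]            # (near-)scalar matrices
  if (any(nd)) {
    b11 <- (a11[nd] - q[nd]) / p[nd]; b22 <- (a22[nd] - q[nd]) / p[nd]
    b33 <- (a33[nd] - q[nd]) / p[nd]
    b12 <- a12[nd] / p[nd]; b13 <- a13[nd] / p[nd]; b23 <- a23[nd] / p[nd]
    # det(B) / 2 for the shifted, scaled matrix B
    r <- (b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
            b13 * (b12 * b23 - b22 * b13)) / 2
    r <- pmin(1, pmax(-1, r))
    phi <- acos(r) / 3
    # smallest eigenvalue uses phi + 2*pi/3
    out[nd] <- q[nd] + 2 * p[nd] * cos(phi + 2 * pi / 3)
  }
  out
}

#' Array-gain minimum-variance beamformer scan
#'
#' Scans every voxel of the grid with a minimum-variance spatial filter under
#' the array-gain constraint: the three leadfield columns of a voxel are
#' normalized to unit norm, and the voxel power is the maximum over source
#' orientations u of `1 / (u' L' C^-1 L u)` with `||u|| = 1`, i.e. the
#' reciprocal of the smallest eigenvalue of `L' C^-1 L`.  The returned map is
#' not yet normalized; see [normalize_threshold_detect()].
#'
#' @param cov channels x channels covariance (already loaded; see
#'   [compute_covariance()]).
#' @param leadfield a [compute_leadfield()] matrix whose positions match the
#'   grid (channels x 3 voxels).
#' @param grid a [build_source_grid()].
#' @return An object of class `source_map`: per-voxel power plus grid
#'   geometry.
#' @export
agmv_scan <- function(cov, leadfield, grid) {
  stopifnot(inherits(grid, "source_grid"))
  m <- nrow(grid$positions_mm)
  if (ncol(leadfield) != 3L * m) {
    stop("leadfield has ", ncol(leadfield) / 3, " voxels, grid has ", m)
  }
  ci <- tryCatch(solve(cov), error = function(e)
    stop("covariance is singular; increase diagonal loading"))
  L <- unclass(leadfield)
  cn <- sqrt(colSums(L^2))
  if (any(cn == 0)) stop("leadfield contains a zero column")
  L <- sweep(L, 2L, cn, "/")
  CL <- ci %*% L
  i1 <- seq.int(1L, 3L * m, by = 3L); i2 <- i1 + 1L; i3 <- i1 + 2L
  a11 <- colSums(L[, i1] * CL[, i1]); a22 <- colSums(L[, i2] * CL[, i2])
  a33 <- colSums(L[, i3] * CL[, i3]); a12 <- colSums(L[, i1] * CL[, i2])
  a13 <- colSums(L[, i1] * CL[, i3]); a23 <- colSums(L[, i2] * CL[, i3])
  lam <- sym3_min_eigen(a11, a22, a33, a12, a13, a23)
  structure(list(power = 1 / lam, grid = grid, normalized = FALSE,
                 threshold = NA_real_, active = NULL, peaks = NULL),
            class = "source_map")
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d voxels, %s", length(x$power),
              if (x$normalized) sprintf("normalized, threshold %g", x$threshold)
              else "unnormalized"))
  if (!is.null(x$peaks)) cat(sprintf(", %d peak(s)", nrow(x$peaks$positions_mm)))
  cat("\n")
  invisible(x)
}

#' Normalize a source map, threshold it and detect peaks
#'
#' Divides the voxel powers by their maximum (so the map maximum is exactly
#' 1), marks voxels above the threshold as active, finds local maxima over
#' the 26-neighbourhood within the active set, and merges peaks closer than
#' `min_separation_mm` (the weaker peak is absorbed by the stronger one).
#'
#' @param map a `source_map` from [agmv_scan()].
#' @param threshold normalized power threshold (0.3 for the simulation study,
#'   0.1 for evoked-potential data).
#' @param min_separation_mm minimum distance between distinct peaks.
#' @return The `source_map` with normalized powers, `active` logical vector
#'   and `peaks` (list with `positions_mm`, `power`, `voxel`).
#' @export
normalize_threshold_detect <- function(map, threshold = 0.3,
                                       min_separation_mm = 20) {
  stopifnot(inherits(map, "source_map"))
  mx <- max(map$power)
  if (!is.finite(mx) || mx <= 0) stop("source map has no positive power")
  p <- map$power / mx
  active <- p > threshold
  grid <- map$grid
  # index lattice for 26-neighbourhood lookups
  ijk <- grid$ijk
  off <- min(ijk) ; n_side <- max(ijk) - off + 1L
  lin <- function(m) (m[, 1L] - off) + n_side * ((m[, 2L] - off) +
                                                   n_side * (m[, 3L] - off)) + 1L
  lookup <- rep(NA_integer_, n_side^3)
  lookup[lin(ijk)] <- seq_len(nrow(ijk))
  nb_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb_off <- nb_off[rowSums(abs(nb_off)) > 0L, ]
  is_peak <- which(active)
  if (length(is_peak)) {
    keep <- vapply(is_peak, function(v) {
      nb <- sweep(nb_off, 2L, ijk[v, ], "+")
      ok <- nb[, 1L] >= off & nb[, 1L] <= off + n_side - 1L &
        nb[, 2L] >= off & nb[, 2L] <= off + n_side - 1L &
        nb[, 3L] >= off & nb[, 3L] <= off + n_side - 1L
      ni <- lookup[lin(nb[ok, , drop = FALSE])]
      ni <- ni[!is.na(ni)]
      all(p[v] >= p[ni])
    }, logical(1))
    is_peak <- is_peak[keep]
  }
  # merge peaks closer than min_separation_mm, strongest first
  if (length(is_peak) > 1L) {
    ord <- is_peak[order(p[is_peak], decreasing = TRUE)]
    kept <- integer()
    for (v in ord) {
      if (!length(kept)) { kept <- v; next }
      dd <- sqrt(rowSums((grid$positions_mm[kept, , drop = FALSE] -
                            matrix(grid$positions_mm[v, ], length(kept), 3L,
                                   byrow = TRUE))^2))
      if (all(dd >= min_separation_mm)) kept <- c(kept, v)
    }
    is_peak <- kept
  }
  map$power <- p
  map$normalized <- TRUE
  map$threshold <- threshold
  map$active <- active
  map$peaks <- list(positions_mm = grid$positions_mm[is_peak, , drop = FALSE],
                    power = p[is_peak], voxel = is_peak)
  map
}

#' Beamformer source map of selected trials
#'
#' Convenience pipeline: covariance over a window, array-gain
#' minimum-variance scan, normalization, thresholding and peak detection.
#'
#' @inheritParams compute_covariance
#' @inheritParams agmv_scan
#' @inheritParams normalize_threshold_detect
#' @return A normalized `source_map` with detected peaks.
#' @export
localize_epochs <- function(epochs, leadfield, grid, window = NULL,
                            loading = 1e-3, trials = NULL, threshold = 0.3,
                            min_separation_mm = 20) {
  C <- compute_covariance(epochs, window = window, loading = loading,
                          trials = trials)
  normalize_threshold_detect(agmv_scan(C, leadfield, grid),
                             threshold = threshold,
                             min_separation_mm = min_separation_mm)
}

#' Write a source map to CSV (and its peaks to JSON-like text)
#' @param map a normalized `source_map`.
#' @param path output CSV path; one row per voxel with columns
#'   `x_mm,y_mm,z_mm,power,active`.
#' @return `path`, invisibly.
#' @export
write_source_map <- function(map, path) {
  stopifnot(inherits(map, "source_map"))
  df <- data.frame(x_mm = map$grid$positions_mm[, 1L],
                   y_mm = map$grid$positions_mm[, 2L],
                   z_mm = map$grid$positions_mm[, 3L],
                   power = map$power,
                   active = if (is.null(map$active)) NA else map$active)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
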