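#' Three-concentric-shell spherical head model
#'
#' The volume conductor is three concentric spheres representing brain, skull
#' and scalp.  Radii are expressed relative to the scalp (outermost radius
#' fixed at 1); `scalp_radius_mm` converts model units to millimetres for
#' metric quantities such as localization error and grid spacing.
#'
#' @param shell_radii increasing radii of brain, skull and scalp shells on the
#'   scalp-normalized scale; the last entry must be 1.
#' @param conductivities relative conductivities of the three shells (the low
#'   middle value is the poorly conducting skull).
#' @param scalp_radius_mm physical scalp radius in millimetres.
#' @return An object of class `head_model`.
#' @examples
#' head_model()
#' @export
head_model <- function(shell_radii = c(0.87, 0.92, 1),
                       conductivities = c(1, 0.0125, 1),
                       scalp_radius_mm = 100) {
  stopifnot(length(shell_radii) == 3L, length(conductivities) == 3L)
  if (any(diff(shell_radii) <= 0)) stop("shell radii must be strictly increasing")
  if (abs(shell_radii[3L] - 1) > 1e-12) stop("outer (scalp) radius must be 1")
  if (any(conductivities <= 0)) stop("conductivities must be positive")
  if (scalp_radius_mm <= 0) stop("scalp_radius_mm must be positive")
  structure(list(shell_radii = as.numeric(shell_radii),
                 conductivities = as.numeric(conductivities),
                 scalp_radius_mm = scalp_radius_mm),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> radii %s, conductivities %s, scalp %g mm\n",
              paste(x$shell_radii, collapse = "/"),
              paste(x$conductivities, collapse = "/"),
              x$scalp_radius_mm))
  invisible(x)
}

#' Current dipole source
#'
#' @param position 3-vector, dipole location in scalp-normalized units;
#'   must be strictly inside the brain shell.
#' @param orientation 3-vector; normalized internally to a unit moment
#'   direction.
#' @param waveform numeric vector of moment magnitude over time (arbitrary
#'   amplitude units).
#' @param fs sampling rate of the waveform in Hz.
#' @param head the [head_model()] used to validate the position.
#' @return An object of class `dipole_source`.
#' @export
dipole_source <- function(position, orientation, waveform, fs = 512,
                          head = head_model()) {
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  stopifnot(length(position) == 3L, length(orientation) == 3L)
  if (sqrt(sum(position^2)) >= head$shell_radii[1L]) {
    stop("dipole must lie strictly inside the brain shell")
  }
  n <- sqrt(sum(orientation^2))
  if (n == 0) stop("orientation must be a nonzero vector")
  structure(list(position = position, orientation = orientation / n,
                 waveform = as.numeric(waveform), fs = fs),
            class = "dipole_source")
}

# Per-degree surface transfer coefficients g_n of the layered sphere.
#
# In the innermost shell the potential of harmonic degree n is
# A1 r^n + S r^-(n+1) with source coefficient S; continuity of potential and
# of radial current at both interfaces plus the insulating scalp boundary give
# a 5x5 linear system per degree.  g_n is the surface potential for S = 1.
# For equal conductivities g_n reduces to (2n+1)/n (homogeneous sphere).
shell_transfer_coefs <- function(head, n_terms) {
  r1 <- head$shell_radii[1L]; r2 <- head$shell_radii[2L]
  s1 <- head$conductivities[1L]; s2 <- head$conductivities[2L]
  s3 <- head$conductivities[3L]
  g <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    rn1 <- r1^n; rm1 <- r1^(-(n + 1))
    rn2 <- r2^n; rm2 <- r2^(-(n + 1))
    dn1 <- n * r1^(n - 1); dm1 <- -(n + 1) * r1^(-(n + 2))
    dn2 <- n * r2^(n - 1); dm2 <- -(n + 1) * r2^(-(n + 2))
    # unknowns: A1, A2, B2, A3, B3
    A <- rbind(
      c(rn1,      -rn1,      -rm1,      0,        0),        # V cont. at r1
      c(s1 * dn1, -s2 * dn1, -s2 * dm1, 0,        0),        # J cont. at r1
      c(0,         rn2,       rm2,     -rn2,     -rm2),      # V cont. at r2
      c(0,         s2 * dn2,  s2 * dm2, -s3 * dn2, -s3 * dm2), # J cont. at r2
      c(0,         0,         0,        n,       -(n + 1))   # insulated scalp
    )
    b <- c(-rm1, -s1 * dm1, 0, 0, 0)
    sol <- solve(A, b)
    g[n] <- sol[4L] + sol[5L]   # A3 * 1^n + B3 * 1^-(n+1)
  }
  g
}

# Legendre polynomials P_n(x) and derivatives P'_n(x) accumulated against
# per-degree weights.  Returns list(A = sum_n wP[n] * n * P_n,
# B = sum_n wB[n] * P'_n), evaluated elementwise over x (any shape).
legendre_accumulate <- function(x, wP, wB) {
  n_terms <- length(wP)
  Pm1 <- array(1, dim = dim(x) %||% length(x))   # P_0
  P <- x                                         # P_1
  dPm1 <- Pm1 * 0                                # P'_0
  dP <- Pm1                                      # P'_1 = 1
  A <- wP[1L] * 1 * P
  B <- wB[1L] * dP
  if (n_terms > 1L) {
    for (n in 1L:(n_terms - 1L)) {
      Pn1 <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
      dPn1 <- dPm1 + (2 * n + 1) * P
      Pm1 <- P; P <- Pn1
      dPm1 <- dP; dP <- dPn1
      A <- A + wP[n + 1L] * (n + 1) * P
      B <- B + wB[n + 1L] * dP
    }
  }
  list(A = A, B = B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Radial/tangential decomposition of a dipole moment at position p.
decompose_moment <- function(position, moment) {
  b <- sqrt(sum(position^2))
  if (b < 1e-12) {
    rhat <- c(0, 0, 1)        # degree-1 term is direction independent at b = 0
    b <- 0
  } else {
    rhat <- position / b
  }
  mr <- sum(moment * rhat)
  mtan <- moment - mr * rhat
  list(b = b, rhat = rhat, mr = mr, mtan = mtan)
}

#' Scalp potentials of a dipole in the three-shell sphere
#'
#' Evaluates the classical spherical-harmonic series solution for a current
#' dipole inside three concentric conducting shells (equivalent to a boundary
#' element solution on spherical geometry) at every sensor of a montage.  The
#' result is average referenced over the sensors and is linear in the dipole
#' moment.
#'
#' @param dipole a [dipole_source()]; the waveform is ignored here, only
#'   position and orientation are used, scaled by `moment`.
#' @param montage a [build_montage()] result.
#' @param head a [head_model()].
#' @param n_terms truncation order of the series (default 100).
#' @param moment dipole moment magnitude multiplying the unit orientation.
#' @return numeric vector of one potential per sensor (arbitrary units,
#'   average reference).
#' @export
three_shell_potential <- function(dipole, montage, head = head_model(),
                                  n_terms = 100, moment = 1) {
  stopifnot(inherits(dipole, "dipole_source"),
            inherits(montage, "sensor_montage"), n_terms >= 1)
  g <- shell_transfer_coefs(head, n_terms)
  v <- dipole_potential(dipole$position, dipole$orientation * moment,
                        montage$positions, head, g)
  v - mean(v)
}

# Core evaluation shared by three_shell_potential() and compute_leadfield():
# sensors is an n x 3 matrix of unit vectors, g the transfer coefficients.
dipole_potential <- function(position, moment, sensors, head, g) {
  dc <- decompose_moment(position, moment)
  n_terms <- length(g)
  bpow <- if (dc$b == 0) c(1, numeric(n_terms - 1L)) else dc$b^(0:(n_terms - 1L))
  x <- as.vector(sensors %*% dc$rhat)
  st <- as.vector(sensors %*% dc$mtan)
  acc <- legendre_accumulate(x, wP = g * bpow * dc$mr, wB = g * bpow)
  as.vector(acc$A + st * acc$B) / (4 * pi * head$conductivities[1L])
}

#' Leadfield matrix over source positions
#'
#' Potentials of unit dipoles along the three Cartesian axes at each source
#' position, evaluated with the three-shell series and average referenced.
#'
#' @param montage a [build_montage()] result.
#' @param head a [head_model()].
#' @param positions m x 3 matrix of source positions in scalp-normalized
#'   units, all strictly inside the brain shell.
#' @param n_terms series truncation order.
#' @return A sensors x (3 m) matrix of class `leadfield`; columns are grouped
#'   in triplets (x, y, z orientation) per position, with the positions kept
#'   as attribute `positions`.
#' @export
compute_leadfield <- function(montage, head = head_model(), positions,
                              n_terms = 100) {
  stopifnot(inherits(montage, "sensor_montage"))
  positions <- matrix(positions, ncol = 3L)
  rad <- sqrt(rowSums(positions^2))
  if (any(rad >= head$shell_radii[1L])) {
    stop("all source positions must lie strictly inside the brain shell")
  }
  g <- shell_transfer_coefs(head, n_terms)
  S <- montage$positions
  n_sens <- nrow(S); m <- nrow(positions)

  b <- rad
  rhat <- positions / ifelse(b < 1e-12, 1, b)
  rhat[b < 1e-12, ] <- rep(c(0, 0, 1), each = sum(b < 1e-12))
  X <- rhat %*% t(S)                       # m x sensors, cos(gamma)
  # accumulate A = sum g_n b^(n-1) n P_n and B = sum g_n b^(n-1) P'_n
  n_terms_eff <- length(g)
  bp <- matrix(1, m, 1)
  Pm1 <- matrix(1, m, n_sens); P <- X
  dPm1 <- 0 * X; dP <- Pm1
  A <- g[1L] * P                           # degree 1: n * P_1, b^0 = 1
  B <- g[1L] * dP
  if (n_terms_eff > 1L) {
    bpv <- rep(1, m)
    for (n in 1L:(n_terms_eff - 1L)) {
      bpv <- bpv * b                       # b^n
      Pn1 <- ((2 * n + 1) * X * P - n * Pm1) / (n + 1)
      dPn1 <- dPm1 + (2 * n + 1) * P
      Pm1 <- P; P <- Pn1
      dPm1 <- dP; dP <- dPn1
      A <- A + (g[n + 1L] * (n + 1) * bpv) * P
      B <- B + (g[n + 1L] * bpv) * dP
    }
  }
  scale <- 1 / (4 * pi * head$conductivities[1L])
  L <- matrix(0, n_sens, 3L * m)
  for (ax in 1:3) {
    e_r <- rhat[, ax]                      # (e . rhat) per position
    # sensor-dependent tangential projection: S[, ax] - (e.rhat) * cos(gamma)
    tang <- matrix(S[, ax], m, n_sens, byrow = TRUE) - e_r * X
    V <- scale * (e_r * A + tang * B)      # m x sensors
    V <- V - rowMeans(V)                   # average reference
    L[, seq.int(ax, by = 3L, length.out = m)] <- t(V)
  }
  structure(L, class = c("leadfield", "matrix"),
            positions = positions, labels = montage$labels)
}
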