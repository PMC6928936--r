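#' SNR grid used throughout the simulation study
#' @return numeric vector of signal-to-noise power ratios.
#' @export
snr_grid <- function() c(100, 50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01)

#' Default two-dipole configuration
#'
#' One dipole per hemisphere at (+/-0.62, 0, 0.48) scalp-normalized units
#' (radius 0.78, a typical cortical depth inside the 0.87 brain shell) with
#' tangential orientations, driven by amplitude-modulated 8 Hz and 12 Hz
#' sinusoids with distinct envelopes.  The two sources are far apart so that
#' they remain separable at low SNR, and superficial enough that their scalp
#' patterns are focal - sparse montages undersample them, which is what makes
#' the interpolation baseline imperfect.
#'
#' @param n_samples trial length in samples.
#' @param fs sampling rate in Hz.
#' @param head the [head_model()] used for validation.
#' @return list of two [dipole_source()] objects.
#' @export
default_dipoles <- function(n_samples = 512, fs = 512, head = head_model()) {
  tt <- (seq_len(n_samples) - 1L) / fs
  env1 <- exp(-((tt - 0.35) / 0.18)^2)
  env2 <- exp(-((tt - 0.6) / 0.22)^2)
  w1 <- env1 * sin(2 * pi * 8 * tt)
  w2 <- env2 * sin(2 * pi * 12 * tt)
  tang <- function(pos, v) {
    r <- pos / sqrt(sum(pos^2))
    u <- v - sum(v * r) * r
    u / sqrt(sum(u^2))
  }
  p1 <- c(-0.62, 0, 0.48); p2 <- c(0.62, 0, 0.48)
  list(
    dipole_source(p1, tang(p1, c(0, 1, 0.4)), w1, fs = fs, head = head),
    dipole_source(p2, tang(p2, c(0, -1, 0.4)), w2, fs = fs, head = head)
  )
}

#' Simulate noiseless trials from dipole sources
#'
#' Each trial is the superposition over dipoles of the sensor pattern of the
#' dipole (three-shell forward solution) times its waveform.  All trials are
#' identical before noise is added.  The output is scaled so that the mean
#' squared amplitude over all samples and channels is 1; with that convention
#' the sensor-level MSE of noisy data against the noiseless signal is 1/SNR.
#'
#' @param dipoles list of [dipole_source()] objects with equal-length
#'   waveforms and equal sampling rates.
#' @param montage a [build_montage()] result.
#' @param head a [head_model()].
#' @param n_trials number of (identical) trials to emit.
#' @param n_terms forward-series truncation.
#' @param normalize logical; scale to unit mean-square power (default TRUE).
#'   Skipped automatically for an all-zero signal.
#' @return An [epoch_array] of dimension n_trials x time x channels.
#' @export
simulate_clean_trials <- function(dipoles, montage, head = head_model(),
                                  n_trials = 1, n_terms = 100,
                                  normalize = TRUE) {
  stopifnot(length(dipoles) >= 1L, n_trials >= 1L)
  lens <- vapply(dipoles, function(d) length(d$waveform), integer(1))
  if (length(unique(lens)) != 1L) stop("dipole waveforms must have equal length")
  fs <- dipoles[[1L]]$fs
  n_t <- lens[1L]
  n_ch <- length(montage$labels)
  trial <- matrix(0, n_t, n_ch)
  for (d in dipoles) {
    pattern <- three_shell_potential(d, montage, head, n_terms = n_terms)
    trial <- trial + outer(d$waveform, pattern)
  }
  p <- mean(trial^2)
  if (normalize && p > 0) trial <- trial / sqrt(p)
  data <- aperm(array(trial, c(n_t, n_ch, n_trials)), c(3L, 1L, 2L))
  epoch_array(data, fs = fs, t0 = 0, labels = montage$labels)
}

# 1/f^alpha Gaussian noise, one column per channel, via spectral shaping of
# white noise; unit-variance columns on average.
pink_noise <- function(n_t, n_ch, alpha) {
  w <- matrix(stats::rnorm(n_t * n_ch), n_t, n_ch)
  if (alpha == 0) return(w)
  f <- seq_len(n_t %/% 2)
  shape <- numeric(n_t)
  shape[1L] <- 0
  shape[1L + f] <- f^(-alpha / 2)
  if (n_t %% 2 == 0) {
    shape[n_t %/% 2 + 1L] <- (n_t %/% 2)^(-alpha / 2)
    if (n_t > 2) shape[n_t:(n_t %/% 2 + 2L)] <- shape[2L:(n_t %/% 2)]
  } else {
    shape[n_t:(n_t %/% 2 + 2L)] <- shape[2L:(n_t %/% 2 + 1L)]
  }
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / n_t
  sweep(x, 2L, pmax(sqrt(colMeans(x^2)), .Machine$double.eps), "/")
}

#' Spatial mixing matrix for surrogate brain noise
#'
#' A random orthogonal matrix blended toward the identity; `smoothing = 0`
#' returns the identity (independent channels), `smoothing = 1` a fully
#' random orthogonal mixing.  Rows are renormalized so channel variances are
#' preserved on average.
#'
#' @param n_ch number of channels.
#' @param smoothing blend weight in `[0, 1]`.
#' @return n_ch x n_ch mixing matrix.
#' @export
spatial_mixing_matrix <- function(n_ch, smoothing = 0.5) {
  stopifnot(smoothing >= 0, smoothing <= 1)
  q <- qr.Q(qr(matrix(stats::rnorm(n_ch^2), n_ch)))
  m <- (1 - smoothing) * diag(n_ch) + smoothing * q
  m / sqrt(rowSums(m^2))
}

#' Add SNR-controlled noise to clean trials
#'
#' Draws an independent noise realization per trial (white Gaussian, or a
#' low-frequency-dominant 1/f^alpha surrogate for brain noise) and scales it
#' so that the empirical power ratio P(clean) / P(noise), taken over the whole
#' array, equals `snr` exactly.
#'
#' @param clean an [epoch_array] with nonzero power.
#' @param snr target signal-to-noise power ratio, > 0.
#' @param kind `"white_gaussian"` or `"brain_surrogate"`.
#' @param spectral_exponent alpha of the 1/f^alpha surrogate spectrum.
#' @param spatial_mixing optional channels x channels mixing matrix applied to
#'   the surrogate noise (see [spatial_mixing_matrix()]).
#' @param seed integer seed; every call is reproducible.
#' @return An [epoch_array] of the same shape as `clean`.
#' @export
add_noise <- function(clean, snr, kind = c("white_gaussian", "brain_surrogate"),
                      spectral_exponent = 1, spatial_mixing = NULL,
                      seed = 1L) {
  stopifnot(inherits(clean, "epoch_array"))
  kind <- match.arg(kind)
  if (!(is.numeric(snr) && length(snr) == 1L && snr > 0)) {
    stop("'snr' must be a single positive number")
  }
  p_clean <- mean(clean$data^2)
  if (p_clean == 0) stop("clean input has zero power")
  d <- dim(clean$data)
  set.seed(seed)
  noise <- array(0, d)
  for (tr in seq_len(d[1L])) {
    nz <- switch(kind,
      white_gaussian = matrix(stats::rnorm(d[2L] * d[3L]), d[2L], d[3L]),
      brain_surrogate = pink_noise(d[2L], d[3L], spectral_exponent))
    if (!is.null(spatial_mixing)) nz <- nz %*% t(spatial_mixing)
    noise[tr, , ] <- nz
  }
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_clean / (snr * p_noise))
  epoch_array(clean$data + noise, fs = clean$fs, t0 = clean$t0,
              labels = clean$labels)
}
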