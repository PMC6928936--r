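#' Default component specification for the synthetic auditory evoked
#' potential
#'
#' The N1 lobe is a negative Gaussian pulse peaking around 70 ms
#' (width sigma 15 ms) and the P2 lobe a positive pulse around 140 ms
#' (sigma 25 ms); amplitudes are expressed relative to each other so that
#' the vertex-channel trial average reaches evoked-potential-like magnitudes.
#'
#' @param n1_latency,p2_latency component peak times in seconds.
#' @param n1_sigma,p2_sigma Gaussian widths in seconds.
#' @param n1_amp,p2_amp relative lobe amplitudes (positive numbers; the N1
#'   lobe enters with a negative sign).
#' @param hemi_latency_offset extra latency (s) of the right-hemisphere
#'   source relative to the left.  Bilateral auditory responses are only
#'   partially synchronous; fully coherent sources would be inseparable for
#'   a minimum-variance beamformer.
#' @param latency_jitter_sd per-trial, per-hemisphere latency jitter (s).
#' @param amp_jitter_sd per-trial log-normal amplitude jitter (sd of log).
#' @return list used by [gen_aep_trials()].
#' @export
aep_components <- function(n1_latency = 0.070, p2_latency = 0.140,
                           n1_sigma = 0.015, p2_sigma = 0.025,
                           n1_amp = 1, p2_amp = 1.1,
                           hemi_latency_offset = 0.012,
                           latency_jitter_sd = 0.003,
                           amp_jitter_sd = 0.1) {
  stopifnot(n1_latency > 0, p2_latency > n1_latency, p2_latency < 1)
  list(n1_latency = n1_latency, p2_latency = p2_latency,
       n1_sigma = n1_sigma, p2_sigma = p2_sigma,
       n1_amp = n1_amp, p2_amp = p2_amp,
       hemi_latency_offset = hemi_latency_offset,
       latency_jitter_sd = latency_jitter_sd, amp_jitter_sd = amp_jitter_sd)
}

#' Generate synthetic auditory-evoked-potential trials
#'
#' Emulates an auditory evoked-potential recording: trials of 666 samples at
#' 512 Hz spanning -300 to 1000 ms, driven by two dipoles at bilateral
#' temporal positions whose biphasic waveform carries the N1 (negative) and
#' P2 (positive) lobes, with per-trial latency and amplitude jitter.  The
#' pre-stimulus interval contains noise only.  Low-frequency-dominant
#' surrogate brain noise is scaled so that the estimated SNR of the trial
#' set - post-stimulus power divided by pre-stimulus power - hits
#' `target_snr`.
#'
#' @param montage a [build_montage()] result.
#' @param head a [head_model()].
#' @param n_trials number of trials (932 emulates the reference recording).
#' @param components an [aep_components()] list.
#' @param target_snr estimated SNR (post/pre power ratio) of single trials;
#'   must exceed 1.  Default 1.2.
#' @param n_samples,fs,t0 epoch geometry; defaults 666 samples, 512 Hz,
#'   -0.3 s.
#' @param cpz_amplitude scale of the noiseless trial-average N1 magnitude at
#'   the CPz channel (arbitrary microvolt-like units).
#' @param spectral_exponent alpha of the 1/f^alpha noise.
#' @param seed integer seed.
#' @return list with elements `clean` and `noisy` ([epoch_array]s of
#'   identical shape), and `truth` (generator ground truth: dipole positions
#'   in scalp-normalized units and mm, component latencies, per-trial jitter
#'   draws).
#' @export
gen_aep_trials <- function(montage, head = head_model(), n_trials = 932,
                           components = aep_components(), target_snr = 1.2,
                           n_samples = 666, fs = 512, t0 = -0.3,
                           cpz_amplitude = 5, spectral_exponent = 1,
                           seed = 1L) {
  stopifnot(inherits(montage, "sensor_montage"), n_trials >= 1)
  if (target_snr <= 1) stop("target_snr must exceed 1 (post = signal + noise)")
  if (components$n1_latency > (n_samples - 1) / fs + t0 ||
      components$p2_latency > (n_samples - 1) / fs + t0) {
    stop("component latencies must lie inside the epoch")
  }
  tt <- t0 + (seq_len(n_samples) - 1L) / fs
  # bilateral temporal dipoles, tangential orientation pointing superior
  dip_pos <- rbind(c(-0.60, -0.15, 0.10), c(0.60, -0.15, 0.10))
  dip_ori <- rbind(c(0.15, 0, 1), c(-0.15, 0, 1))
  dip_ori <- dip_ori / sqrt(rowSums(dip_ori^2))
  patterns <- sapply(1:2, function(i) {
    d <- dipole_source(dip_pos[i, ], dip_ori[i, ], numeric(n_samples),
                       fs = fs, head = head)
    three_shell_potential(d, montage, head)
  })                                        # channels x 2

  set.seed(seed)
  # independent per-trial jitters for each (component, hemisphere) pair
  lat_jit <- array(stats::rnorm(n_trials * 4, 0, components$latency_jitter_sd),
                   c(n_trials, 2L, 2L))     # trial x component x hemisphere
  amp_jit <- array(exp(stats::rnorm(n_trials * 4, 0, components$amp_jitter_sd)),
                   c(n_trials, 2L, 2L))
  lobe <- function(lat, sig) exp(-((tt - lat)^2) / (2 * sig^2)) * (tt >= 0)
  n_ch <- length(montage$labels)
  clean <- array(0, c(n_trials, n_samples, n_ch))
  hemi_off <- c(0, components$hemi_latency_offset)
  for (tr in seq_len(n_trials)) {
    for (h in 1:2) {
      w <- -components$n1_amp * amp_jit[tr, 1L, h] *
        lobe(components$n1_latency + hemi_off[h] + lat_jit[tr, 1L, h],
             components$n1_sigma) +
        components$p2_amp * amp_jit[tr, 2L, h] *
        lobe(components$p2_latency + hemi_off[h] + lat_jit[tr, 2L, h],
             components$p2_sigma)
      clean[tr, , ] <- clean[tr, , ] + outer(w, patterns[, h])
    }
  }
  # scale so the noiseless trial-average N1 magnitude at CPz is cpz_amplitude
  cpz <- match("CPz", montage$labels)
  avg_cpz <- colMeans(matrix(clean[, , cpz], n_trials, n_samples))
  n1_mag <- max(0 - avg_cpz[tt >= 0.04 & tt <= 0.11])
  if (n1_mag > 0) clean <- clean * (cpz_amplitude / n1_mag)

  post <- tt >= 0
  p_signal <- mean(clean[, post, ]^2)
  # noise power such that (P_sig + P_noise) / P_noise = target_snr
  p_noise <- p_signal / (target_snr - 1)
  noise <- array(0, dim(clean))
  for (tr in seq_len(n_trials)) {
    noise[tr, , ] <- pink_noise(n_samples, n_ch, spectral_exponent)
  }
  noise <- noise * sqrt(p_noise / mean(noise[, post, ]^2))
  clean_ep <- epoch_array(clean, fs = fs, t0 = t0, labels = montage$labels)
  noisy_ep <- epoch_array(clean + noise, fs = fs, t0 = t0,
                          labels = montage$labels)
  list(clean = clean_ep, noisy = noisy_ep,
       truth = list(dipole_positions = dip_pos,
                    dipole_positions_mm = dip_pos * head$scalp_radius_mm,
                    dipole_orientations = dip_ori,
                    components = components, latency_jitter = lat_jit,
                    amplitude_jitter = amp_jit, target_snr = target_snr))
}

#' Estimated SNR of an epoch array with a pre-stimulus baseline
#'
#' Power of the post-stimulus interval (t >= 0) divided by power of the
#' pre-stimulus interval (t < 0), pooled over trials and channels.
#'
#' @param epochs an [epoch_array] with `t0 < 0`.
#' @return estimated signal-to-noise power ratio.
#' @export
estimate_snr <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_array"))
  tt <- epoch_times(epochs)
  if (!any(tt < 0)) stop("epochs have no pre-stimulus interval")
  mean(epochs$data[, tt >= 0, ]^2) / mean(epochs$data[, tt < 0, ]^2)
}
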