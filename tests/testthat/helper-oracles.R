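# Independent brute-force oracles used across the suite.  These deliberately
# re-derive each quantity with the most literal implementation available
# (nested loops, textbook formulas) and never call the code paths they check.

# Textbook series solution for a dipole in a homogeneous conducting sphere of
# radius 1 with insulating boundary, evaluated at unit-sphere sensors:
# V = 1/(4 pi sigma) * sum_n (2n+1)/n * b^(n-1) [n m_r P_n + m_t P_n^1 cos(phi)]
oracle_homogeneous_potential <- function(pos, mom, sensors, sigma = 1,
                                         n_terms = 100) {
  b <- sqrt(sum(pos^2))
  rh <- if (b < 1e-12) c(0, 0, 1) else pos / b
  mr <- sum(mom * rh)
  mt <- mom - mr * rh
  x <- as.vector(sensors %*% rh)
  st <- as.vector(sensors %*% mt)       # = |mt| sin(gamma) cos(phi) / sin(gamma)
  v <- numeric(nrow(sensors))
  for (i in seq_len(nrow(sensors))) {
    P <- numeric(n_terms + 1L); dP <- numeric(n_terms + 1L)
    P[1L] <- 1; P[2L] <- x[i]; dP[2L] <- 1
    if (n_terms >= 2) {
      for (k in 2:n_terms) {
        P[k + 1L] <- ((2 * k - 1) * x[i] * P[k] - (k - 1) * P[k - 1L]) / k
        dP[k + 1L] <- dP[k - 1L] + (2 * k - 1) * P[k]
      }
    }
    vi <- 0
    for (n in 1:n_terms) {
      bp <- if (n == 1) 1 else b^(n - 1)
      vi <- vi + (2 * n + 1) / n * bp * (n * mr * P[n + 1L] + st[i] * dP[n + 1L])
    }
    v[i] <- vi / (4 * pi * sigma)
  }
  v - mean(v)
}

# Literal nested-loop 2-D convolution with "same" zero padding, tensors
# (C, W, T, B), kernel (kt, kw, Cin, Cout).
oracle_conv2d <- function(x, k, bias, s) {
  d <- dim(x); kt <- dim(k)[1L]; kw <- dim(k)[2L]; Cout <- dim(k)[4L]
  W <- d[2L]; Tn <- d[3L]; B <- d[4L]
  pt <- (kt - 1) / 2; pw <- (kw - 1) / 2
  Wo <- ceiling(W / s); To <- ceiling(Tn / s)
  y <- array(0, c(Cout, Wo, To, B))
  for (b in 1:B) for (to in 1:To) for (wo in 1:Wo) for (co in 1:Cout) {
    acc <- bias[co]
    for (dt in 1:kt) for (dw in 1:kw) {
      ti <- s * (to - 1) + dt - pt
      wi <- s * (wo - 1) + dw - pw
      if (ti >= 1 && ti <= Tn && wi >= 1 && wi <= W) {
        acc <- acc + sum(x[, wi, ti, b] * k[dt, dw, , co])
      }
    }
    y[co, wo, to, b] <- acc
  }
  y
}

# Brute-force per-trial metrics (double loops over samples/channels).
oracle_mse <- function(ref, est) {
  d <- dim(ref$data)
  out <- numeric(d[1L])
  for (tr in seq_len(d[1L])) {
    acc <- 0
    for (ch in seq_len(d[3L])) {
      s <- 0
      for (t in seq_len(d[2L])) s <- s + (ref$data[tr, t, ch] - est$data[tr, t, ch])^2
      acc <- acc + s / d[2L]
    }
    out[tr] <- acc / d[3L]
  }
  out
}

oracle_pearson <- function(ref, est) {
  d <- dim(ref$data)
  out <- numeric(d[1L])
  for (tr in seq_len(d[1L])) {
    a <- as.vector(ref$data[tr, , ]); b <- as.vector(est$data[tr, , ])
    ca <- a - mean(a); cb <- b - mean(b)
    out[tr] <- sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
  }
  out
}

oracle_covariance <- function(x) {   # x: samples x channels
  n <- nrow(x); p <- ncol(x)
  mu <- colSums(x) / n
  C <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    C[i, j] <- sum((x[, i] - mu[i]) * (x[, j] - mu[j])) / (n - 1)
  }
  C
}

# Fixtures shared across files (built once per test run).
test_montage <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_montage()
    val
  }
})

test_head <- function() head_model()

# Small clean + noisy dataset for mid-weight tests.
make_small_dataset <- function(n_trials = 6, snr = 5, seed = 3L,
                               n_samples = 128) {
  mon <- test_montage(); hm <- test_head()
  dip <- default_dipoles(n_samples = n_samples, head = hm)
  clean <- simulate_clean_trials(dip, mon, hm, n_trials = n_trials)
  noisy <- add_noise(clean, snr, seed = seed)
  list(montage = mon, head = hm, clean = clean, noisy = noisy)
}
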