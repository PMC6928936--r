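random_epoch_pair <- function(n_tr = 2, n_t = 7, n_ch = 3) {
  a <- epoch_array(array(rnorm(n_tr * n_t * n_ch), c(n_tr, n_t, n_ch)))
  b <- epoch_array(array(rnorm(n_tr * n_t * n_ch), c(n_tr, n_t, n_ch)))
  list(a = a, b = b)
}

test_that("MSE: identity, offset, and brute-force equivalence", {
  p <- random_epoch_pair()
  expect_equal(mse_epochs(p$a, p$a), c(0, 0))
  shifted <- epoch_array(p$a$data + 1.5)
  expect_equal(mse_epochs(p$a, shifted), c(1.5^2, 1.5^2), tolerance = 1e-12)
  set.seed(30)
  for (i in 1:100) {
    p <- random_epoch_pair(sample(1:3, 1), sample(4:9, 1), sample(2:5, 1))
    expect_equal(mse_epochs(p$a, p$b), oracle_mse(p$a, p$b), tolerance = 1e-12)
  }
})

test_that("Pearson: bounds, sign, brute-force equivalence", {
  p <- random_epoch_pair()
  expect_equal(pearson_epochs(p$a, p$a), c(1, 1), tolerance = 1e-12)
  neg <- epoch_array(-p$a$data)
  expect_equal(pearson_epochs(p$a, neg), c(-1, -1), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:100) {
    p <- random_epoch_pair(sample(1:3, 1), sample(4:9, 1), sample(2:5, 1))
    r <- pearson_epochs(p$a, p$b)
    expect_true(all(r >= -1 & r <= 1))
    expect_equal(r, oracle_pearson(p$a, p$b), tolerance = 1e-12)
  }
  const <- epoch_array(array(1, c(1, 4, 2)))
  expect_error(pearson_epochs(const, const), "constant")
})

# hand-built source maps on a tiny lattice
toy_map <- function(power, ijk, spacing = 5) {
  grid <- structure(list(positions_mm = ijk * spacing,
                         positions = ijk * spacing / 100, ijk = ijk,
                         spacing_mm = spacing, brain_radius_mm = 87),
                    class = "source_grid")
  structure(list(power = power, grid = grid, normalized = FALSE,
                 threshold = NA_real_, active = NULL, peaks = NULL),
            class = "source_map")
}

test_that("amplitude error: identity, renormalization, hand computation", {
  ijk <- as.matrix(expand.grid(-1:1, -1:1, 0))
  m1 <- normalize_threshold_detect(toy_map(c(1, 2, 3, 4, 10, 4, 3, 2, 1), ijk),
                                   threshold = 0.2)
  expect_equal(amplitude_error(m1, m1), 0)
  m2 <- normalize_threshold_detect(toy_map(5 * c(1, 2, 3, 4, 10, 4, 3, 2, 1), ijk),
                                   threshold = 0.2)
  expect_equal(amplitude_error(m1, m2), 0, tolerance = 1e-12)
  m3 <- normalize_threshold_detect(toy_map(c(1, 2, 3, 4, 10, 4, 3, 6, 1), ijk),
                                   threshold = 0.2)
  # roi around the peak (0,0,0): max ref 1.0; max est within 20 mm = 1.0 too
  expect_equal(amplitude_error(m1, m3, roi_mm = 4), 0)
  # single-voxel roi at the (0, 5, 0) voxel: |2/10 - 6/10| = 0.4
  expect_equal(amplitude_error(m1, m3, roi_centres_mm = rbind(c(0, 5, 0)),
                               roi_mm = 1), abs(2 / 10 - 6 / 10))
})

test_that("localization error: zero, one lattice step, brute force", {
  ijk <- as.matrix(expand.grid(0:3, 0, 0))
  a <- normalize_threshold_detect(toy_map(c(10, 1, 1, 1), ijk), threshold = 0.5)
  expect_equal(localization_error(a, a), 0)
  b <- normalize_threshold_detect(toy_map(c(1, 10, 1, 1), ijk), threshold = 0.5)
  expect_equal(localization_error(a, b), 5)
  set.seed(32)
  for (i in 1:20) {
    pa <- matrix(runif(3, -50, 50), 1)
    pb <- matrix(runif(3, -50, 50), 1)
    ma <- a; ma$peaks <- list(positions_mm = pa, power = 1, voxel = 1L)
    mb <- a; mb$peaks <- list(positions_mm = pb, power = 1, voxel = 1L)
    expect_equal(localization_error(ma, mb), sqrt(sum((pa - pb)^2)),
                 tolerance = 1e-12)
  }
})

test_that("focality is the reciprocal active-voxel count", {
  ijk <- as.matrix(expand.grid(0:4, 0, 0))
  m <- normalize_threshold_detect(toy_map(c(10, 9, 8, 1, 1), ijk),
                                  threshold = 0.5)
  expect_equal(focality(m), 1 / 3)
  single <- normalize_threshold_detect(toy_map(c(10, 1, 1, 1, 1), ijk),
                                       threshold = 0.5)
  expect_equal(focality(single), 1)
  expect_equal(single$peaks$power, 1)       # normalized max is exactly 1
  # focality shrinks (count grows) as the threshold drops
  counts <- sapply(c(0.95, 0.5, 0.05), function(th)
    sum(normalize_threshold_detect(toy_map(c(10, 9, 8, 1, 1), ijk), th)$active))
  expect_true(all(diff(counts) >= 0))
})

test_that("ERP extraction finds injected components exactly", {
  n_t <- 666; fs <- 512; t0 <- -0.3
  tt <- t0 + (0:(n_t - 1)) / fs
  y <- matrix(0, n_t, 2)
  i70 <- which.min(abs(tt - 0.070)); i140 <- which.min(abs(tt - 0.140))
  y[i70, 1] <- -5; y[i140, 1] <- 3.5
  avg <- epoch_array(array(y, c(1, n_t, 2)), fs = fs, t0 = t0,
                     labels = c("CPz", "AFz"))
  n1 <- extract_erp(avg, erp_component("N1"), "CPz")
  p2 <- extract_erp(avg, erp_component("P2"), "CPz")
  expect_equal(n1$amplitude, 5)
  expect_equal(n1$latency_ms, tt[i70] * 1000)
  expect_equal(p2$amplitude, 3.5)
  expect_equal(p2$latency_ms, tt[i140] * 1000)
  # flat signal: documented degenerate behaviour
  flat <- extract_erp(avg, erp_component("N1"), "AFz")
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$latency_ms, epoch_times(avg)[min(which(tt >= 0.040))] * 1000)
})

test_that("component errors sum absolute differences over N1 and P2", {
  hr <- list(N1 = list(amplitude = 5, latency_ms = 66),
             P2 = list(amplitude = 6.1, latency_ms = 139))
  d <- list(N1 = list(amplitude = 4.5, latency_ms = 70),
            P2 = list(amplitude = 4.8, latency_ms = 145))
  err <- sensor_component_errors(hr, d)
  expect_equal(err$latency_error_ms, 4 + 6)
  expect_equal(err$amplitude_error, 0.5 + 1.3)
  expect_error(sensor_component_errors(hr["N1"], d), "N1 and P2")
})

test_that("error-source count is the matched symmetric difference", {
  A <- rbind(c(0, 0, 0), c(50, 0, 0))
  expect_equal(error_source_count(A, A), 0)
  B <- rbind(c(0, 0, 0), c(-50, 0, 0))       # C far from B
  expect_equal(error_source_count(A, B), 2)
  expect_equal(error_source_count(A, A + 5), 0)   # within 20 mm matching
  expect_equal(error_source_count(A, matrix(numeric(0), 0, 3)), 2)
  set.seed(33)
  for (i in 1:20) {
    a <- matrix(runif(3 * sample(0:3, 1), -80, 80), ncol = 3)
    b <- matrix(runif(3 * sample(0:3, 1), -80, 80), ncol = 3)
    # brute force: enumerate all one-to-one matchings under 20 mm
    best <- 0
    if (nrow(a) && nrow(b)) {
      d <- as.matrix(dist(rbind(a, b)))[seq_len(nrow(a)),
                                        nrow(a) + seq_len(nrow(b)), drop = FALSE]
      perms <- function(v) if (length(v) <= 1) list(v) else
        do.call(c, lapply(seq_along(v), function(i)
          lapply(perms(v[-i]), function(p) c(v[i], p))))
      k <- min(nrow(a), nrow(b))
      for (pa in perms(seq_len(nrow(a)))) {
        m <- sum(d[cbind(pa[seq_len(k)], seq_len(k))] <= 20)
        best <- max(best, m)
      }
      for (pb in perms(seq_len(nrow(b)))) {
        m <- sum(d[cbind(seq_len(k), pb[seq_len(k)])] <= 20)
        best <- max(best, m)
      }
    }
    expect_equal(error_source_count(a, b),
                 (nrow(a) - best) + (nrow(b) - best))
  }
})

test_that("pointwise t-test handles identical inputs and counts 84 points", {
  set.seed(34)
  a <- epoch_array(array(rnorm(6 * 666 * 2), c(6, 666, 2)), fs = 512, t0 = -0.3)
  r <- pointwise_ttest(a, a, downsample = 8, alpha = 0.01)
  expect_equal(nrow(r$significant), ceiling(666 / 8))
  expect_false(any(r$significant))
  expect_true(all(r$degenerate))
})

test_that("null calibration: about 1% of points flagged at alpha 0.01", {
  set.seed(35)
  a <- epoch_array(array(rnorm(20 * 512 * 8), c(20, 512, 8)))
  b <- epoch_array(array(rnorm(20 * 512 * 8), c(20, 512, 8)))
  r <- pointwise_ttest(a, b, downsample = 1, alpha = 0.01)
  n <- length(r$significant)
  rate <- mean(r$significant)
  ci <- qbinom(c(0.005, 0.995), n, 0.01) / n
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})
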