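test_that("source grid counts match brute-force lattice enumeration", {
  hm <- test_head()                        # brain radius 87 mm
  g <- build_source_grid(hm, spacing_mm = 10)
  ax <- seq(-90, 90, by = 10)
  cnt <- 0L
  for (x in ax) for (y in ax) for (z in ax) {
    if (sqrt(x^2 + y^2 + z^2) < 87) cnt <- cnt + 1L
  }
  expect_identical(nrow(g$positions_mm), cnt)
  expect_true(all(sqrt(rowSums(g$positions_mm^2)) < 87))
  # spacing equal to the brain diameter leaves only the origin
  g1 <- build_source_grid(hm, spacing_mm = 174)
  expect_identical(nrow(g1$positions_mm), 1L)
  expect_equal(g1$positions_mm[1L, ], c(i = 0, j = 0, k = 0))
  expect_error(build_source_grid(hm, spacing_mm = 200), "diameter")
})

test_that("default 5 mm grid has the expected scale", {
  g <- build_source_grid(test_head(), spacing_mm = 5)
  expect_equal(g$spacing_mm, 5)
  # ~ (4/3) pi 87^3 / 5^3 voxels, within lattice discretisation error
  expect_gt(nrow(g$positions_mm), 20000)
  expect_lt(nrow(g$positions_mm), 24000)
})

test_that("covariance matches the textbook estimator plus loading", {
  set.seed(50)
  x <- array(rnorm(3 * 40 * 5), c(3, 40, 5))
  ep <- epoch_array(x)
  lam <- 0.01
  C <- compute_covariance(ep, loading = lam)
  flat <- matrix(aperm(x, c(2, 1, 3)), 3 * 40, 5)  # samples pooled over trials
  C0 <- oracle_covariance(flat)
  expect_equal(C - diag(lam * sum(diag(C0)) / 5, 5), C0, tolerance = 1e-12)
  # white unit-variance data with many samples is close to the identity
  big <- epoch_array(array(rnorm(20000 * 4), c(1, 20000, 4)))
  Cb <- compute_covariance(big, loading = 0)
  expect_lt(max(abs(Cb - diag(4))), 0.06)
  # constant signal: only the (zero) loading term remains
  const <- epoch_array(array(5, c(1, 10, 3)))
  expect_equal(compute_covariance(const, loading = 2), matrix(0, 3, 3))
  expect_error(compute_covariance(ep, window = c(0, 0.001)), "2 samples")
})

test_that("smallest-eigenvalue kernel agrees with eigen()", {
  set.seed(51)
  n <- 200
  a <- matrix(rnorm(n * 6), n)
  a[1, ] <- c(2, 2, 2, 0, 0, 0)            # scalar matrix corner case
  lam <- eegsr:::sym3_min_eigen(a[, 1] + 3, a[, 2] + 3, a[, 3] + 3,
                                a[, 4], a[, 5], a[, 6])
  for (i in seq_len(n)) {
    M <- matrix(c(a[i, 1] + 3, a[i, 4], a[i, 5],
                  a[i, 4], a[i, 2] + 3, a[i, 6],
                  a[i, 5], a[i, 6], a[i, 3] + 3), 3, 3)
    expect_equal(lam[i], min(eigen(M, symmetric = TRUE)$values),
                 tolerance = 1e-8)
  }
})

test_that("identity covariance reproduces the per-voxel brute force", {
  mon <- test_montage(); hm <- test_head()
  g <- build_source_grid(hm, spacing_mm = 30)
  L <- compute_leadfield(mon, hm, g$positions, n_terms = 40)
  map <- agmv_scan(diag(64), L, g)
  Ln <- sweep(unclass(L), 2, sqrt(colSums(unclass(L)^2)), "/")
  for (v in seq_len(nrow(g$positions_mm))) {
    Lv <- Ln[, 3 * (v - 1) + 1:3]
    expect_equal(map$power[v],
                 1 / min(eigen(crossprod(Lv), symmetric = TRUE)$values),
                 tolerance = 1e-8)
  }
})

test_that("beamformer power map is invariant to covariance scaling", {
  ds <- make_small_dataset(n_trials = 2, n_samples = 64)
  g <- build_source_grid(ds$head, spacing_mm = 25)
  L <- compute_leadfield(ds$montage, ds$head, g$positions, n_terms = 40)
  C <- compute_covariance(ds$noisy)
  m1 <- normalize_threshold_detect(agmv_scan(C, L, g))
  m2 <- normalize_threshold_detect(agmv_scan(7.3 * C, L, g))
  expect_equal(m1$power, m2$power, tolerance = 1e-9)
  expect_identical(m1$peaks$voxel, m2$peaks$voxel)
  expect_equal(max(m1$power), 1)
})

test_that("a noiseless single dipole is localized within one grid step", {
  mon <- test_montage(); hm <- test_head()
  g <- build_source_grid(hm, spacing_mm = 10)
  L <- compute_leadfield(mon, hm, g$positions, n_terms = 60)
  set.seed(52)
  wave <- sin(2 * pi * 6 * (0:63) / 512) * exp(-((0:63) - 32)^2 / 300)
  for (i in 1:4) {
    repeat {
      pos <- runif(3, -0.7, 0.7)
      if (sqrt(sum(pos^2)) < 0.67) break    # >= 20 mm inside the brain surface
    }
    dip <- dipole_source(pos, rnorm(3), wave)
    ep <- simulate_clean_trials(list(dip), mon, hm, n_trials = 1, n_terms = 60)
    map <- localize_epochs(ep, L, g, loading = 1e-6)
    top <- g$positions_mm[which.max(map$power), ]
    err <- sqrt(sum((top - pos * hm$scalp_radius_mm)^2))
    expect_lte(err, 10)
  }
})

test_that("peak detection matches exhaustive local-maxima enumeration", {
  set.seed(53)
  ijk <- as.matrix(expand.grid(0:9, 0:9, 0:9))
  grid <- structure(list(positions_mm = ijk * 5, positions = ijk * 0.05,
                         ijk = ijk, spacing_mm = 5, brain_radius_mm = 87),
                    class = "source_grid")
  pw <- runif(1000)
  map <- structure(list(power = pw, grid = grid, normalized = FALSE,
                        threshold = NA_real_, active = NULL, peaks = NULL),
                   class = "source_map")
  out <- normalize_threshold_detect(map, threshold = 0.5,
                                    min_separation_mm = 0)
  p <- pw / max(pw)
  brute <- c()
  for (v in seq_len(1000)) {
    if (p[v] <= 0.5) next
    ismax <- TRUE
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- ijk[v, ] + c(dx, dy, dz)
      if (any(nb < 0) || any(nb > 9)) next
      w <- which(ijk[, 1] == nb[1] & ijk[, 2] == nb[2] & ijk[, 3] == nb[3])
      if (p[w] > p[v]) ismax <- FALSE
    }
    if (ismax) brute <- c(brute, v)
  }
  expect_setequal(out$peaks$voxel, brute)
  # active set equals the thresholded set and shrinks with the threshold
  expect_identical(out$active, p > 0.5)
  expect_true(all(normalize_threshold_detect(map, 0.8)$active <= out$active))
})

test_that("degenerate maps are rejected", {
  ijk <- as.matrix(expand.grid(0:1, 0, 0))
  grid <- structure(list(positions_mm = ijk * 5, positions = ijk * 0.05,
                         ijk = ijk, spacing_mm = 5, brain_radius_mm = 87),
                    class = "source_grid")
  map <- structure(list(power = c(0, 0), grid = grid, normalized = FALSE,
                        threshold = NA_real_, active = NULL, peaks = NULL),
                   class = "source_map")
  expect_error(normalize_threshold_detect(map), "positive")
})
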