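# The network is validated at reduced tensor sizes: the engine is size
# generic, so correctness at (T = 16..64, W = 8..64) transfers to the study
# geometry, which is exercised for shape and the headline claim in
# test-acceptance.R.

test_that("parameter count equals the hand-computed layer sum", {
  cfg <- sr_config()
  # 8 layers: sum(kh * kw * cin * cout + cout), computed independently
  by_hand <- (13 * 5 * 1 * 64 + 64) + 2 * (13 * 5 * 64 * 64 + 64) +
    3 * (13 * 9 * 64 * 64 + 64) + (13 * 5 * 64 * 64 + 64) +
    (7 * 1 * 64 * 1 + 1)
  expect_identical(sr_param_count(cfg), by_hand)
  m <- sr_network(cfg, c(512, 64))
  got <- sum(vapply(m$weights, length, numeric(1)))
  expect_identical(as.integer(got), as.integer(by_hand))
})

test_that("strided convolution matches the brute-force oracle", {
  set.seed(40)
  x <- array(rnorm(3 * 8 * 16 * 2), c(3, 8, 16, 2))
  k <- array(rnorm(5 * 3 * 3 * 4), c(5, 3, 3, 4))
  bias <- rnorm(4)
  for (s in c(1L, 2L)) {
    y <- eegsr:::cpp_conv2d_fwd(as.numeric(x), dim(x), as.numeric(k), dim(k),
                                bias, s)
    expect_equal(y, oracle_conv2d(x, k, bias, s), tolerance = 1e-4)
  }
})

test_that("backward passes agree with numerical directional derivatives", {
  set.seed(41)
  x <- array(rnorm(3 * 8 * 16 * 2), c(3, 8, 16, 2))
  k <- array(rnorm(5 * 3 * 3 * 4), c(5, 3, 3, 4))
  bias <- rnorm(4)
  s <- 2L
  y <- eegsr:::cpp_conv2d_fwd(as.numeric(x), dim(x), as.numeric(k), dim(k),
                              bias, s)
  dy <- array(rnorm(length(y)), dim(y))
  dx <- eegsr:::cpp_conv2d_bwd_data(as.numeric(dy), as.numeric(k), dim(k), s,
                                    dim(x))
  gw <- eegsr:::cpp_conv2d_bwd_weights(as.numeric(x), dim(x), as.numeric(dy),
                                       dim(k), s)
  loss <- function(xx, kk, bb) sum(oracle_conv2d(xx, kk, bb, s) * dy)
  h <- 1e-3
  dirx <- array(rnorm(length(x)), dim(x))
  dirk <- array(rnorm(length(k)), dim(k))
  num_x <- (loss(x + h * dirx, k, bias) - loss(x - h * dirx, k, bias)) / (2 * h)
  num_k <- (loss(x, k + h * dirk, bias) - loss(x, k - h * dirk, bias)) / (2 * h)
  expect_equal(sum(dx * dirx), num_x, tolerance = 1e-3)
  expect_equal(sum(gw$dk * dirk), num_k, tolerance = 1e-3)
  expect_equal(as.numeric(gw$db), apply(dy, 1, sum), tolerance = 1e-3)
})

test_that("transposed convolution is the exact adjoint of the strided conv", {
  set.seed(42)
  xs <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  k <- array(rnorm(5 * 3 * 6 * 4), c(5, 3, 6, 4))   # (kt,kw,Cout,Cin) storage
  yb <- eegsr:::cpp_tconv2d_fwd(as.numeric(xs), dim(xs), as.numeric(k), dim(k),
                                numeric(6), 2L, c(6L, 8L, 16L, 2L))
  z <- array(rnorm(6 * 8 * 16 * 2), c(6, 8, 16, 2))
  cz <- eegsr:::cpp_conv2d_fwd(as.numeric(z), dim(z), as.numeric(k), dim(k),
                               numeric(4), 2L)
  expect_equal(sum(cz * xs), sum(z * yb), tolerance = 1e-4)
})

test_that("whole-network gradient matches a numerical check", {
  set.seed(43)
  cfg <- sr_config(channels = 8, filters = 4)
  m <- sr_network(cfg, c(16, 8))
  x <- eegsr:::epochs_to_tensor(array(rnorm(2 * 16 * 8), c(2, 16, 8)), 1:2)
  tgt <- as.numeric(eegsr:::epochs_to_tensor(array(rnorm(2 * 16 * 8),
                                                   c(2, 16, 8)), 1:2))
  r <- eegsr:::cpp_srnet_pass(m$layers, m$weights, as.numeric(x), dim(x),
                              tgt, 16L, FALSE)
  h <- 1e-2
  for (l in c(1L, 4L, 8L)) {            # conv, transposed, output layers
    w2 <- m$weights
    dir <- array(rnorm(length(w2[[2 * l - 1]])), dim(w2[[2 * l - 1]]))
    w2[[2 * l - 1]] <- w2[[2 * l - 1]] + h * dir
    lp <- eegsr:::cpp_srnet_pass(m$layers, w2, as.numeric(x), dim(x), tgt,
                                 16L, FALSE)$loss
    w2[[2 * l - 1]] <- w2[[2 * l - 1]] - 2 * h * dir
    lm <- eegsr:::cpp_srnet_pass(m$layers, w2, as.numeric(x), dim(x), tgt,
                                 16L, FALSE)$loss
    num <- (lp - lm) / (2 * h)
    ana <- sum(r$grads[[2 * l - 1]] * dir)
    expect_equal(ana, num, tolerance = 5e-2)
  }
})

test_that("shape is preserved for 512- and 666-sample inputs", {
  m <- sr_network(input_shape = c(512, 64))
  x512 <- epoch_array(array(rnorm(512 * 64), c(1, 512, 64)))
  expect_equal(dim(predict(m, x512)$data), c(1L, 512L, 64L))
  x666 <- epoch_array(array(rnorm(666 * 64), c(1, 666, 64)), fs = 512,
                      t0 = -0.3)
  expect_equal(dim(predict(m, x666)$data), c(1L, 666L, 64L))
  expect_error(sr_network(input_shape = c(512, 32)), "channel count")
  expect_error(sr_network(input_shape = c(4, 64)), "at least 8")
  expect_error(predict(m, epoch_array(array(0, c(1, 16, 32)))), "channels")
})

test_that("with zero biases the network is a linear operator", {
  set.seed(44)
  m <- sr_network(input_shape = c(64, 64))
  for (i in seq(2, 16, 2)) m$weights[[i]][] <- 0
  a <- epoch_array(array(rnorm(64 * 64), c(1, 64, 64)))
  b <- epoch_array(array(rnorm(64 * 64), c(1, 64, 64)))
  comb <- epoch_array(2 * a$data - 3 * b$data)
  lhs <- predict(m, comb)$data
  rhs <- 2 * predict(m, a)$data - 3 * predict(m, b)$data
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-4)
  # doubling the input doubles the output
  expect_equal(predict(m, epoch_array(2 * a$data))$data / 2,
               predict(m, a)$data, tolerance = 1e-4)
})

test_that("a zero-weight final layer yields an all-zero output", {
  m <- sr_network(input_shape = c(64, 64))
  m$weights[[15]][] <- 0
  m$weights[[16]][] <- 0
  x <- epoch_array(array(rnorm(64 * 64), c(1, 64, 64)))
  expect_true(all(predict(m, x)$data == 0))
})

test_that("zero epochs returns He-initialised weights and empty history", {
  x <- epoch_array(array(rnorm(4 * 16 * 64), c(4, 16, 64)))
  m0 <- sr_fit(x, x, epochs = 0, seed = 9L)
  ref <- sr_network(input_shape = c(16, 64), seed = 9L)
  expect_identical(m0$weights, ref$weights)
  expect_equal(nrow(m0$history), 0L)
  expect_false(m0$trained)
})

test_that("training is deterministic given the seed", {
  set.seed(45)
  x <- epoch_array(array(rnorm(4 * 16 * 64), c(4, 16, 64)))
  y <- epoch_array(array(rnorm(4 * 16 * 64), c(4, 16, 64)))
  f1 <- sr_fit(x, y, epochs = 2, batch_size = 2, seed = 12L)
  f2 <- sr_fit(x, y, epochs = 2, batch_size = 2, seed = 12L)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("training on the identity task collapses the loss", {
  set.seed(46)
  base <- array(rnorm(16 * 64), c(16, 64))
  x <- epoch_array(aperm(array(base, c(16, 64, 8)) *
                           rep(seq(0.5, 1.5, length.out = 8),
                               each = 16 * 64), c(3, 1, 2)))
  f <- sr_fit(x, x, epochs = 40, batch_size = 2, seed = 13L)
  expect_lt(f$history$train_mse[40], 1e-3 * f$initial_mse)
})

test_that("the SNR-keyed epoch schedule matches the study protocol", {
  expect_identical(vapply(c(100, 50, 10, 5, 1, 0.5, 0.1, 0.05, 0.01),
                          sr_epoch_schedule, integer(1)),
                   c(40L, 40L, 80L, 80L, 150L, 200L, 200L, 500L, 500L))
  expect_identical(sr_epoch_schedule(data = "experimental"), 300L)
})

test_that("trial splits have the protocol sizes and are reproducible", {
  s1000 <- split_trials(1000, n_repeats = 5, seed = 2L)
  expect_length(s1000, 5L)
  for (sp in s1000) {
    expect_length(sp$train, 640L)
    expect_length(sp$val, 160L)
    expect_length(sp$test, 200L)
    expect_identical(sort(c(sp$train, sp$val, sp$test)), 1:1000)
  }
  sp932 <- split_trials(932, n_repeats = 1, seed = 2L)[[1L]]
  expect_length(sp932$train, 596L)
  expect_length(sp932$val, 150L)
  expect_length(sp932$test, 186L)
  expect_identical(split_trials(50, seed = 3L), split_trials(50, seed = 3L))
  expect_false(identical(split_trials(50, seed = 3L),
                         split_trials(50, seed = 4L)))
  expect_error(split_trials(4), "at least 5")
})

test_that("aligned-shape preconditions are enforced", {
  x <- epoch_array(array(rnorm(2 * 16 * 64), c(2, 16, 64)))
  y <- epoch_array(array(rnorm(2 * 24 * 64), c(2, 24, 64)))
  expect_error(sr_fit(x, y, epochs = 1), "identical shape")
})
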