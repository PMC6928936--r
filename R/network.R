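#' Configuration of the super-resolution network
#'
#' Fixes the encoder-decoder-integration architecture and its optimisation
#' hyper-parameters.  The defaults are the study configuration: an encoder of
#' three strided convolutions (13 x 5 kernels over time x channel, 64 filters,
#' stride 2 on both axes), a decoder of three transposed convolutions (13 x 9
#' kernels, 64 filters, stride-2 upsampling), and an integration head of a
#' 13 x 5 / 64-filter convolution followed by a 7 x 1 / 1-filter convolution,
#' both stride 1.  Activations are linear (y = x) everywhere, weights use He
#' initialisation, and training minimises elementwise mean squared error with
#' Adam at learning rate 5e-4.
#'
#' @param kernel_encoder,kernel_decoder,kernel_integration,kernel_output
#'   kernel sizes (time, channel) of the three stages.
#' @param filters number of filters in every internal layer.
#' @param lr Adam learning rate.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @param batch_size minibatch size (one epoch is one full pass over the
#'   training trials).
#' @param channels expected channel dimension of the input (64).
#' @param seed default seed for weight initialisation and trial shuffling.
#' @return A list of class `sr_config`.
#' @export
sr_config <- function(kernel_encoder = c(13, 5), kernel_decoder = c(13, 9),
                      kernel_integration = c(13, 5), kernel_output = c(7, 1),
                      filters = 64, lr = 5e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, batch_size = 32, channels = 64, seed = 1L) {
  structure(list(kernel_encoder = kernel_encoder,
                 kernel_decoder = kernel_decoder,
                 kernel_integration = kernel_integration,
                 kernel_output = kernel_output,
                 filters = filters, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, batch_size = batch_size, channels = channels,
                 seed = as.integer(seed)),
            class = "sr_config")
}

#' Training-length schedule keyed by SNR
#'
#' Maximum epoch counts used as the stopping criterion: 40 for SNR 100 and
#' 50, 80 for SNR 10 and 5, 150 for SNR 1, 200 for SNR 0.5 and 0.1, 500 for
#' SNR 0.05 and 0.01 on simulated data, and 300 for evoked-potential-like
#' experimental data.
#'
#' @param snr signal-to-noise power ratio of the simulated data (ignored for
#'   `data = "experimental"`).
#' @param data `"simulated"` or `"experimental"`.
#' @return integer epoch count.
#' @export
sr_epoch_schedule <- function(snr = NULL, data = c("simulated", "experimental")) {
  data <- match.arg(data)
  if (data == "experimental") return(300L)
  stopifnot(is.numeric(snr), length(snr) == 1L, snr > 0)
  if (snr >= 50) 40L
  else if (snr >= 5) 80L
  else if (snr >= 1) 150L
  else if (snr >= 0.1) 200L
  else 500L
}

# Layer table: one row per layer with columns
# (type [0 conv, 1 transposed], kt, kw, cin, cout, stride).
sr_layers <- function(config) {
  f <- config$filters
  ke <- config$kernel_encoder; kd <- config$kernel_decoder
  ki <- config$kernel_integration; ko <- config$kernel_output
  rbind(
    c(0L, ke[1], ke[2], 1L, f, 2L),
    c(0L, ke[1], ke[2], f, f, 2L),
    c(0L, ke[1], ke[2], f, f, 2L),
    c(1L, kd[1], kd[2], f, f, 2L),
    c(1L, kd[1], kd[2], f, f, 2L),
    c(1L, kd[1], kd[2], f, f, 2L),
    c(0L, ki[1], ki[2], f, f, 1L),
    c(0L, ko[1], ko[2], f, 1L, 1L)
  )
}

#' Parameter count of the network
#' @param config an [sr_config()].
#' @return total number of trainable weights and biases.
#' @export
sr_param_count <- function(config = sr_config()) {
  ly <- sr_layers(config)
  sum(ly[, 2] * ly[, 3] * ly[, 4] * ly[, 5] + ly[, 5])
}

# He-initialised weights: kernels ~ N(0, 2 / fan_in) with
# fan_in = kt * kw * cin; biases start at zero.  Transposed-layer kernels are
# stored as the kernel of the mirrored strided convolution, i.e. with
# dimension (kt, kw, cout, cin).
sr_init_weights <- function(layers) {
  w <- vector("list", 2L * nrow(layers))
  for (l in seq_len(nrow(layers))) {
    kt <- layers[l, 2]; kw <- layers[l, 3]
    cin <- layers[l, 4]; cout <- layers[l, 5]
    sd <- sqrt(2 / (kt * kw * cin))
    kdim <- if (layers[l, 1] == 1L) c(kt, kw, cout, cin) else c(kt, kw, cin, cout)
    w[[2L * l - 1L]] <- array(stats::rnorm(prod(kdim), sd = sd), kdim)
    w[[2L * l]] <- numeric(cout)
  }
  w
}

#' Build an (untrained) super-resolution network
#'
#' Instantiates the encoder-decoder-integration network for a given input
#' shape with He-initialised weights.  The network maps time x 64 inputs to
#' outputs of identical shape; time lengths that are not a multiple of 8 are
#' handled internally by reflection padding before the encoder and an exact
#' crop in the integration stage.
#'
#' @param config an [sr_config()].
#' @param input_shape integer vector (time, channels); channels must equal
#'   `config$channels` and time must be at least 8.
#' @param seed seed for the He initialisation (default from the config).
#' @return An object of class `sr_model` with `trained = FALSE`.
#' @examples
#' m <- sr_network(input_shape = c(512, 64))
#' m
#' @export
sr_network <- function(config = sr_config(), input_shape = c(512, 64),
                       seed = config$seed) {
  stopifnot(length(input_shape) == 2L)
  if (input_shape[2L] != config$channels) {
    stop("input channel count must be ", config$channels,
         " (override via sr_config(channels = ...))")
  }
  if (input_shape[1L] < 8L) stop("time dimension must be at least 8 samples")
  layers <- sr_layers(config)
  set.seed(seed)
  structure(list(config = config, layers = layers,
                 weights = sr_init_weights(layers),
                 input_shape = as.integer(input_shape),
                 history = data.frame(epoch = integer(), train_mse = numeric(),
                                      val_mse = numeric()),
                 epochs_trained = 0L, trained = FALSE, seed = as.integer(seed)),
            class = "sr_model")
}

# ---- tensor plumbing -------------------------------------------------------

# (trials, time, channels) -> network tensor (1, channels, time_padded, B),
# time reflection-padded at the end up to the next multiple of 8.
epochs_to_tensor <- function(data, trial_idx) {
  x0 <- aperm(data[trial_idx, , , drop = FALSE], c(3L, 2L, 1L))
  n_ch <- dim(x0)[1L]; n_t <- dim(x0)[2L]; b <- dim(x0)[3L]
  pad <- (8L - n_t %% 8L) %% 8L
  if (pad > 0L) {
    refl <- n_t - seq_len(pad)             # reflect tail without edge repeat
    x <- array(0, c(n_ch, n_t + pad, b))
    x[, seq_len(n_t), ] <- x0
    x[, n_t + seq_len(pad), ] <- x0[, refl, , drop = FALSE]
    x0 <- x
  }
  dim(x0) <- c(1L, dim(x0))
  x0
}

# network output tensor (1, channels, time, B) -> (trials, time, channels)
tensor_to_epochs <- function(y) {
  d <- dim(y)
  aperm(array(y, d[2:4]), c(3L, 2L, 1L))
}

sr_forward_chunk <- function(model, data, trial_idx) {
  x <- epochs_to_tensor(data, trial_idx)
  y <- cpp_srnet_fwd(model$layers, model$weights, as.numeric(x), dim(x))
  n_t <- dim(data)[2L]
  tensor_to_epochs(y[, , seq_len(n_t), , drop = FALSE])
}

# ---- fitting ---------------------------------------------------------------

#' Fit the super-resolution network
#'
#' Trains the encoder-decoder-integration network to map interpolated
#' low-resolution epochs to the corresponding high-resolution epochs by
#' minimising elementwise mean squared error with Adam.  Training runs for
#' exactly `epochs` passes over the training trials (the stopping criterion
#' is the fixed epoch budget; validation loss is recorded but never triggers
#' early stopping) and is fully reproducible from `seed` on a single thread.
#'
#' @param x an [epoch_array] of network inputs (interpolated LR, 64
#'   channels).
#' @param y an [epoch_array] of targets (HR), same shape as `x` and with
#'   aligned trials.
#' @param config an [sr_config()].
#' @param epochs number of training epochs; `0` returns the He-initialised
#'   network with an empty history.  Use [sr_epoch_schedule()] for the
#'   SNR-keyed study schedule.
#' @param batch_size minibatch size (default from the config).
#' @param validation optional list `list(x = , y = )` of epoch arrays used to
#'   record a validation MSE per epoch.
#' @param seed seed controlling initialisation and shuffling.
#' @param verbose print one line per epoch.
#' @return An object of class `sr_model` with the per-epoch loss history and
#'   `initial_mse`, the loss of the first batch at the He initialisation; see
#'   [predict.sr_model()] to apply the model.
#' @export
sr_fit <- function(x, y, config = sr_config(), epochs,
                   batch_size = config$batch_size, validation = NULL,
                   seed = config$seed, verbose = FALSE) {
  stopifnot(inherits(x, "epoch_array"), inherits(y, "epoch_array"))
  if (!identical(dim(x$data), dim(y$data))) {
    stop("input and target epoch arrays must have identical shape")
  }
  d <- dim(x$data)
  model <- sr_network(config, input_shape = d[c(2L, 3L)], seed = seed)
  if (epochs == 0L) {
    model$fs <- x$fs; model$t0 <- x$t0; model$labels <- x$labels
    return(model)
  }
  n_trials <- d[1L]
  n_t <- d[2L]
  state <- list(m = lapply(model$weights, function(w) w * 0),
                v = lapply(model$weights, function(w) w * 0), t = 0L)
  hist_train <- hist_val <- numeric(epochs)
  initial_mse <- NA_real_
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n_trials)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      tr <- batches[[bi]]
      xb <- epochs_to_tensor(x$data, tr)
      yb <- epochs_to_tensor(y$data, tr)[, , seq_len(n_t), , drop = FALSE]
      res <- cpp_srnet_pass(model$layers, model$weights, as.numeric(xb),
                            dim(xb), as.numeric(yb), n_t, FALSE)
      if (!is.finite(res$loss)) {
        stop(sprintf("non-finite training loss at epoch %d, batch %d", ep, bi))
      }
      # loss of the very first batch is evaluated at the He initialisation
      if (is.na(initial_mse)) initial_mse <- res$loss
      ep_loss <- ep_loss + res$loss * length(tr)
      state <- adam_update(model, res$grads, state, config)
      model$weights <- state$weights
    }
    hist_train[ep] <- ep_loss / n_trials
    hist_val[ep] <- if (!is.null(validation)) {
      sr_eval_mse(model, validation$x, validation$y)
    } else NA_real_
    if (verbose) {
      cat(sprintf("epoch %3d  train MSE %.6g  val MSE %.6g\n",
                  ep, hist_train[ep], hist_val[ep]))
    }
  }
  model$history <- data.frame(epoch = seq_len(epochs), train_mse = hist_train,
                              val_mse = hist_val)
  model$initial_mse <- initial_mse
  model$epochs_trained <- as.integer(epochs)
  model$trained <- TRUE
  model$fs <- x$fs; model$t0 <- x$t0; model$labels <- x$labels
  model
}

adam_update <- function(model, grads, state, config) {
  state$t <- state$t + 1L
  c1 <- 1 - config$beta1^state$t
  c2 <- 1 - config$beta2^state$t
  w <- model$weights
  for (i in seq_along(w)) {
    g <- grads[[i]]
    state$m[[i]] <- config$beta1 * state$m[[i]] + (1 - config$beta1) * g
    state$v[[i]] <- config$beta2 * state$v[[i]] + (1 - config$beta2) * g * g
    w[[i]] <- w[[i]] - config$lr * (state$m[[i]] / c1) /
      (sqrt(state$v[[i]] / c2) + config$eps)
  }
  state$weights <- w
  state
}

# Mean squared error of the model output against a target epoch array,
# evaluated in chunks.
sr_eval_mse <- function(model, x, y, chunk = 8L) {
  est <- predict(model, x, chunk = chunk)
  mean((est$data - y$data)^2)
}

#' Apply a fitted network to epochs
#'
#' @param object an `sr_model`.
#' @param newdata an [epoch_array] with the channel count the network was
#'   built for; any time length of at least 8 samples is accepted and the
#'   output keeps the input shape exactly.
#' @param chunk trials per forward pass.
#' @param ... unused.
#' @return An [epoch_array] of super-resolved epochs.
#' @export
predict.sr_model <- function(object, newdata, chunk = 8L, ...) {
  stopifnot(inherits(newdata, "epoch_array"))
  d <- dim(newdata$data)
  if (d[3L] != object$config$channels) {
    stop("epoch array has ", d[3L], " channels; network expects ",
         object$config$channels)
  }
  out <- array(0, d)
  starts <- seq(1L, d[1L], by = chunk)
  for (s in starts) {
    tr <- s:min(s + chunk - 1L, d[1L])
    out[tr, , ] <- sr_forward_chunk(object, newdata$data, tr)
  }
  if (!all(is.finite(out))) stop("network produced non-finite output")
  epoch_array(out, fs = newdata$fs, t0 = newdata$t0, labels = newdata$labels)
}

#' Apply a trained super-resolution network (convenience wrapper)
#' @param model an `sr_model` (see [sr_fit()]).
#' @param lr_epochs interpolated low-resolution [epoch_array].
#' @return super-resolved [epoch_array]; identical to
#'   `predict(model, lr_epochs)`.
#' @export
apply_sr <- function(model, lr_epochs) predict(model, lr_epochs)

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> %s, %d layers, %s parameters\n",
              if (x$trained) sprintf("trained %d epochs", x$epochs_trained)
              else "untrained (He init)",
              nrow(x$layers), format(sr_param_count(x$config), big.mark = ",")))
  if (x$trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train MSE %.5g", last$train_mse))
    if (is.finite(last$val_mse)) cat(sprintf(", val MSE %.5g", last$val_mse))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.sr_model <- function(object, ...) {
  ly <- object$layers
  stage <- c("encoder", "encoder", "encoder", "decoder", "decoder", "decoder",
             "integration", "integration")[seq_len(nrow(ly))]
  df <- data.frame(stage = stage,
                   type = ifelse(ly[, 1] == 1L, "tconv", "conv"),
                   kernel = sprintf("%dx%d", ly[, 2], ly[, 3]),
                   filters = ly[, 5], stride = ly[, 6],
                   params = ly[, 2] * ly[, 3] * ly[, 4] * ly[, 5] + ly[, 5])
  cat("Linear convolutional encoder-decoder for EEG super-resolution\n")
  print(df, row.names = FALSE)
  cat(sprintf("Total parameters: %s\n",
              format(sum(df$params), big.mark = ",")))
  if (object$trained) {
    cat(sprintf("Trained %d epochs (Adam, lr %g, batch %d)\n",
                object$epochs_trained, object$config$lr,
                object$config$batch_size))
  }
  invisible(df)
}

#' @export
coef.sr_model <- function(object, ...) object$weights

#' Plot training history of a fitted network
#' @param x an `sr_model` with a training history.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.sr_model <- function(x, ...) {
  if (!nrow(x$history)) stop("model has no training history")
  h <- x$history
  cols <- c("black", "firebrick")
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = cols, log = "y", xlab = "epoch",
                    ylab = "MSE", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1, col = cols,
                   bty = "n")
  invisible(x)
}

# ---- trial splitting -------------------------------------------------------

#' Train/validation/test splits of trials
#'
#' Partitions `n_trials` into disjoint, exhaustive train / validation / test
#' index sets with proportions 0.64 / 0.16 / 0.20 (train and test sizes are
#' floored, validation takes the remainder, so 1000 trials give 640/160/200
#' and 932 give 596/150/186), repeated `n_repeats` times with different
#' random permutations for cross-validation.  Reproducible from `seed`.
#'
#' @param n_trials number of trials (at least 5).
#' @param n_repeats number of independent repeats (default 5).
#' @param seed integer seed.
#' @return A list of `n_repeats` lists with integer elements `train`, `val`,
#'   `test`.
#' @export
split_trials <- function(n_trials, n_repeats = 5, seed = 1L) {
  if (n_trials < 5L) stop("need at least 5 trials to split")
  n_train <- floor(0.64 * n_trials)
  n_test <- floor(0.20 * n_trials)
  n_val <- n_trials - n_train - n_test
  if (min(n_train, n_val, n_test) < 1L) stop("too few trials to split")
  set.seed(seed)
  lapply(seq_len(n_repeats), function(r) {
    p <- sample.int(n_trials)
    list(train = sort(p[seq_len(n_train)]),
         val = sort(p[n_train + seq_len(n_val)]),
         test = sort(p[n_train + n_val + seq_len(n_test)]))
  })
}
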