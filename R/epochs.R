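#' Epoched multi-channel EEG container
#'
#' An `epoch_array` holds a block of epoched EEG as a numeric array of
#' dimension trials x time x channels, together with the sampling rate, the
#' time of the first sample and the channel labels.  It is the common currency
#' of every stage of the package: simulation, channel subsampling,
#' interpolation, network training and evaluation all consume and produce
#' `epoch_array` objects.
#'
#' @param data numeric array, trials x time x channels.  A matrix is accepted
#'   for a single trial (time x channels).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds (e.g. `-0.3` for a 300 ms
#'   pre-stimulus interval).
#' @param labels character vector of channel names; length must equal the
#'   channel dimension.
#' @return An object of class `epoch_array`.
#' @examples
#' x <- epoch_array(array(rnorm(2 * 16 * 4), c(2, 16, 4)),
#'                  fs = 512, labels = paste0("ch", 1:4))
#' x
#' @export
epoch_array <- function(data, fs = 512, t0 = 0, labels = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("epoch data must be finite (no NA/NaN/Inf)")
  if (!(is.numeric(fs) && length(fs) == 1L && fs > 0)) {
    stop("'fs' must be a single positive number")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(data)[3L]))
  if (length(labels) != dim(data)[3L]) {
    stop("length(labels) must equal the channel dimension")
  }
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  structure(list(data = data, fs = fs, t0 = t0, labels = as.character(labels)),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_array> %d trial(s) x %d samples x %d channels @ %g Hz, t0 = %g s\n",
              d[1L], d[2L], d[3L], x$fs, x$t0))
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

#' @export
as.array.epoch_array <- function(x, ...) x$data

#' Time axis of an epoch array
#' @param x an [epoch_array].
#' @return numeric vector of sample times in seconds.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_array"))
  x$t0 + (seq_len(dim(x$data)[2L]) - 1L) / x$fs
}

#' Subset trials of an epoch array
#' @param x an [epoch_array].
#' @param trials integer indices of the trials to keep.
#' @return An [epoch_array] with the selected trials.
#' @export
epoch_subset <- function(x, trials) {
  stopifnot(inherits(x, "epoch_array"))
  epoch_array(x$data[trials, , , drop = FALSE], fs = x$fs, t0 = x$t0,
              labels = x$labels)
}

#' Average an epoch array over trials
#' @param x an [epoch_array].
#' @return A single-trial [epoch_array] containing the trial mean.
#' @export
epoch_average <- function(x) {
  stopifnot(inherits(x, "epoch_array"))
  m <- apply(x$data, c(2L, 3L), mean)
  epoch_array(array(m, c(1L, dim(m))), fs = x$fs, t0 = x$t0, labels = x$labels)
}

#' Read and write epoch containers
#'
#' Epoch arrays are persisted as a versioned container holding the four
#' datasets `data`, `fs`, `t0` and `labels` (R native serialization,
#' version 3).  A write followed by a read round-trips bit-exactly.
#'
#' @param x an [epoch_array].
#' @param path file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns the
#'   restored [epoch_array].
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_array"))
  payload <- list(format = "eegsr-epochs", version = 1L,
                  data = x$data, fs = x$fs, t0 = x$t0, labels = x$labels)
  saveRDS(payload, path, version = 3L)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$format, "eegsr-epochs")) {
    stop("not an eegsr epoch container: ", path)
  }
  epoch_array(payload$data, fs = payload$fs, t0 = payload$t0,
              labels = payload$labels)
}
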