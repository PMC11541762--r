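#' Blink-locked epoch container
#'
#' An `epoch_set` holds a stack of fixed-length epochs time-locked to an eye
#' blink peak: a numeric array of `n_epochs x n_series x n_times`, the
#' epoch-relative time grid in milliseconds, one condition label per epoch,
#' and the kind of series stored (scalp channels, decomposition components, or
#' the single blink component trace).
#'
#' Time zero sits on the sample grid at the blink-peak sample; the default
#' epoch window runs from -500 ms to +1000 ms with inclusive endpoints, i.e.
#' 376 samples at 250 Hz.
#'
#' @param data numeric array `n_epochs x n_series x n_times` (microvolts).
#' @param time_ms numeric vector of epoch-relative times in ms, length
#'   `n_times`, strictly increasing, containing 0.
#' @param labels character/factor vector of condition labels, one per epoch.
#' @param fs sampling rate in Hz.
#' @param series_kind one of `"channels"`, `"components"`, `"blink"`,
#'   `"fused"`.
#' @param series_names optional names for the series dimension.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, labels, fs,
                      series_kind = c("channels", "components", "blink", "fused"),
                      series_names = NULL) {
  series_kind <- match.arg(series_kind)
  if (length(dim(data)) != 3) {
    abort("`data` must be a 3-D array (epochs x series x times).")
  }
  if (dim(data)[3] != length(time_ms)) {
    abort("Length of `time_ms` must match the third dimension of `data`.")
  }
  if (dim(data)[1] != length(labels)) {
    abort("`labels` must have one entry per epoch.")
  }
  if (any(diff(time_ms) <= 0)) abort("`time_ms` must be strictly increasing.")
  if (min(abs(time_ms)) > 1e-9) abort("Time zero must lie on the sample grid.")
  if (is.null(series_names)) {
    series_names <- sprintf("%s%02d", substr(series_kind, 1, 2), seq_len(dim(data)[2]))
  }
  dimnames(data) <- list(NULL, series_names, NULL)
  structure(
    list(data = data, time_ms = as.numeric(time_ms),
         labels = as.character(labels), fs = fs, series_kind = series_kind),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set: %d epochs x %d %s x %d samples @ %g Hz>\n",
              d[1], d[2], x$series_kind, d[3], x$fs))
  cat(sprintf("  time %g..%g ms; conditions: %s\n",
              min(x$time_ms), max(x$time_ms),
              paste(sprintf("%s (%d)", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_epochs <- function(x) dim(x$data)[1]
n_series <- function(x) dim(x$data)[2]
n_times  <- function(x) dim(x$data)[3]

#' Subset epochs of an epoch_set
#'
#' @param x an [epoch_set()].
#' @param i integer or logical index over epochs.
#' @return An `epoch_set` with the selected epochs, labels kept in register.
#' @export
epochs_subset <- function(x, i) {
  stopifnot(inherits(x, "epoch_set"))
  out <- x
  out$data <- x$data[i, , , drop = FALSE]
  out$labels <- x$labels[i]
  out
}

#' Keep a subset of series (rows) of an epoch_set
#'
#' @param x an [epoch_set()].
#' @param j integer index over series.
#' @param series_kind optional new series kind for the result.
#' @return An `epoch_set` with the selected series.
#' @export
series_subset <- function(x, j, series_kind = x$series_kind) {
  stopifnot(inherits(x, "epoch_set"))
  out <- x
  out$data <- x$data[, j, , drop = FALSE]
  out$series_kind <- series_kind
  out
}

#' Tidy view of an epoch_set
#'
#' Long tibble with one row per epoch x series x time sample.
#'
#' @param x an [epoch_set()].
#' @param ... unused.
#' @return A tibble with columns `epoch`, `series`, `time_ms`, `value`,
#'   `label`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    series = rep(rep(dimnames(x$data)[[2]], each = d[1]), times = d[3]),
    time_ms = rep(x$time_ms, each = d[1] * d[2]),
    value = as.vector(x$data),
    label = rep(x$labels, times = d[2] * d[3])
  )
}

# sample index (1-based) of a given epoch-relative time in ms
time_index <- function(x, t_ms) {
  i <- which.min(abs(x$time_ms - t_ms))
  if (abs(x$time_ms[i] - t_ms) > 1000 / x$fs / 2 + 1e-9) {
    abort(sprintf("Time %g ms is not on the epoch grid.", t_ms))
  }
  i
}
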