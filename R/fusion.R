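#' PCA on channel-space epochs with a variance-coverage selection rule
#'
#' Fits PCA on the `(epochs * times) x channels` matrix after per-channel
#' mean removal and keeps the smallest number of components whose cumulative
#' explained-variance ratio reaches `var_threshold` (default 95%). Loadings
#' follow a fixed sign convention (largest-magnitude weight positive) so
#' component signs are reproducible. Epochs are then projected onto the
#' retained loadings.
#'
#' @param epochs channel-space [epoch_set()].
#' @param var_threshold cumulative explained-variance target in (0, 1].
#' @return A `pc_set`: list with `pc_epochs` (component [epoch_set()]),
#'   `loadings` (`channels x k`), `explained_variance_ratio` (all channels),
#'   `k`, `center` (channel means), `cum_explained` (of the retained set).
#' @export
fit_pca_select <- function(epochs, var_threshold = 0.95) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$series_kind != "channels") abort("PCA expects channel-space epochs.")
  d <- dim(epochs$data)
  if (d[1] * d[3] <= d[2]) abort("Need more epoch samples than channels.")
  x <- epoch_matrix(epochs)                       # (epochs*times) x channels
  ctr <- colMeans(x)
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  if (sum(ev) <= 0) abort("Zero-variance data; PCA undefined.")
  evr <- ev / sum(ev)
  k <- which(cumsum(evr) >= var_threshold - 1e-12)[1]
  load <- p$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  pcs <- project_epochs(epochs, load, ctr)
  structure(list(pc_epochs = pcs, loadings = load,
                 explained_variance_ratio = evr, k = k, center = ctr,
                 cum_explained = sum(evr[seq_len(k)])),
            class = "pc_set")
}

#' @export
print.pc_set <- function(x, ...) {
  cat(sprintf("<pc_set: k = %d components, %.2f%% variance>\n",
              x$k, 100 * x$cum_explained))
  invisible(x)
}

# flatten epochs to (epochs*times) x series
epoch_matrix <- function(epochs) {
  d <- dim(epochs$data)
  m <- aperm(epochs$data, c(1, 3, 2))
  dim(m) <- c(d[1] * d[3], d[2])
  m
}

# project channel epochs onto loadings (channels x k), after centering
project_epochs <- function(epochs, loadings, center) {
  d <- dim(epochs$data)
  k <- ncol(loadings)
  out <- array(0, dim = c(d[1], k, d[3]))
  for (i in seq_len(d[1])) {
    out[i, , ] <- t(loadings) %*% (epochs$data[i, , ] - center)
  }
  epoch_set(out, epochs$time_ms, epochs$labels, epochs$fs, "components",
            sprintf("PC%02d", seq_len(k)))
}

#' Concatenation fusion: EEG principal components + aligned blink series
#'
#' Row-stacks the k retained principal-component series with the single
#' synchronized blink-component series, per epoch, giving the pcEEG+ feature
#' stream with `k + 1` series.
#'
#' @param pcs a `pc_set` from [fit_pca_select()], or a component
#'   [epoch_set()].
#' @param blink_sync an aligned blink [epoch_set()] (1 series), same epoch
#'   count and time grid.
#' @return A `fused` [epoch_set()] with attributes `provenance = "pcEEG+"`
#'   and `component_blocks` (named index ranges for the EEG and blink rows).
#' @export
fuse_concat <- function(pcs, blink_sync) {
  eeg <- if (inherits(pcs, "pc_set")) pcs$pc_epochs else pcs
  stopifnot(inherits(eeg, "epoch_set"), inherits(blink_sync, "epoch_set"))
  if (n_epochs(eeg) != n_epochs(blink_sync) ||
      n_times(eeg) != n_times(blink_sync) ||
      max(abs(eeg$time_ms - blink_sync$time_ms)) > 1e-9) {
    abort("Epoch count and time grid must match between streams.")
  }
  if (!identical(eeg$labels, blink_sync$labels)) {
    abort("Condition labels differ between streams.")
  }
  k <- n_series(eeg)
  d <- dim(eeg$data)
  arr <- array(0, dim = c(d[1], k + n_series(blink_sync), d[3]))
  arr[, seq_len(k), ] <- eeg$data
  arr[, k + seq_len(n_series(blink_sync)), ] <- blink_sync$data
  out <- epoch_set(arr, eeg$time_ms, eeg$labels, eeg$fs, "fused",
                   c(dimnames(eeg$data)[[2]], dimnames(blink_sync$data)[[2]]))
  attr(out, "provenance") <- "pcEEG+"
  attr(out, "component_blocks") <- list(eeg = seq_len(k),
                                        blink = k + seq_len(n_series(blink_sync)))
  out
}

#' Canonical correlation between EEG and aligned blink channel-space epochs
#'
#' Solves the generalized eigenproblem
#' `Sxx^-1 Sxb Sbb^-1 Sxb' u = rho^2 u` (and its counterpart for `v`) on the
#' flattened `(epochs*times) x series` matrices, with a ridge term
#' `eps * trace/dim` added to each autocovariance for invertibility. Weight
#' vectors are normalized to unit variance (`u' Sxx u = 1`), pairs sorted by
#' descending canonical correlation, and the canonical variates
#' `X'(t) = u'X(t)`, `B'(t) = v'B(t)` are computed per epoch.
#'
#' @param eeg_epochs channel-space EEG [epoch_set()].
#' @param blink_channelspace_sync aligned blink channel-space [epoch_set()]
#'   (BCS), same epoch/time structure.
#' @param n_pairs number of canonical pairs to keep (default 1).
#' @param ridge relative ridge coefficient (default 1e-8); set to 0 to
#'   require exactly invertible covariances.
#' @return A `cca_fit`: list with `pairs` (list of `u`, `v`, `rho` per pair),
#'   `x_variates`, `b_variates` (epoch arrays `n_epochs x n_pairs x n_times`),
#'   covariance matrices `S_xx`, `S_bb`, `S_xb`, and centers.
#' @export
fit_cca <- function(eeg_epochs, blink_channelspace_sync, n_pairs = 1,
                    ridge = 1e-8) {
  x_ep <- eeg_epochs; b_ep <- blink_channelspace_sync
  stopifnot(inherits(x_ep, "epoch_set"), inherits(b_ep, "epoch_set"))
  if (n_epochs(x_ep) != n_epochs(b_ep) || n_times(x_ep) != n_times(b_ep)) {
    abort("EEG and blink streams must share epoch count and time grid.")
  }
  x <- epoch_matrix(x_ep); b <- epoch_matrix(b_ep)
  cx <- colMeans(x); cb <- colMeans(b)
  x <- sweep(x, 2, cx); b <- sweep(b, 2, cb)
  n <- nrow(x)
  sxx <- crossprod(x) / (n - 1)
  sbb <- crossprod(b) / (n - 1)
  sxb <- crossprod(x, b) / (n - 1)
  if (ridge > 0) {
    sxx <- sxx + diag(ridge * sum(diag(sxx)) / nrow(sxx), nrow(sxx))
    sbb <- sbb + diag(ridge * sum(diag(sbb)) / nrow(sbb), nrow(sbb))
  }
  sxx_i <- tryCatch(solve(sxx), error = function(e) {
    abort("Singular EEG covariance; increase the `ridge` regularization term.")
  })
  sbb_i <- tryCatch(solve(sbb), error = function(e) {
    abort("Singular blink covariance; increase the `ridge` regularization term.")
  })
  m <- sxx_i %*% sxb %*% sbb_i %*% t(sxb)
  eg <- eigen(m)
  ord <- order(Re(eg$values), decreasing = TRUE)
  n_pairs <- min(n_pairs, ncol(x), ncol(b))
  pairs <- vector("list", n_pairs)
  for (j in seq_len(n_pairs)) {
    u <- Re(eg$vectors[, ord[j]])
    u <- u / sqrt(drop(t(u) %*% sxx %*% u))
    v <- drop(sbb_i %*% t(sxb) %*% u)
    v <- v / sqrt(drop(t(v) %*% sbb %*% v))
    rho <- drop(t(u) %*% sxb %*% v)
    if (rho < 0) { v <- -v; rho <- -rho }
    # sign convention: largest-magnitude EEG weight positive
    if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
    pairs[[j]] <- list(u = u, v = v, rho = min(rho, 1))
  }
  xv <- variate_epochs(x_ep, lapply(pairs, `[[`, "u"), cx)
  bv <- variate_epochs(b_ep, lapply(pairs, `[[`, "v"), cb)
  structure(list(pairs = pairs, x_variates = xv, b_variates = bv,
                 S_xx = sxx, S_bb = sbb, S_xb = sxb,
                 center_x = cx, center_b = cb,
                 time_ms = x_ep$time_ms, labels = x_ep$labels, fs = x_ep$fs),
            class = "cca_fit")
}

variate_epochs <- function(epochs, ws, center) {
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], length(ws), d[3]))
  for (i in seq_len(d[1])) {
    xc <- epochs$data[i, , ] - center
    for (j in seq_along(ws)) out[i, j, ] <- drop(ws[[j]] %*% xc)
  }
  out
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit: %d pair(s), rho = %s>\n", length(x$pairs),
              paste(sprintf("%.3f", vapply(x$pairs, `[[`, numeric(1), "rho")),
                    collapse = ", ")))
  invisible(x)
}

#' CCA fusion: stack canonical variates per epoch
#'
#' For each retained canonical pair, stacks the EEG variate `X'` and the
#' blink variate `B'` as fused series per epoch (2 series per pair).
#'
#' @param fit a `cca_fit` from [fit_cca()].
#' @return A `fused` [epoch_set()] with `provenance = "CCA"` and
#'   `component_blocks` marking EEG-derived vs blink-derived rows.
#' @export
fuse_cca <- function(fit) {
  stopifnot(inherits(fit, "cca_fit"))
  if (length(fit$pairs) == 0) abort("No canonical pairs.")
  np <- length(fit$pairs)
  d <- dim(fit$x_variates)
  arr <- array(0, dim = c(d[1], 2 * np, d[3]))
  nms <- character(2 * np)
  for (j in seq_len(np)) {
    arr[, 2 * j - 1, ] <- fit$x_variates[, j, ]
    arr[, 2 * j, ] <- fit$b_variates[, j, ]
    nms[2 * j - 1] <- sprintf("Xv%02d", j)
    nms[2 * j] <- sprintf("Bv%02d", j)
  }
  out <- epoch_set(arr, fit$time_ms, fit$labels, fit$fs, "fused", nms)
  attr(out, "provenance") <- "CCA"
  attr(out, "component_blocks") <- list(eeg = seq(1, 2 * np, by = 2),
                                        blink = seq(2, 2 * np, by = 2))
  out
}
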