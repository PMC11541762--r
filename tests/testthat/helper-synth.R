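# small shared fixtures, built in code

quick_config <- function(...) {
  defaults <- list(
    n_channels = 12, fs = 250, duration = 60,
    conditions = c("A", "B"), blink_rate = 12,
    evoked_lag = c(A = 160, B = 200), snr = 5, seed = 42L
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# epoch_set built directly from an array, for plumbing tests
toy_epochs <- function(arr, fs = 250, labels = NULL,
                       kind = "channels") {
  d <- dim(arr)
  t_ms <- seq(0, by = 1000 / fs, length.out = d[3])
  epoch_set(arr, t_ms, labels %||% rep("x", d[1]), fs, kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nearest ground-truth blink index for each detected event
match_events <- function(detected, truth) {
  vapply(detected, function(p) which.min(abs(truth - p)), integer(1))
}

# independent CCA oracle: whiten each block via eigendecomposition, then
# SVD of the cross-correlation of the whitened blocks
cca_oracle <- function(x, b) {
  x <- sweep(x, 2, colMeans(x)); b <- sweep(b, 2, colMeans(b))
  n <- nrow(x)
  sxx <- crossprod(x) / (n - 1); sbb <- crossprod(b) / (n - 1)
  sxb <- crossprod(x, b) / (n - 1)
  isqrt <- function(s) {
    e <- eigen(s, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nrow(s)) %*% t(e$vectors)
  }
  wx <- isqrt(sxx); wb <- isqrt(sbb)
  sv <- svd(wx %*% sxb %*% wb)
  list(rho = sv$d, u = wx %*% sv$u, v = wb %*% sv$v)
}
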