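test_that("rank-1 data keeps a single component explaining everything", {
  w <- c(1, 0.5, -0.3, 0.2)
  src <- sin(seq(0, 6 * pi, length.out = 60))
  arr <- array(0, dim = c(4, 4, 60))
  for (i in 1:4) arr[i, , ] <- w %o% (i * src)
  p <- fit_pca_select(toy_epochs(arr))
  expect_equal(p$k, 1)
  expect_equal(p$cum_explained, 1.0, tolerance = 1e-12)
})

test_that("cumulative-variance rule keeps the smallest k reaching 95%", {
  # build data whose covariance eigen-spectrum fractions are 0.60/0.30/0.05/0.05
  set.seed(8)
  n <- 20000
  z <- matrix(rnorm(n * 4), n, 4)
  z <- qr.Q(qr(z))  # orthonormal columns kill sampling cross-correlation
  z <- sweep(z, 2, sqrt(colMeans(z^2)), "/")
  x <- z %*% diag(sqrt(c(0.60, 0.30, 0.05, 0.05)))
  arr <- array(0, dim = c(n / 100, 4, 100))
  for (i in seq_len(n / 100)) arr[i, , ] <- t(x[((i - 1) * 100 + 1):(i * 100), ])
  p <- fit_pca_select(toy_epochs(arr))
  expect_equal(p$k, 3)  # 0.90 < 0.95 <= 0.95
  expect_gte(p$cum_explained, 0.95)
})

test_that("retained components always cover at least 95% of the variance", {
  for (s in c(1L, 2L, 3L)) {
    out <- simulate_epochset(quick_config(seed = s), 20)
    p <- fit_pca_select(out$eeg)
    expect_gte(p$cum_explained, 0.95)
    if (p$k > 1) {
      expect_lt(sum(p$explained_variance_ratio[seq_len(p$k - 1)]), 0.95)
    }
  }
})

test_that("back-projecting retained PCs recovers >= 95% of signal variance", {
  out <- simulate_epochset(quick_config(seed = 21L), 30)
  p <- fit_pca_select(out$eeg)
  d <- dim(out$eeg$data)
  resid_ss <- 0
  tot_ss <- 0
  for (i in seq_len(d[1])) {
    xc <- out$eeg$data[i, , ] - p$center
    rec <- p$loadings %*% (t(p$loadings) %*% xc)
    resid_ss <- resid_ss + sum((xc - rec)^2)
    tot_ss <- tot_ss + sum(xc^2)
  }
  expect_gte(1 - resid_ss / tot_ss, 0.95)
})

test_that("concatenation fusion stacks k PCs + 1 blink series", {
  out <- simulate_epochset(quick_config(seed = 31L), 10)
  p <- fit_pca_select(out$eeg)
  fused <- fuse_concat(p, out$blink)
  expect_equal(dim(fused$data)[2], p$k + 1)
  expect_equal(attr(fused, "provenance"), "pcEEG+")
  blocks <- attr(fused, "component_blocks")
  expect_equal(blocks$eeg, seq_len(p$k))
  expect_equal(blocks$blink, p$k + 1L)
  # blink rows are carried through untouched
  expect_equal(fused$data[, p$k + 1, ], out$blink$data[, 1, ])

  # epoch/time mismatch errors
  short <- epochs_subset(out$blink, 1:5)
  expect_error(fuse_concat(p, short), "match")
})

test_that("fused feature length is (k+1) * w for k in 1..10, w in {5, 13, 25}", {
  for (k in 1:10) {
    for (w in c(5L, 13L, 25L)) {
      arr_e <- array(rnorm(6 * k * 40), dim = c(6, k, 40))
      arr_b <- array(rnorm(6 * 1 * 40), dim = c(6, 1, 40))
      fused <- fuse_concat(toy_epochs(arr_e, kind = "components"),
                           toy_epochs(arr_b, kind = "blink"))
      fm <- window_features(fused, start = 3, w = w)
      expect_equal(nrow(fm), (k + 1) * w)
      expect_equal(ncol(fm), 6)
    }
  }
})

test_that("CCA matches the whitening + SVD oracle to 1e-8 over 20 seeds", {
  for (s in 1:20) {
    set.seed(s)
    n <- 200
    x <- matrix(rnorm(n * 4), n, 4)
    b <- matrix(rnorm(n * 3), n, 3)
    b[, 1] <- b[, 1] + 0.5 * x[, 1]   # induce correlation
    ex <- toy_epochs(array(t(x), dim = c(1, 4, n)))
    eb <- toy_epochs(array(t(b), dim = c(1, 3, n)))
    fit <- fit_cca(ex, eb, n_pairs = 3, ridge = 0)
    orc <- cca_oracle(x, b)
    rhos <- vapply(fit$pairs, `[[`, numeric(1), "rho")
    expect_equal(rhos, orc$rho[1:3], tolerance = 1e-8)
    for (j in 1:3) {
      u <- fit$pairs[[j]]$u; uo <- orc$u[, j]
      v <- fit$pairs[[j]]$v; vo <- orc$v[, j]
      s_u <- sign(sum(u * uo))
      expect_equal(u, s_u * drop(uo), tolerance = 1e-6)
      expect_equal(v, s_u * drop(vo), tolerance = 1e-6)
    }
  }
})

test_that("CCA weight normalization and correlation bounds hold", {
  set.seed(99)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3)
  b <- matrix(rnorm(n * 2), n, 2)
  ex <- toy_epochs(array(t(x), dim = c(1, 3, n)))
  eb <- toy_epochs(array(t(b), dim = c(1, 2, n)))
  fit <- fit_cca(ex, eb, n_pairs = 2, ridge = 0)
  for (p in fit$pairs) {
    expect_equal(drop(t(p$u) %*% fit$S_xx %*% p$u), 1, tolerance = 1e-9)
    expect_equal(drop(t(p$v) %*% fit$S_bb %*% p$v), 1, tolerance = 1e-9)
    expect_gte(p$rho, 0)
    expect_lte(p$rho, 1)
  }
})

test_that("a shared 1-D signal gives rho = 1 and proportional variates", {
  sig <- sin(seq(0, 8 * pi, length.out = 250))
  ex <- toy_epochs(array(sig, dim = c(1, 1, 250)))
  fit <- fit_cca(ex, ex, ridge = 0)
  expect_equal(fit$pairs[[1]]$rho, 1, tolerance = 1e-9)
  fused <- fuse_cca(fit)
  expect_equal(dim(fused$data)[2], 2)
  xv <- fused$data[1, 1, ]; bv <- fused$data[1, 2, ]
  expect_equal(cor(xv, bv), 1, tolerance = 1e-8)
})

test_that("independent noise stays below the permutation-null 95th percentile", {
  set.seed(7)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  b <- matrix(rnorm(n * 2), n, 2)
  fit <- fit_cca(toy_epochs(array(t(x), dim = c(1, 3, n))),
                 toy_epochs(array(t(b), dim = c(1, 2, n))))
  null_rhos <- vapply(1:100, function(i) {
    cca_oracle(x, b[sample(n), , drop = FALSE])$rho[1]
  }, numeric(1))
  expect_lt(fit$pairs[[1]]$rho, quantile(null_rhos, 0.95) + 0.05)
})

test_that("CCA correlation is invariant to invertible channel remixing", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4)
  b <- matrix(rnorm(n * 2), n, 2)
  b[, 2] <- b[, 2] + 0.4 * x[, 2]
  a_mix <- matrix(rnorm(16), 4, 4) + diag(4)
  fit1 <- fit_cca(toy_epochs(array(t(x), dim = c(1, 4, n))),
                  toy_epochs(array(t(b), dim = c(1, 2, n))), ridge = 0)
  fit2 <- fit_cca(toy_epochs(array(t(x %*% a_mix), dim = c(1, 4, n))),
                  toy_epochs(array(t(b), dim = c(1, 2, n))), ridge = 0)
  expect_equal(fit1$pairs[[1]]$rho, fit2$pairs[[1]]$rho, tolerance = 1e-8)
})

test_that("eigen-route optimum matches direct maximization on a 2x2 case", {
  set.seed(23)
  n <- 500
  x <- matrix(rnorm(n * 2), n, 2)
  b <- matrix(rnorm(n * 2), n, 2)
  b[, 1] <- b[, 1] + 0.8 * (x[, 1] - x[, 2])
  fit <- fit_cca(toy_epochs(array(t(x), dim = c(1, 2, n))),
                 toy_epochs(array(t(b), dim = c(1, 2, n))), ridge = 0)
  # gradient-free maximization of corr(Xu, Bv) over angles
  obj <- function(th) {
    u <- c(cos(th[1]), sin(th[1])); v <- c(cos(th[2]), sin(th[2]))
    -abs(cor(x %*% u, b %*% v))
  }
  best <- optim(c(0.5, 0.5), obj, method = "Nelder-Mead",
                control = list(reltol = 1e-14))
  expect_equal(fit$pairs[[1]]$rho, -best$value, tolerance = 1e-6)
})

test_that("the first canonical variate tracks a shared blink-locked source", {
  cfg <- quick_config(n_channels = 10, conditions = "A",
                      evoked_lag = c(A = 160), snr = 10, seed = 41L)
  out <- simulate_epochset(cfg, 40)
  bcs <- blinkfuse:::blink_to_channelspace(out$blink, out$truth$mixing)
  # inject the blink into the EEG stream so the two streams share a source
  shared <- out$eeg
  shared$data <- shared$data + 0.05 * bcs$data
  fit <- fit_cca(shared, bcs)
  fused <- fuse_cca(fit)
  truth_series <- as.vector(t(out$blink$data[, 1, ]))
  xv <- as.vector(t(fused$data[, 1, ]))
  expect_gt(abs(cor(xv, truth_series)), 0.9)
})
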