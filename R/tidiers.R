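#' Tidy a principal-component set
#'
#' @param x a `pc_set` from [fit_pca_select()].
#' @param ... unused.
#' @return A tibble: `component`, `explained_variance_ratio`, `cumulative`,
#'   `retained`.
#' @export
tidy.pc_set <- function(x, ...) {
  evr <- x$explained_variance_ratio
  tibble(component = seq_along(evr), explained_variance_ratio = evr,
         cumulative = cumsum(evr), retained = seq_along(evr) <= x$k)
}

#' Glance at a principal-component set
#'
#' @param x a `pc_set`.
#' @param ... unused.
#' @return A one-row tibble: `k`, `cum_explained`, `n_channels`.
#' @export
glance.pc_set <- function(x, ...) {
  tibble(k = x$k, cum_explained = x$cum_explained,
         n_channels = nrow(x$loadings))
}

#' Tidy a CCA fit
#'
#' @param x a `cca_fit` from [fit_cca()].
#' @param ... unused.
#' @return A tibble of canonical weights: `pair`, `stream` (`"eeg"` or
#'   `"blink"`), `term`, `weight`, `rho`.
#' @export
tidy.cca_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$pairs), function(j) {
    p <- x$pairs[[j]]
    dplyr::bind_rows(
      tibble(pair = j, stream = "eeg",
             term = sprintf("x%02d", seq_along(p$u)), weight = p$u, rho = p$rho),
      tibble(pair = j, stream = "blink",
             term = sprintf("b%02d", seq_along(p$v)), weight = p$v, rho = p$rho)
    )
  }))
}

#' Glance at a CCA fit
#'
#' @param x a `cca_fit`.
#' @param ... unused.
#' @return A one-row tibble: `n_pairs`, `rho_1`.
#' @export
glance.cca_fit <- function(x, ...) {
  tibble(n_pairs = length(x$pairs), rho_1 = x$pairs[[1]]$rho)
}

#' Tidy a temporal generalization matrix
#'
#' @param x a `tgm` from [temporal_generalization()].
#' @param ... unused.
#' @return A long tibble: `train_ms`, `test_ms`, `score`.
#' @export
tidy.tgm <- function(x, ...) {
  tibble(train_ms = rep(x$center_ms, times = length(x$center_ms)),
         test_ms = rep(x$center_ms, each = length(x$center_ms)),
         score = as.vector(x$scores))
}

#' Glance at a temporal generalization matrix
#'
#' @param x a `tgm`.
#' @param ... unused.
#' @return A one-row tibble: `peak_score`, `peak_train_ms`, `peak_test_ms`,
#'   `diag_peak_ms`, `chance`.
#' @export
glance.tgm <- function(x, ...) {
  idx <- which(x$scores == max(x$scores), arr.ind = TRUE)[1, ]
  dg <- diag(x$scores)
  tibble(peak_score = max(x$scores),
         peak_train_ms = x$center_ms[idx[1]],
         peak_test_ms = x$center_ms[idx[2]],
         diag_peak_ms = x$center_ms[which.max(dg)],
         chance = x$chance)
}

#' Tidy an extreme-pixel permutation result
#'
#' @param x a `perm_null` from [extreme_pixel_permutation()].
#' @param ... unused.
#' @return A long tibble: `row`, `col`, `observed`, `significant`.
#' @export
tidy.perm_null <- function(x, ...) {
  d <- dim(x$observed_map)
  tibble(row = rep(seq_len(d[1]), times = d[2]),
         col = rep(seq_len(d[2]), each = d[1]),
         observed = as.vector(x$observed_map),
         significant = as.vector(x$significance_mask))
}

#' Glance at an extreme-pixel permutation result
#'
#' @param x a `perm_null`.
#' @param ... unused.
#' @return A one-row tibble: `n_perm`, `lower_crit`, `upper_crit`,
#'   `n_significant`, `alpha`.
#' @export
glance.perm_null <- function(x, ...) {
  tibble(n_perm = x$n_perm, lower_crit = x$lower_crit,
         upper_crit = x$upper_crit,
         n_significant = sum(x$significance_mask), alpha = x$alpha)
}

#' Glance at a decoding curve
#'
#' @param x a `decoding_curve` from [decode_timecourse()].
#' @param ... unused.
#' @return A one-row tibble: `peak_acc`, `peak_ms`, `mean_acc`, `chance`.
#' @export
glance.decoding_curve <- function(x, ...) {
  i <- which.max(x$acc)
  tibble(peak_acc = x$acc[i], peak_ms = x$center_ms[i],
         mean_acc = mean(x$acc), chance = x$chance[1])
}
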