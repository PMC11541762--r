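#' Pointwise paired t-tests with FDR correction
#'
#' Two-sided paired t-test per comparison point (e.g. per training time),
#' followed by Benjamini-Hochberg step-up correction across points
#' (Benjamini-Yekutieli available via `method = "BY"`). Points with
#' zero-variance differences get an undefined (NA) p-value, flagged rather
#' than silently dropped.
#'
#' @param a,b numeric matrices `participants x points` (or vectors for a
#'   single point), paired by row.
#' @param alpha significance level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return A `paired_test` tibble: `point`, `mean_diff`, `t_stat`, `p_raw`,
#'   `p_fdr`, `significant` (`p_fdr < alpha`); attribute `alpha`.
#' @export
paired_t_fdr <- function(a, b, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have identical shape.")
  if (nrow(a) < 3) abort("Need at least 3 participants for a paired test.")
  d <- a - b
  n <- nrow(d)
  mean_d <- colMeans(d)
  sd_d <- apply(d, 2, sd)
  t_stat <- ifelse(sd_d > 0, mean_d / (sd_d / sqrt(n)), NA_real_)
  p_raw <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  if (anyNA(p_raw)) warn("Zero-variance differences at some points; p undefined (NA).")
  p_fdr <- p.adjust(p_raw, method = method)
  structure(tibble(point = seq_along(mean_d), mean_diff = mean_d,
                   t_stat = t_stat, p_raw = p_raw, p_fdr = p_fdr,
                   significant = !is.na(p_fdr) & p_fdr < alpha),
            alpha = alpha,
            class = c("paired_test", "tbl_df", "tbl", "data.frame"))
}

#' Extreme-pixel permutation test over temporal generalization maps
#'
#' Family-wise inference for a stack of per-participant difference maps
#' (e.g. per-participant TGM differences between two methods). Each
#' permutation randomly flips the sign of every participant's map
#' (equivalent, for two paired conditions, to reallocating participants
#' between groups), computes the mean map, and records its maximum and
#' minimum pixel. An observed pixel is significant when the observed mean
#' exceeds the `1 - alpha/2` quantile of the max distribution or falls below
#' the `alpha/2` quantile of the min distribution — a two-tailed test at
#' `alpha = 0.01` by default, i.e. the 99.5th/0.5th percentiles.
#'
#' @param observed_maps per-participant difference maps: a 3-D array
#'   `participants x rows x cols`, or a list of equally shaped matrices.
#' @param n_perm number of permutations (default 1000; below 100 a warning
#'   is raised).
#' @param alpha two-tailed family-wise level (default 0.01).
#' @param seed seed; the permutation sequence is reproducible.
#' @return A `perm_null`: list with `observed_map` (mean map), `max_dist`,
#'   `min_dist` (length `n_perm`), `upper_crit`, `lower_crit`,
#'   `significance_mask` (logical matrix), `alpha`, `n_perm`.
#' @export
extreme_pixel_permutation <- function(observed_maps, n_perm = 1000,
                                      alpha = 0.01, seed = 1L) {
  if (is.list(observed_maps)) {
    shp <- dim(observed_maps[[1]])
    if (!all(vapply(observed_maps, function(m) identical(dim(m), shp), logical(1)))) {
      abort("All maps must share the same shape.")
    }
    arr <- array(0, dim = c(length(observed_maps), shp))
    for (i in seq_along(observed_maps)) arr[i, , ] <- observed_maps[[i]]
    observed_maps <- arr
  }
  if (length(dim(observed_maps)) != 3) {
    abort("`observed_maps` must be participants x rows x cols.")
  }
  n_sub <- dim(observed_maps)[1]
  if (n_sub < 2) abort("Need at least 2 participants.")
  if (n_perm < 100) warn("Fewer than 100 permutations; critical values will be coarse.")
  obs <- apply(observed_maps, c(2, 3), mean)
  flat <- matrix(observed_maps, nrow = n_sub)   # participants x pixels
  with_rng(seed, {
    mx <- numeric(n_perm); mn <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n_sub, replace = TRUE)
      pm <- colMeans(flat * s)
      mx[p] <- max(pm); mn[p] <- min(pm)
    }
  })
  upper <- quantile(mx, 1 - alpha / 2, names = FALSE, type = 7)
  lower <- quantile(mn, alpha / 2, names = FALSE, type = 7)
  structure(list(observed_map = obs, max_dist = mx, min_dist = mn,
                 upper_crit = upper, lower_crit = lower,
                 significance_mask = obs > upper | obs < lower,
                 alpha = alpha, n_perm = n_perm),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("<perm_null: %d permutations, crit [%.3g, %.3g], %d/%d significant pixels>\n",
              x$n_perm, x$lower_crit, x$upper_crit,
              sum(x$significance_mask), length(x$significance_mask)))
  invisible(x)
}
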