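#' Plot a decoding time course
#'
#' Accuracy over window centers with a +/- SD ribbon over cross-validation
#' repetitions and a dashed chance-level line.
#'
#' @param object a `decoding_curve` from [decode_timecourse()], or the
#'   `curves` tibble of a [run_pipeline()] result (with a `method` column).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.decoding_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  has_method <- "method" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$center_ms, y = .data$acc,
    colour = if (has_method) .data$method else NULL,
    fill = if (has_method) .data$method else NULL))
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$acc - .data$acc_sd,
                                      ymax = .data$acc + .data$acc_sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = df$chance[1], linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Time relative to blink peak (ms)",
                  y = "Decoding accuracy (%)",
                  colour = "Method", fill = "Method") +
    ggplot2::theme_minimal()
  p
}

#' Plot a temporal generalization matrix
#'
#' Train-time by test-time decoding scores as a raster centered on chance.
#'
#' @param object a `tgm` from [temporal_generalization()].
#' @param mask optional logical matrix (e.g. a permutation significance
#'   mask) outlined on top.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tgm <- function(object, mask = NULL, ...) {
  df <- tidy.tgm(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$test_ms, y = .data$train_ms,
                                        fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = object$chance,
                                  low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "Testing time (ms)", y = "Training time (ms)",
                  fill = "Accuracy (%)") +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    md <- df
    md$sig <- as.vector(t(mask))
    p <- p + ggplot2::geom_point(
      data = md[md$sig, , drop = FALSE],
      ggplot2::aes(x = .data$test_ms, y = .data$train_ms),
      inherit.aes = FALSE, shape = 0, size = 1, colour = "black")
  }
  p
}

#' Plot a global-field-power profile
#'
#' @param object a `gfp_profile` from [compute_gfp()].
#' @param ... unused.
#' @return A ggplot object with the peak marked.
#' @export
autoplot.gfp_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_ms, y = .data$gfp)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "peak_time_ms"),
                        linetype = "dotted") +
    ggplot2::labs(x = "Time relative to blink peak (ms)", y = "GFP (µV)") +
    ggplot2::theme_minimal()
}

#' Plot an extreme-pixel permutation result
#'
#' Observed mean difference map with significant pixels outlined.
#'
#' @param object a `perm_null` from [extreme_pixel_permutation()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.perm_null <- function(object, ...) {
  df <- tidy.perm_null(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$observed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 0, size = 1.2, colour = "black") +
    ggplot2::labs(x = "Test window", y = "Train window",
                  fill = "Mean diff (%)") +
    ggplot2::theme_minimal()
}
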