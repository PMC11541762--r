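#' Band-pass filter, resample, and reference a continuous recording
#'
#' Applies a zero-phase FIR band-pass (forward-backward filtering of a
#' windowed-sinc design), decimates to `target_fs` (which must divide the
#' input rate), flags flatline channels (constant for more than
#' `flatline_s` seconds) and channels whose best absolute correlation with
#' any other channel falls below `corr_min`, and re-references to the common
#' average. Flagged channels are recorded in the `flagged_channels` attribute;
#' set `drop_flagged = TRUE` to remove flatline channels from the data.
#'
#' @param raw a [continuous_recording()].
#' @param highpass_hz,lowpass_hz band edges in Hz (defaults 0.1 and 40).
#' @param target_fs output sampling rate; must divide `raw$fs`.
#' @param flatline_s flatline duration threshold in seconds (default 0.5).
#' @param corr_min neighbor-correlation floor (default 0.8).
#' @param drop_flagged drop flatline channels (default FALSE; flags only).
#' @param n_taps FIR length; default one second of taps (rounded odd).
#' @return A filtered, resampled, average-referenced [continuous_recording()]
#'   with attributes `flagged_channels` (named list with `flatline` and
#'   `low_correlation` label vectors).
#' @export
preprocess <- function(raw, highpass_hz = 0.1, lowpass_hz = 40,
                       target_fs = 250, flatline_s = 0.5, corr_min = 0.8,
                       drop_flagged = FALSE, n_taps = NULL) {
  stopifnot(inherits(raw, "continuous_recording"))
  fs <- raw$fs
  if (fs < target_fs) abort("`target_fs` cannot exceed the input rate.")
  if (lowpass_hz >= fs / 2) abort("`lowpass_hz` must be below Nyquist.")
  if (fs %% target_fs != 0) abort("`target_fs` must divide the input rate.")

  # flag before filtering: flatline = any constant run > flatline_s
  flat <- vapply(seq_len(nrow(raw$data)), function(i) {
    r <- rle(diff(raw$data[i, ]) == 0)
    any(r$values & r$lengths >= flatline_s * fs)
  }, logical(1))

  if (is.null(n_taps)) n_taps <- 2L * floor(fs / 2) + 1L
  h <- signal::fir1(n_taps - 1, c(highpass_hz, lowpass_hz) / (fs / 2),
                    type = "pass")
  filtered <- t(apply(raw$data, 1, function(x) signal::filtfilt(h, x)))

  q <- fs %/% target_fs
  if (q > 1) filtered <- filtered[, seq(1, ncol(filtered), by = q), drop = FALSE]

  # neighbor-correlation check on the filtered, resampled data
  cm <- suppressWarnings(abs(cor(t(filtered))))
  diag(cm) <- NA
  best <- apply(cm, 1, max, na.rm = TRUE)
  lowcor <- is.na(best) | best < corr_min

  if (all(flat | lowcor)) {
    abort("All channels flagged (flatline or low correlation); recording unrecoverable.")
  }
  flags <- list(flatline = raw$channel_labels[flat],
                low_correlation = raw$channel_labels[lowcor & !flat])

  keep <- if (drop_flagged) !flat else rep(TRUE, nrow(filtered))
  filtered <- filtered[keep, , drop = FALSE]
  labels <- raw$channel_labels[keep]

  filtered <- sweep(filtered, 2, colMeans(filtered))  # common average reference
  out <- continuous_recording(filtered, target_fs, labels, raw$participant_id)
  attr(out, "flagged_channels") <- flags
  out
}

#' Component decomposition container
#'
#' Holds an unmixing/mixing pair, component activations, and per-component
#' eye-candidate flags. `mixing %*% unmixing` must act as the identity on the
#' retained subspace.
#'
#' @param unmixing `components x channels` matrix.
#' @param mixing `channels x components` matrix; default pseudoinverse of
#'   `unmixing`.
#' @param activations `components x samples`; computed from `data` when given.
#' @param eye_candidate_flags logical per component.
#' @param fs sampling rate of the activations.
#' @param channel_labels channel names matching the mixing rows.
#' @return An object of class `component_decomposition`.
#' @export
component_decomposition <- function(unmixing, mixing = NULL,
                                    activations = NULL,
                                    eye_candidate_flags = NULL,
                                    fs = NULL, channel_labels = NULL) {
  unmixing <- as.matrix(unmixing)
  if (is.null(mixing)) mixing <- MASS::ginv(unmixing)
  mixing <- as.matrix(mixing)
  p <- unmixing %*% mixing
  if (max(abs(p - diag(nrow(p)))) > 1e-6 * max(1, max(abs(p)))) {
    abort("`mixing` is not a right-inverse of `unmixing` on the retained subspace.")
  }
  if (is.null(eye_candidate_flags)) {
    eye_candidate_flags <- rep(TRUE, nrow(unmixing))
  }
  structure(list(unmixing = unmixing, mixing = mixing,
                 activations = activations,
                 eye_candidate_flags = eye_candidate_flags,
                 fs = fs, channel_labels = channel_labels),
            class = "component_decomposition")
}

#' Decompose a recording into components
#'
#' Pluggable decomposition: either apply a user-supplied unmixing matrix, or
#' estimate one with a symmetric fixed-point ICA (whitening followed by
#' orthogonalized tanh-contrast iterations). Eye-candidate flags come from a
#' frontal-topography heuristic (anterior channel weights dominate the mixing
#' column, with equal left/right anterior signs) unless supplied.
#'
#' @param rec a [continuous_recording()].
#' @param unmixing optional `components x channels` matrix; skips estimation.
#' @param n_components number of components when estimating (default all).
#' @param eye_candidate_flags optional logical per component.
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed seed for the random initial rotation.
#' @return A [component_decomposition()] with activations filled in.
#' @export
decompose_components <- function(rec, unmixing = NULL,
                                 n_components = NULL,
                                 eye_candidate_flags = NULL,
                                 max_iter = 200, tol = 1e-6, seed = 1L) {
  stopifnot(inherits(rec, "continuous_recording"))
  x <- rec$data
  if (is.null(unmixing)) {
    unmixing <- fixed_point_ica(x, n_components %||% nrow(x), max_iter, tol, seed)
  }
  unmixing <- as.matrix(unmixing)
  mixing <- MASS::ginv(unmixing)
  acts <- unmixing %*% x
  if (is.null(eye_candidate_flags)) {
    eye_candidate_flags <- apply(mixing, 2, frontal_dominant)
    if (!any(eye_candidate_flags)) eye_candidate_flags[] <- TRUE
  }
  component_decomposition(unmixing, mixing, acts, eye_candidate_flags,
                          fs = rec$fs, channel_labels = rec$channel_labels)
}

# anterior weights (first fifth of the montage) dominate the column and the
# two most anterior weights agree in sign
frontal_dominant <- function(col) {
  n <- length(col)
  ant <- seq_len(max(2, ceiling(n / 5)))
  mean(abs(col[ant])) > mean(abs(col[-ant])) && sign(col[1]) == sign(col[2])
}

# symmetric fixed-point ICA: whiten, then orthogonalized tanh-contrast updates
fixed_point_ica <- function(x, n_components, max_iter, tol, seed) {
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, sum(eg$values > 1e-12 * eg$values[1]))
  wh <- diag(1 / sqrt(eg$values[seq_len(k)])) %*% t(eg$vectors[, seq_len(k)])
  z <- wh %*% xc
  with_rng(seed, {
    w <- matrix(rnorm(k * k), k, k)
  })
  sym_orth <- function(m) {
    s <- svd(m)
    s$u %*% t(s$v)
  }
  w <- sym_orth(w)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- g %*% t(z) / ncol(z) - diag(rowMeans(gp)) %*% w
    w_new <- sym_orth(w_new)
    if (max(abs(abs(rowSums(w_new * w)) - 1)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  w %*% wh
}

#' Identify the blink component among eye candidates
#'
#' Back-projects each eye-candidate component onto the two anterior channels
#' and returns the candidate with the largest positive Pearson correlation
#' between its left and right anterior projections. Blinks drive both
#' anterior channels with the same polarity (correlation near +1), whereas
#' horizontal eye movements drive them with opposite polarity (negative).
#'
#' @param decomp a [component_decomposition()] with activations.
#' @param left_anterior,right_anterior channel names or indices (defaults
#'   `"Fp1"`, `"Fp2"`).
#' @return Integer component index (the blink component, BC).
#' @export
identify_blink_component <- function(decomp, left_anterior = "Fp1",
                                     right_anterior = "Fp2") {
  stopifnot(inherits(decomp, "component_decomposition"))
  cand <- which(decomp$eye_candidate_flags)
  if (length(cand) == 0) abort("No eye-candidate components.")
  if (is.null(decomp$activations)) abort("Decomposition has no activations.")
  li <- resolve_channel(left_anterior, decomp$channel_labels)
  ri <- resolve_channel(right_anterior, decomp$channel_labels)
  rs <- vapply(cand, function(j) {
    lp <- decomp$mixing[li, j] * decomp$activations[j, ]
    rp <- decomp$mixing[ri, j] * decomp$activations[j, ]
    if (sd(lp) == 0 || sd(rp) == 0) return(-Inf)
    cor(lp, rp)
  }, numeric(1))
  if (max(rs) <= 0) {
    abort("No candidate shows a positive left/right anterior correlation; no blink component found.")
  }
  cand[which.max(rs)]
}

resolve_channel <- function(ch, labels) {
  if (is.numeric(ch)) return(as.integer(ch))
  i <- match(ch, labels)
  if (is.na(i)) abort(sprintf("Channel '%s' not found.", ch))
  i
}

#' Detect blink peaks in a blink-component signal
#'
#' Thresholds the signal at `mean + sd_multiplier * SD` (computed over the
#' whole series). Each contiguous supra-threshold interval of at least
#' `min_duration_ms` yields one event at the interval's maximum sample;
#' events closer than `refractory_ms` are merged, keeping the larger peak.
#' A zero-variance signal yields an empty series.
#'
#' @param blink_signal numeric vector (blink-component activation).
#' @param fs sampling rate in Hz.
#' @param sd_multiplier threshold in SD units above the mean (default 1.5).
#' @param min_duration_ms minimum supra-threshold duration (default 50).
#' @param refractory_ms minimum separation between events (default 200).
#' @return A tibble of class `blink_events` with columns `peak_sample` (sorted,
#'   1-based) and `peak_value`; attributes `threshold`, `fs`.
#' @export
detect_blinks <- function(blink_signal, fs, sd_multiplier = 1.5,
                          min_duration_ms = 50, refractory_ms = 200) {
  if (length(blink_signal) == 0) abort("Empty signal.")
  if (any(!is.finite(blink_signal))) abort("Signal contains non-finite values.")
  s <- sd(blink_signal)
  thr <- mean(blink_signal) + sd_multiplier * s
  empty <- structure(tibble(peak_sample = integer(), peak_value = numeric()),
                     threshold = thr, fs = fs,
                     class = c("blink_events", "tbl_df", "tbl", "data.frame"))
  if (s == 0) return(empty)
  above <- blink_signal > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= min_duration_ms * fs / 1000)
  if (length(runs) == 0) return(empty)
  peaks <- vapply(runs, function(k) {
    seg <- starts[k]:ends[k]
    seg[which.max(blink_signal[seg])]
  }, integer(1))
  vals <- blink_signal[peaks]
  # merge peaks closer than the refractory gap, keeping the larger one
  ord <- order(peaks)
  peaks <- peaks[ord]; vals <- vals[ord]
  keep <- rep(TRUE, length(peaks))
  last <- 1L
  for (i in seq_along(peaks)[-1]) {
    if ((peaks[i] - peaks[last]) < refractory_ms * fs / 1000) {
      if (vals[i] > vals[last]) { keep[last] <- FALSE; last <- i }
      else keep[i] <- FALSE
    } else last <- i
  }
  structure(tibble(peak_sample = peaks[keep], peak_value = vals[keep]),
            threshold = thr, fs = fs,
            class = c("blink_events", "tbl_df", "tbl", "data.frame"))
}

#' Cut blink-locked epochs from a continuous series
#'
#' Extracts one epoch per event over `window_ms` relative to each blink peak,
#' with inclusive endpoints on the sample grid (so -500..1000 ms at 250 Hz is
#' 376 samples). Events whose window would run off either end of the
#' recording are dropped; the count of dropped events is stored in the
#' `n_dropped` attribute.
#'
#' @param series a [continuous_recording()], or a numeric matrix
#'   `series x samples`, or a numeric vector (single series).
#' @param events a `blink_events` tibble from [detect_blinks()], or an
#'   integer vector of peak samples.
#' @param fs sampling rate; taken from `series` when it is a recording.
#' @param window_ms two-element window in ms (default `c(-500, 1000)`).
#' @param labels optional condition label per event.
#' @param series_kind stored on the result (default `"channels"` for
#'   recordings, `"blink"` for vectors).
#' @return An [epoch_set()]; attribute `n_dropped` counts discarded events.
#' @export
epoch_blink_locked <- function(series, events, fs = NULL,
                               window_ms = c(-500, 1000), labels = NULL,
                               series_kind = NULL) {
  if (inherits(series, "continuous_recording")) {
    fs <- series$fs
    series_names <- series$channel_labels
    mat <- series$data
    series_kind <- series_kind %||% "channels"
  } else if (is.matrix(series)) {
    mat <- series
    series_names <- rownames(series)
    series_kind <- series_kind %||% "channels"
  } else {
    mat <- matrix(series, nrow = 1)
    series_names <- "BC"
    series_kind <- series_kind %||% "blink"
  }
  if (is.null(fs)) abort("`fs` is required when `series` is not a recording.")
  peaks <- if (is.data.frame(events)) events$peak_sample else as.integer(events)
  ord <- order(peaks)
  peaks <- peaks[ord]
  if (!is.null(labels)) labels <- labels[ord]

  lo <- round(window_ms[1] * fs / 1000)
  hi <- round(window_ms[2] * fs / 1000)
  t_ms <- seq(lo, hi) * 1000 / fs
  ok <- (peaks + lo) >= 1 & (peaks + hi) <= ncol(mat)
  n_dropped <- sum(!ok)
  peaks <- peaks[ok]
  if (!is.null(labels)) labels <- labels[ok]
  if (length(peaks) == 0) abort("No events with a full epoch window; empty epoch set.")

  arr <- array(0, dim = c(length(peaks), nrow(mat), length(t_ms)))
  for (i in seq_along(peaks)) {
    arr[i, , ] <- mat[, (peaks[i] + lo):(peaks[i] + hi), drop = FALSE]
  }
  es <- epoch_set(arr, t_ms, labels %||% rep("all", length(peaks)), fs,
                  series_kind, series_names)
  attr(es, "n_dropped") <- n_dropped
  attr(es, "event_samples") <- peaks
  es
}

#' Iteratively reject artifact epochs
#'
#' An epoch violates the absolute rule when any sample exceeds `abs_uv`
#' microvolts in magnitude, and the variance rule when the z-score of its
#' per-series SD against the across-epoch SD distribution exceeds
#' `sd_thresh` for any series. Violating epochs are removed worst-first, at
#' most `floor(max_frac_per_iter * n_current)` (but at least one when any
#' violate) per iteration, recomputing the SD statistics after each pass,
#' until no epoch violates either rule.
#'
#' @param epochs an [epoch_set()].
#' @param abs_uv absolute amplitude threshold in uV (default 500).
#' @param sd_thresh SD z-score threshold (default 5).
#' @param max_frac_per_iter per-iteration removal cap (default 0.10).
#' @return A list: `epochs` (cleaned [epoch_set()], labels in register) and
#'   `log` (tibble: `iteration`, `epoch`, `rule`, `score` for each removal).
#' @export
reject_epochs <- function(epochs, abs_uv = 500, sd_thresh = 5,
                          max_frac_per_iter = 0.10) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) == 0) abort("Empty epoch set.")
  kept <- seq_len(n_epochs(epochs))
  cur <- epochs
  log <- list()
  iter <- 0L
  repeat {
    iter <- iter + 1L
    n <- n_epochs(cur)
    absmax <- apply(abs(cur$data), 1, max)
    sds <- apply(cur$data, c(1, 2), sd)           # epochs x series
    mu <- colMeans(sds)
    sg <- apply(sds, 2, sd)
    sg[sg == 0] <- Inf                            # no spread -> no violation
    z <- sweep(sweep(sds, 2, mu), 2, sg, "/")
    zmax <- apply(z, 1, max)
    # severity relative to each rule's threshold; worst offenders first
    score <- pmax(absmax / abs_uv, zmax / sd_thresh)
    bad <- which(absmax > abs_uv | zmax > sd_thresh)
    if (length(bad) == 0) break
    cap <- max(1L, floor(max_frac_per_iter * n))
    drop <- bad[order(score[bad], decreasing = TRUE)][seq_len(min(cap, length(bad)))]
    rule <- ifelse(absmax[drop] > abs_uv, "absolute", "sd")
    log[[iter]] <- tibble(iteration = iter, epoch = kept[drop],
                          rule = rule, score = score[drop])
    if (length(drop) == n) abort("All epochs rejected.")
    keep_idx <- setdiff(seq_len(n), drop)
    cur <- epochs_subset(cur, keep_idx)
    kept <- kept[keep_idx]
  }
  list(epochs = cur,
       log = if (length(log)) dplyr::bind_rows(log) else
         tibble(iteration = integer(), epoch = integer(),
                rule = character(), score = numeric()))
}
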