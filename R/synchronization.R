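#' Global field power of the average blink-locked response
#'
#' Averages the epochs, then computes, at each time point, the spatial
#' standard deviation across channels of the average (the Lehmann-Skrandies
#' global field power: the population SD across channels, which is invariant
#' to adding a common offset to all channels at one instant). The GFP peak is
#' the argmax inside `search_window_ms` (default 0-500 ms post-blink, where
#' the blink-evoked response is expected).
#'
#' @param epochs a channel-space [epoch_set()] with at least 2 channels.
#' @param search_window_ms window for the peak search (default `c(0, 500)`).
#' @return A `gfp_profile`: tibble with `time_ms`, `gfp` (uV); attributes
#'   `peak_time_ms`, `peak_value`, `fs`, `boundary_peak` (TRUE when the
#'   argmax lies on the search-window edge, indicating possible truncation).
#' @export
compute_gfp <- function(epochs, search_window_ms = c(0, 500)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$series_kind != "channels") {
    abort("GFP is defined on channel-space epochs.")
  }
  if (n_series(epochs) < 2) abort("GFP is undefined for a single channel.")
  avg <- apply(epochs$data, c(2, 3), mean)            # channels x times
  mu <- colMeans(avg)
  gfp <- sqrt(colMeans(sweep(avg, 2, mu)^2))          # population SD
  in_win <- epochs$time_ms >= search_window_ms[1] &
    epochs$time_ms <= search_window_ms[2]
  if (!any(in_win)) abort("Search window contains no samples.")
  idx_win <- which(in_win)
  pk <- idx_win[which.max(gfp[idx_win])]
  structure(tibble(time_ms = epochs$time_ms, gfp = gfp),
            peak_time_ms = epochs$time_ms[pk],
            peak_value = gfp[pk],
            fs = epochs$fs,
            boundary_peak = pk == idx_win[1] || pk == idx_win[length(idx_win)],
            class = c("gfp_profile", "tbl_df", "tbl", "data.frame"))
}

#' Blink-to-GFP synchronization offset
#'
#' The offset is `delta_t = t_GFP_max - t_blink_max`: the latency of the
#' post-blink GFP maximum relative to the blink peak. Epochs are cut so the
#' blink peak sits at 0 ms, so `blink_peak_ms` defaults to 0; pass the
#' argmax of the mean blink trace to re-estimate it. Negative offsets are
#' preserved.
#'
#' @param gfp a `gfp_profile` from [compute_gfp()].
#' @param blink_peak_ms blink-peak latency in ms (default 0).
#' @param participant_id,condition bookkeeping columns for the result.
#' @return A `sync_offset` tibble (one row): `participant_id`, `condition`,
#'   `delta_t_ms`, `delta_t_samples` (= `round(delta_t_ms * fs / 1000)`),
#'   `t_blink_max_ms`, `peak_value`, `boundary_peak`.
#' @export
compute_offset <- function(gfp, blink_peak_ms = 0,
                           participant_id = "P01", condition = "pooled") {
  stopifnot(inherits(gfp, "gfp_profile"))
  fs <- attr(gfp, "fs")
  delta_ms <- attr(gfp, "peak_time_ms") - blink_peak_ms
  if (isTRUE(attr(gfp, "boundary_peak"))) {
    warn("GFP peak lies on the search-window boundary; offset may be truncated.")
  }
  new_sync_offset(tibble(
    participant_id = participant_id, condition = condition,
    delta_t_ms = delta_ms,
    delta_t_samples = as.integer(round(delta_ms * fs / 1000)),
    t_blink_max_ms = blink_peak_ms,
    peak_value = attr(gfp, "peak_value"),
    boundary_peak = isTRUE(attr(gfp, "boundary_peak"))
  ), fs)
}

new_sync_offset <- function(tbl, fs) {
  structure(tbl, fs = fs,
            class = c("sync_offset", "tbl_df", "tbl", "data.frame"))
}

#' Average synchronization offsets across conditions
#'
#' Per-participant standardized alignment: the arithmetic mean of the
#' per-condition offsets, re-quantized to the sample grid. All rows must
#' belong to one participant.
#'
#' @param offsets a `sync_offset` tibble (rows = conditions).
#' @return A one-row `sync_offset` with `condition = "pooled"`.
#' @export
average_offsets <- function(offsets) {
  stopifnot(inherits(offsets, "sync_offset"))
  if (nrow(offsets) == 0) abort("Empty offset list.")
  if (length(unique(offsets$participant_id)) != 1) {
    abort("Offsets from multiple participants; average per participant.")
  }
  fs <- attr(offsets, "fs")
  m <- mean(offsets$delta_t_ms)
  new_sync_offset(tibble(
    participant_id = offsets$participant_id[1], condition = "pooled",
    delta_t_ms = m,
    delta_t_samples = as.integer(round(m * fs / 1000)),
    t_blink_max_ms = mean(offsets$t_blink_max_ms),
    peak_value = mean(offsets$peak_value),
    boundary_peak = any(offsets$boundary_peak)
  ), fs)
}

#' Shift the blink signal into register with the evoked EEG
#'
#' Applies `BC_sync(t) = BC(t + delta_t)` per epoch on the sample grid: a
#' positive offset pulls later samples earlier so the blink peak lines up
#' with the GFP peak. Vacated samples at the edge are filled by replicating
#' the edge value (default) or with zeros.
#'
#' @param blink_epochs an [epoch_set()] (blink component, or its channel-space
#'   back-projection).
#' @param offset a one-row `sync_offset`, or an integer number of samples.
#' @param fill edge policy: `"replicate"` (default) or `"zero"`.
#' @return An [epoch_set()] of the same shape, shifted.
#' @export
shift_blink <- function(blink_epochs, offset, fill = c("replicate", "zero")) {
  stopifnot(inherits(blink_epochs, "epoch_set"))
  fill <- match.arg(fill)
  k <- if (inherits(offset, "data.frame")) {
    if (nrow(offset) != 1) abort("`offset` must be a single row; see average_offsets().")
    offset$delta_t_samples[1]
  } else as.integer(offset)
  nt <- n_times(blink_epochs)
  if (abs(k) >= nt) abort("Shift magnitude reaches the epoch length.")
  if (k == 0) return(blink_epochs)
  out <- blink_epochs
  src <- seq_len(nt) + k
  if (fill == "replicate") {
    src <- pmin(pmax(src, 1L), nt)
    out$data <- blink_epochs$data[, , src, drop = FALSE]
  } else {
    ok <- src >= 1 & src <= nt
    out$data[] <- 0
    out$data[, , which(ok)] <- blink_epochs$data[, , src[ok], drop = FALSE]
  }
  out
}

#' Align the blink signal to the post-blink GFP peak
#'
#' Applies the estimated offset in the registering direction: for a positive
#' offset (GFP peak after the blink peak) the blink is delayed so its peak
#' coincides with the GFP peak, putting blink and evoked-EEG dynamics in the
#' same feature windows. This is [shift_blink()] with the negated offset;
#' the raw primitive is kept separately because the shift formula is
#' conventionally written as an advance.
#'
#' @param blink_epochs an [epoch_set()] (blink component or its channel-space
#'   back-projection).
#' @param offset a one-row `sync_offset`, or an integer number of samples.
#' @param fill edge policy passed to [shift_blink()].
#' @return An [epoch_set()] with the blink peak registered to the GFP peak.
#' @export
align_blink <- function(blink_epochs, offset, fill = c("replicate", "zero")) {
  k <- if (inherits(offset, "data.frame")) offset$delta_t_samples[1] else
    as.integer(offset)
  shift_blink(blink_epochs, -k, fill = match.arg(fill))
}

#' Estimate per-condition and pooled offsets for an epoch set
#'
#' Convenience wrapper: computes the GFP offset per condition (re-estimating
#' the blink-peak latency from the mean blink trace, which is ~0 by epoch
#' construction), then the per-participant pooled average used for alignment.
#'
#' @param eeg_epochs channel-space [epoch_set()].
#' @param blink_epochs blink-component [epoch_set()] (1 series), or NULL to
#'   take the blink peak latency as 0.
#' @param search_window_ms GFP peak search window.
#' @param participant_id bookkeeping.
#' @return A `sync_offset` tibble: one row per condition plus a `"pooled"`
#'   row.
#' @export
estimate_offsets <- function(eeg_epochs, blink_epochs = NULL,
                             search_window_ms = c(0, 500),
                             participant_id = "P01") {
  stopifnot(inherits(eeg_epochs, "epoch_set"))
  blink_peak_ms <- 0
  if (!is.null(blink_epochs)) {
    mb <- apply(blink_epochs$data[, 1, , drop = FALSE], 3, mean)
    blink_peak_ms <- blink_epochs$time_ms[which.max(mb)]
  }
  conds <- unique(eeg_epochs$labels)
  rows <- purrr::map(conds, function(cn) {
    sub <- epochs_subset(eeg_epochs, eeg_epochs$labels == cn)
    compute_offset(compute_gfp(sub, search_window_ms),
                   blink_peak_ms = blink_peak_ms,
                   participant_id = participant_id, condition = cn)
  })
  per_cond <- new_sync_offset(dplyr::bind_rows(rows), attr(rows[[1]], "fs"))
  pooled <- average_offsets(per_cond)
  new_sync_offset(dplyr::bind_rows(per_cond, pooled), attr(pooled, "fs"))
}
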