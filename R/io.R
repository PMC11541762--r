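#' Read a continuous recording from a delimited text file
#'
#' Expects a CSV with one column per channel (header = channel labels) and
#' one row per sample, in microvolts.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param participant_id identifier attached to the recording.
#' @return A [continuous_recording()].
#' @export
read_recording_csv <- function(path, fs, participant_id = "P01") {
  df <- read.csv(path, check.names = FALSE)
  continuous_recording(t(as.matrix(df)), fs, colnames(df), participant_id)
}

#' Write a continuous recording to CSV
#'
#' @param rec a [continuous_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  colnames(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table (columns: sample, label)
#'
#' @param path CSV path with integer `sample` (1-based) and `label` columns.
#' @return A tibble sorted by sample.
#' @export
read_event_table <- function(path) {
  df <- read.csv(path)
  if (!all(c("sample", "label") %in% names(df))) {
    abort("Event table must have columns `sample` and `label`.")
  }
  as_tibble(df[order(df$sample), c("sample", "label")])
}

#' Read a delimited unmixing (or mixing) matrix
#'
#' Plain CSV of numbers, no header: rows = components, columns = channels
#' (or the transpose for a mixing matrix).
#'
#' @param path CSV path.
#' @return A numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  as.matrix(read.csv(path, header = FALSE))
}

#' Write epochs to a long-format CSV container
#'
#' Columns `epoch`, `series`, `time_ms`, `value`, `label`, with the sampling
#' rate and series kind stored in a `# key: value` comment header.
#'
#' @param epochs an [epoch_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epochs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs: %g", epochs$fs), con)
  writeLines(sprintf("# series_kind: %s", epochs$series_kind), con)
  write.csv(as_tibble(epochs), con, row.names = FALSE)
  invisible(path)
}

#' Read epochs from the long-format CSV container
#'
#' @param path a file written by [write_epochs_csv()].
#' @return An [epoch_set()].
#' @export
read_epochs_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  get <- function(key) sub(sprintf("^# %s: ", key), "", grep(key, hdr, value = TRUE)[1])
  fs <- as.numeric(get("fs"))
  kind <- get("series_kind")
  df <- read.csv(path, comment.char = "#")
  series <- unique(df$series)
  t_ms <- sort(unique(df$time_ms))
  eps <- sort(unique(df$epoch))
  arr <- array(0, dim = c(length(eps), length(series), length(t_ms)))
  arr[cbind(match(df$epoch, eps), match(df$series, series),
            match(df$time_ms, t_ms))] <- df$value
  labels <- df$label[!duplicated(df$epoch)][order(eps)]
  epoch_set(arr, t_ms, labels, fs, kind, series)
}

#' Write a run manifest to JSON
#'
#' @param run a `blinkfuse_run` from [run_pipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest_json <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
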