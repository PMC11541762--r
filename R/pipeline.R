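#' Configuration for an end-to-end decoding run
#'
#' Bundles the input (a [sim_config()] for synthetic data, or paths to a
#' delimited recording plus event table), the method set to compare, and the
#' decoding/statistics parameters. All requested methods are decoded on
#' identical trial splits so contrasts are paired.
#'
#' @param sim a [sim_config()] (synthetic input), or NULL when reading files.
#' @param recording_path,events_path optional input files (delimited
#'   recording, CSV event table with columns `sample`, `label`); checked at
#'   construction time.
#' @param fs sampling rate of a file-based recording.
#' @param methods subset of `"pcEEG+"`, `"pcEEG"`, `"syncBlink"`, `"CCA"`,
#'   `"rawEEG"`.
#' @param contrast NULL for multi-class decoding over all conditions, or a
#'   condition name for that-condition-vs-rest (others pooled, then
#'   balanced).
#' @param n_epochs_per_condition epochs per condition for synthetic input.
#' @param window_ms,step_samples,repetitions,test_frac,C decoding parameters.
#' @param tgm also compute a temporal generalization matrix per method.
#' @param alpha,n_perm statistics parameters (used by [cohort_stats()]).
#' @param seed master seed; all stage seeds derive from it.
#' @return A validated `run_config` list.
#' @export
run_config <- function(sim = NULL, recording_path = NULL, events_path = NULL,
                       fs = NULL,
                       methods = c("pcEEG+", "pcEEG", "syncBlink"),
                       contrast = NULL, n_epochs_per_condition = 100,
                       window_ms = 50, step_samples = 1, repetitions = 5,
                       test_frac = 0.20, C = 1, tgm = FALSE,
                       alpha = 0.05, n_perm = 1000, seed = 1L) {
  known <- c("pcEEG+", "pcEEG", "syncBlink", "CCA", "rawEEG")
  if (length(methods) == 0 || !all(methods %in% known)) {
    abort(sprintf("`methods` must be a non-empty subset of: %s.",
                  paste(known, collapse = ", ")))
  }
  if (is.null(sim)) {
    if (is.null(recording_path) || is.null(events_path)) {
      abort("Provide either `sim` or both `recording_path` and `events_path`.")
    }
    for (p in c(recording_path, events_path)) {
      if (!file.exists(p)) abort(sprintf("Input path not found: %s", p))
    }
    if (is.null(fs)) abort("`fs` is required for file-based input.")
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(sim = sim, recording_path = recording_path,
                 events_path = events_path, fs = fs, methods = methods,
                 contrast = contrast,
                 n_epochs_per_condition = n_epochs_per_condition,
                 window_ms = window_ms, step_samples = step_samples,
                 repetitions = repetitions, test_frac = test_frac, C = C,
                 tgm = tgm, alpha = alpha, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the end-to-end comparison pipeline
#'
#' simulate (or load) -> synchronize -> fuse -> decode, executing every
#' requested method on identical stratified folds. The returned manifest
#' records seeds, parameters, per-stage counts and the estimated offsets.
#'
#' @param config a [run_config()].
#' @param participant_id identifier recorded in outputs.
#' @return A `blinkfuse_run`: list with `curves` (tibble with a `method`
#'   column), `offsets` (a `sync_offset` tibble), `tgms` (named list or
#'   NULL), `manifest` (list).
#' @export
run_pipeline <- function(config, participant_id = "P01") {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed

  sim <- stage("input", {
    if (!is.null(config$sim)) {
      simulate_epochset(config$sim, config$n_epochs_per_condition,
                        participant_id = participant_id)
    } else {
      load_file_input(config, participant_id)
    }
  })
  eeg <- sim$eeg; blink <- sim$blink

  offsets <- stage("synchronize",
                   estimate_offsets(eeg, blink, participant_id = participant_id))
  pooled <- offsets[offsets$condition == "pooled", ]
  blink_sync <- stage("synchronize", align_blink(blink, pooled))

  labels <- eeg$labels
  if (!is.null(config$contrast)) labels <- pool_rest(labels, config$contrast)
  kept <- stage("balance", balance_classes(labels, seed = child_seed(seed, 1)))
  eeg_b <- epochs_subset(eeg, kept); eeg_b$labels <- labels[kept]
  blink_b <- epochs_subset(blink_sync, kept); blink_b$labels <- labels[kept]

  folds <- make_folds(eeg_b$labels, config$repetitions, config$test_frac,
                      seed = child_seed(seed, 2))

  streams <- stage("fuse", {
    s <- list()
    needs_pca <- any(c("pcEEG", "pcEEG+") %in% config$methods)
    pca <- if (needs_pca) fit_pca_select(eeg_b) else NULL
    if ("rawEEG" %in% config$methods) s$rawEEG <- eeg_b
    if ("pcEEG" %in% config$methods) s$pcEEG <- pca$pc_epochs
    if ("syncBlink" %in% config$methods) s$syncBlink <- blink_b
    if ("pcEEG+" %in% config$methods) s[["pcEEG+"]] <- fuse_concat(pca, blink_b)
    if ("CCA" %in% config$methods) {
      bcs <- blink_to_channelspace(blink_b, sim$truth$mixing)
      s$CCA <- fuse_cca(fit_cca(eeg_b, bcs))
    }
    s[config$methods[config$methods %in% names(s)]]
  })

  curves <- stage("decode", {
    dplyr::bind_rows(lapply(names(streams), function(m) {
      cv <- decode_timecourse(streams[[m]], config$window_ms,
                              config$step_samples, C = config$C,
                              folds = folds)
      dplyr::mutate(tibble::as_tibble(cv), method = m, .before = 1)
    }))
  })

  tgms <- NULL
  if (config$tgm) {
    tgms <- stage("tgm", {
      setNames(lapply(names(streams), function(m) {
        temporal_generalization(streams[[m]], config$window_ms,
                                config$step_samples, C = config$C,
                                folds = folds)
      }), names(streams))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("blinkfuse")),
    participant_id = participant_id, seed = seed,
    methods = config$methods, contrast = config$contrast,
    window_ms = config$window_ms, step_samples = config$step_samples,
    repetitions = config$repetitions, test_frac = config$test_frac,
    C = config$C,
    n_epochs_input = n_epochs(eeg), n_epochs_balanced = n_epochs(eeg_b),
    conditions = unique(eeg$labels),
    offsets = as.data.frame(offsets)
  )
  structure(list(curves = curves, offsets = offsets, tgms = tgms,
                 manifest = manifest),
            class = "blinkfuse_run")
}

#' @export
print.blinkfuse_run <- function(x, ...) {
  pk <- x$curves |>
    dplyr::group_by(.data$method) |>
    dplyr::slice_max(.data$acc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cat(sprintf("<blinkfuse_run: %s | %d balanced epochs>\n",
              x$manifest$participant_id, x$manifest$n_epochs_balanced))
  for (i in seq_len(nrow(pk))) {
    cat(sprintf("  %-10s peak %.1f%% at %g ms\n",
                pk$method[i], pk$acc[i], pk$center_ms[i]))
  }
  invisible(x)
}

# back-project the single blink component through its mixing column (BCS)
blink_to_channelspace <- function(blink_epochs, mixing,
                                  column = "blink") {
  col <- if (is.character(column)) mixing[, column] else mixing[, column]
  d <- dim(blink_epochs$data)
  arr <- array(0, dim = c(d[1], length(col), d[3]))
  for (i in seq_len(d[1])) {
    arr[i, , ] <- col %o% blink_epochs$data[i, 1, ]
  }
  epoch_set(arr, blink_epochs$time_ms, blink_epochs$labels, blink_epochs$fs,
            "channels", names(col) %||% sprintf("CH%02d", seq_along(col)))
}

# file-based input: delimited recording + CSV event table -> epoch streams
load_file_input <- function(config, participant_id) {
  rec <- read_recording_csv(config$recording_path, fs = config$fs,
                            participant_id = participant_id)
  ev <- read_event_table(config$events_path)
  rec <- preprocess(rec, target_fs = rec$fs)
  decomp <- decompose_components(rec, seed = child_seed(config$seed, 9))
  bc <- identify_blink_component(decomp,
                                 left_anterior = rec$channel_labels[1],
                                 right_anterior = rec$channel_labels[2])
  eeg_clean <- remove_components(rec, decomp, drop = bc)
  eeg <- epoch_blink_locked(eeg_clean, ev$sample, labels = ev$label)
  blink <- epoch_blink_locked(decomp$activations[bc, ], ev$sample,
                              fs = rec$fs, labels = ev$label,
                              series_kind = "blink")
  mixing <- decomp$mixing
  colnames(mixing) <- ifelse(seq_len(ncol(mixing)) == bc, "blink",
                             sprintf("IC%02d", seq_len(ncol(mixing))))
  list(eeg = eeg, blink = blink,
       truth = list(mixing = mixing, labels = eeg$labels,
                    participant_id = participant_id))
}

#' Remove components from a recording by back-projection
#'
#' Reconstructs the channel data from all components except `drop`.
#'
#' @param rec a [continuous_recording()].
#' @param decomp a [component_decomposition()] with activations.
#' @param drop integer indices of components to remove.
#' @return A [continuous_recording()] with the components removed.
#' @export
remove_components <- function(rec, decomp, drop) {
  keep <- setdiff(seq_len(nrow(decomp$unmixing)), drop)
  data <- decomp$mixing[, keep, drop = FALSE] %*%
    decomp$activations[keep, , drop = FALSE]
  continuous_recording(data, rec$fs, rec$channel_labels, rec$participant_id)
}

#' Paired cohort statistics between two methods
#'
#' Given one [run_pipeline()] result per participant, compares two methods
#' with pointwise paired t-tests (FDR-corrected) on the decoding curves and,
#' when TGMs were computed, an extreme-pixel permutation test on the
#' per-participant TGM difference maps.
#'
#' @param runs list of `blinkfuse_run` objects (one per participant).
#' @param method_a,method_b method names present in every run.
#' @param alpha_t level for the curve contrast (default 0.05).
#' @param alpha_perm two-tailed level for the TGM contrast (default 0.01).
#' @param n_perm permutations (default 1000).
#' @param seed seed for the permutation draw.
#' @return A list: `curve_test` (a `paired_test`), `tgm_test` (a `perm_null`
#'   or NULL).
#' @export
cohort_stats <- function(runs, method_a, method_b, alpha_t = 0.05,
                         alpha_perm = 0.01, n_perm = 1000, seed = 1L) {
  get_curve <- function(r, m) {
    cv <- r$curves[r$curves$method == m, ]
    if (nrow(cv) == 0) abort(sprintf("Method '%s' missing from a run.", m))
    cv$acc
  }
  a <- do.call(rbind, lapply(runs, get_curve, method_a))
  b <- do.call(rbind, lapply(runs, get_curve, method_b))
  curve_test <- paired_t_fdr(a, b, alpha = alpha_t)
  tgm_test <- NULL
  if (!is.null(runs[[1]]$tgms)) {
    maps <- lapply(runs, function(r) {
      r$tgms[[method_a]]$scores - r$tgms[[method_b]]$scores
    })
    tgm_test <- extreme_pixel_permutation(maps, n_perm = n_perm,
                                          alpha = alpha_perm, seed = seed)
  }
  list(curve_test = curve_test, tgm_test = tgm_test)
}
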