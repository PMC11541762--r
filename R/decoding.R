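#' Sliding-window length in samples
#'
#' `ceiling(window_ms * fs / 1000)`, rounded up to an odd count so the window
#' is centered on a sample: 50 ms at 250 Hz gives 13 samples.
#'
#' @param window_ms window length in ms.
#' @param fs sampling rate in Hz.
#' @return Odd integer sample count.
#' @export
window_samples <- function(window_ms, fs) {
  n <- as.integer(ceiling(window_ms * fs / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Enumerate sliding-window positions over an epoch grid
#'
#' @param epochs an [epoch_set()] (any series kind).
#' @param window_ms window length in ms (default 50).
#' @param step_samples stride between consecutive windows (default 1).
#' @return A tibble: `window` (index), `start` (first in-window sample,
#'   1-based), `center_ms` (time of the center sample); attribute
#'   `window_samples`.
#' @export
slide_windows <- function(epochs, window_ms = 50, step_samples = 1) {
  stopifnot(inherits(epochs, "epoch_set"))
  w <- window_samples(window_ms, epochs$fs)
  nt <- n_times(epochs)
  if (w > nt) abort("Window longer than the epoch.")
  starts <- seq(1L, nt - w + 1L, by = step_samples)
  out <- tibble(window = seq_along(starts), start = starts,
                center_ms = epochs$time_ms[starts + (w - 1L) %/% 2L])
  attr(out, "window_samples") <- w
  out
}

#' Assemble the feature matrix for one window position
#'
#' Flattens `series x in-window samples` per trial: with 5 series and a
#' 13-sample window over 500 trials the result is 65 x 500.
#'
#' @param epochs an [epoch_set()].
#' @param start first in-window sample (1-based).
#' @param w window length in samples.
#' @return Numeric matrix `n_features x n_trials`
#'   (`n_features = n_series * w`).
#' @export
window_features <- function(epochs, start, w) {
  d <- dim(epochs$data)
  if (start < 1 || start + w - 1 > d[3]) abort("Window exceeds the epoch grid.")
  sub <- epochs$data[, , start:(start + w - 1L), drop = FALSE]
  m <- aperm(sub, c(2, 3, 1))         # series x times x epochs
  dim(m) <- c(d[2] * w, d[1])
  m
}

#' Balance classes by downsampling to the minority count
#'
#' @param labels condition label per trial.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return Sorted integer indices of kept trials.
#' @export
balance_classes <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2) abort("Need at least two classes.")
  if (any(tab == 0)) abort("Empty class.")
  n_min <- min(tab)
  with_rng(seed, {
    kept <- unlist(lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  sort(kept)
}

# stratified train/test folds shared across methods and windows
make_folds <- function(labels, repetitions = 5, test_frac = 0.20, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  with_rng(seed, {
    lapply(seq_len(repetitions), function(r) {
      test <- unlist(lapply(classes, function(cl) {
        idx <- which(labels == cl)
        n_test <- max(1L, round(test_frac * length(idx)))
        sample(idx, n_test)
      }))
      test <- sort(test)
      list(train = setdiff(seq_along(labels), test), test = test)
    })
  })
}

# ---- linear SVM (one-vs-rest for k > 2) ------------------------------------

# fit on trials x features; returns per-class weight vectors and offsets
fit_linear_svm <- function(x, y, C = 1) {
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("Training fold is missing a class.")
  models <- lapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    m <- e1071::svm(x = x, y = yy, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
    w <- drop(t(m$coefs) %*% m$SV)
    b <- -m$rho
    dec <- drop(x %*% w) + b
    if (mean(dec[y == cl]) < mean(dec[y != cl])) { w <- -w; b <- -b }
    list(w = w, b = b)
  })
  list(classes = classes, models = models)
}

predict_linear_svm <- function(fit, x) {
  dec <- vapply(fit$models, function(m) drop(x %*% m$w) + m$b,
                numeric(nrow(x)))
  if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
  fit$classes[max.col(dec, ties.method = "first")]
}

# ---- metrics ---------------------------------------------------------------

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `Acc = 100 (TP + TN) / (TP + TN + FP + FN)`, `Sen = 100 TP / (TP + FN)`,
#' `Spe = 100 TN / (TN + FP)`. When `TP + FN = 0` sensitivity is undefined
#' and reported as `NA` with a warning (never silently 0); likewise for
#' specificity when `TN + FP = 0`.
#'
#' @param tp,tn,fp,fn non-negative integer counts (vectorized over classes).
#' @return A tibble with columns `acc`, `sen`, `spe` in percent.
#' @export
evaluate_metrics <- function(tp, tn, fp, fn) {
  total <- tp + tn + fp + fn
  if (any(total <= 0)) abort("Confusion counts sum to zero.")
  sen <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  spe <- ifelse(tn + fp > 0, 100 * tn / (tn + fp), NA_real_)
  if (anyNA(sen)) warn("Sensitivity undefined (no positive trials); reported as NA.")
  if (anyNA(spe)) warn("Specificity undefined (no negative trials); reported as NA.")
  tibble(acc = 100 * (tp + tn) / total, sen = sen, spe = spe)
}

# macro-averaged one-vs-rest metrics from a confusion matrix (rows = truth)
confusion_macro <- function(cm) {
  n <- sum(cm)
  classes <- rownames(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[cl, ]) - tp
    fp <- sum(cm[, cl]) - tp
    tn <- n - tp - fn - fp
    c(tp = tp, tn = tn, fp = fp, fn = fn)
  })
  counts <- do.call(rbind, per)
  m <- suppressWarnings(
    evaluate_metrics(counts[, "tp"], counts[, "tn"], counts[, "fp"], counts[, "fn"]))
  tibble(acc = 100 * sum(diag(cm)) / n,
         sen = mean(m$sen, na.rm = TRUE),
         spe = mean(m$spe, na.rm = TRUE))
}

# z-score columns by train-set statistics; zero-SD features get scale 1
train_scaler <- function(x_train) {
  mu <- colMeans(x_train)
  sg <- apply(x_train, 2, sd)
  n_flat <- sum(sg == 0)
  sg[sg == 0] <- 1
  list(mu = mu, sd = sg, n_flat_features = n_flat)
}

apply_scaler <- function(x, sc) sweep(sweep(x, 2, sc$mu), 2, sc$sd, "/")

#' Cross-validated linear-SVM decoding of one feature matrix
#'
#' Five-repetition (by default) cross-validation: per repetition a stratified
#' random 80/20 train/test split, z-scoring of features with train-set mean
#' and SD only, a linear SVM (one-vs-rest for more than two classes), and
#' test-set confusion counts. Metrics are averaged over repetitions.
#'
#' @param features `n_features x n_trials` matrix (see [window_features()]).
#' @param labels condition per trial (should be balanced; see
#'   [balance_classes()]).
#' @param repetitions number of CV repetitions (default 5).
#' @param test_frac held-out fraction (default 0.20).
#' @param seed seed for the splits (ignored when `folds` given).
#' @param C SVM cost parameter (default 1).
#' @param folds optional fold list from a previous run, to pair methods.
#' @return A one-row tibble `acc`, `sen`, `spe`, `acc_sd`, `chance`;
#'   attributes `per_rep` (tibble), `folds`, `scalers` (train-set
#'   normalization parameters per repetition).
#' @export
cross_validated_decode <- function(features, labels, repetitions = 5,
                                   test_frac = 0.20, seed = 1L, C = 1,
                                   folds = NULL) {
  labels <- as.character(labels)
  if (ncol(features) != length(labels)) abort("One label per trial required.")
  if (length(labels) < 10) abort("Too few trials for cross-validation.")
  if (anyNA(features)) abort("Features contain NA.")
  if (is.null(folds)) folds <- make_folds(labels, repetitions, test_frac, seed)
  xt <- t(features)                    # trials x features
  classes <- sort(unique(labels))
  per_rep <- vector("list", length(folds))
  scalers <- vector("list", length(folds))
  for (r in seq_along(folds)) {
    tr <- folds[[r]]$train; te <- folds[[r]]$test
    sc <- train_scaler(xt[tr, , drop = FALSE])
    scalers[[r]] <- sc
    fit <- fit_linear_svm(apply_scaler(xt[tr, , drop = FALSE], sc),
                          labels[tr], C = C)
    pred <- predict_linear_svm(fit, apply_scaler(xt[te, , drop = FALSE], sc))
    cm <- table(factor(labels[te], levels = classes),
                factor(pred, levels = classes))
    per_rep[[r]] <- confusion_macro(as.matrix(cm))
  }
  reps <- dplyr::bind_rows(per_rep)
  out <- tibble(acc = mean(reps$acc), sen = mean(reps$sen),
                spe = mean(reps$spe), acc_sd = sd(reps$acc),
                chance = 100 / length(classes))
  attr(out, "per_rep") <- reps
  attr(out, "folds") <- folds
  attr(out, "scalers") <- scalers
  out
}

#' Sliding-window decoding time course
#'
#' Runs [cross_validated_decode()] at every window position with one shared
#' set of stratified folds, so curves from different feature streams are
#' paired trial-for-trial.
#'
#' @param epochs an [epoch_set()] (fused or single-stream).
#' @param window_ms,step_samples window geometry (defaults 50 ms, stride 1).
#' @param repetitions,test_frac,seed,C,folds as [cross_validated_decode()].
#' @return A `decoding_curve` tibble: `window`, `center_ms`, `acc`, `sen`,
#'   `spe`, `acc_sd`, `chance`; attribute `folds`.
#' @export
decode_timecourse <- function(epochs, window_ms = 50, step_samples = 1,
                              repetitions = 5, test_frac = 0.20, seed = 1L,
                              C = 1, folds = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  wins <- slide_windows(epochs, window_ms, step_samples)
  w <- attr(wins, "window_samples")
  if (is.null(folds)) folds <- make_folds(epochs$labels, repetitions, test_frac, seed)
  rows <- purrr::map(seq_len(nrow(wins)), function(i) {
    fm <- window_features(epochs, wins$start[i], w)
    cross_validated_decode(fm, epochs$labels, C = C, folds = folds)
  })
  out <- dplyr::bind_cols(wins, dplyr::bind_rows(rows))
  attr(out, "folds") <- folds
  class(out) <- c("decoding_curve", class(out))
  out
}

#' Temporal generalization matrix
#'
#' For every training window, fits the classifier on the training folds
#' (z-scored with that window's train-set statistics) and evaluates it at
#' every test window, normalizing the test trials with the training window's
#' parameters. With shared folds the diagonal reproduces the sliding-window
#' time course exactly.
#'
#' @param epochs an [epoch_set()].
#' @param window_ms,step_samples window geometry.
#' @param repetitions,test_frac,seed,C,folds as [cross_validated_decode()].
#' @return A `tgm` object: list with `scores` (`n_train x n_test` mean
#'   accuracy, %), `center_ms` (window centers), `folds`, `chance`.
#' @export
temporal_generalization <- function(epochs, window_ms = 50, step_samples = 1,
                                    repetitions = 5, test_frac = 0.20,
                                    seed = 1L, C = 1, folds = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  wins <- slide_windows(epochs, window_ms, step_samples)
  w <- attr(wins, "window_samples")
  labels <- epochs$labels
  classes <- sort(unique(labels))
  if (is.null(folds)) folds <- make_folds(labels, repetitions, test_frac, seed)
  nw <- nrow(wins)
  feats <- lapply(wins$start, function(s) t(window_features(epochs, s, w)))
  acc <- array(0, dim = c(length(folds), nw, nw))
  for (r in seq_along(folds)) {
    tr <- folds[[r]]$train; te <- folds[[r]]$test
    for (i in seq_len(nw)) {
      sc <- train_scaler(feats[[i]][tr, , drop = FALSE])
      fit <- fit_linear_svm(apply_scaler(feats[[i]][tr, , drop = FALSE], sc),
                            labels[tr], C = C)
      for (j in seq_len(nw)) {
        pred <- predict_linear_svm(fit, apply_scaler(feats[[j]][te, , drop = FALSE], sc))
        cm <- table(factor(labels[te], levels = classes),
                    factor(pred, levels = classes))
        acc[r, i, j] <- 100 * sum(diag(as.matrix(cm))) / length(te)
      }
    }
  }
  structure(list(scores = apply(acc, c(2, 3), mean),
                 center_ms = wins$center_ms, folds = folds,
                 chance = 100 / length(classes)),
            class = "tgm")
}

#' @export
print.tgm <- function(x, ...) {
  cat(sprintf("<tgm: %d x %d windows, %g..%g ms, max %.1f%% (chance %.1f%%)>\n",
              nrow(x$scores), ncol(x$scores), min(x$center_ms),
              max(x$center_ms), max(x$scores), x$chance))
  invisible(x)
}

#' Pool conditions into a one-vs-rest contrast
#'
#' Relabels trials as the target condition vs `"rest"` (all other conditions
#' pooled). Balancing is applied after pooling by [balance_classes()].
#'
#' @param labels condition per trial.
#' @param positive the target condition.
#' @return Character vector of `positive` / `"rest"` labels.
#' @export
pool_rest <- function(labels, positive) {
  if (!positive %in% labels) abort("`positive` is not among the labels.")
  ifelse(labels == positive, positive, "rest")
}
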