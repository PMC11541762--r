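test_that("50 ms at 250 Hz spans 13 samples and windows count as n - w + 1", {
  expect_equal(window_samples(50, 250), 13L)
  arr <- array(rnorm(4 * 2 * 376), dim = c(4, 2, 376))
  es <- epoch_set(arr, seq(-500, 1000, by = 4), rep(c("A", "B"), 2), 250,
                  "channels")
  wins <- slide_windows(es)
  expect_equal(nrow(wins), 376 - 13 + 1)
  expect_error(slide_windows(toy_epochs(array(0, dim = c(1, 1, 5))), 50),
               "longer")
})

test_that("feature matrices are series x window samples by trials", {
  arr <- array(rnorm(500 * 5 * 40), dim = c(500, 5, 40))
  es <- toy_epochs(arr, kind = "components",
                   labels = rep(c("A", "B"), 250))
  fm <- window_features(es, start = 10, w = 13)
  expect_equal(dim(fm), c(65L, 500L))
  # with one appended blink series the fused matrix is 78 x 500
  blink <- toy_epochs(array(rnorm(500 * 40), dim = c(500, 1, 40)),
                      kind = "blink", labels = es$labels)
  fused <- fuse_concat(es, blink)
  expect_equal(dim(window_features(fused, 10, 13)), c(78L, 500L))
})

test_that("class balancing downsamples to the minority count, deterministically", {
  labs <- c(rep("A", 600), rep("B", 467))
  kept <- balance_classes(labs, seed = 3L)
  expect_equal(as.integer(table(labs[kept])), c(467L, 467L))
  expect_identical(kept, balance_classes(labs, seed = 3L))
  expect_identical(balance_classes(rep(c("A", "B"), 250), seed = 1L), 1:500)
  expect_error(balance_classes(rep("A", 10)), "two classes")
})

test_that("metric identities match the confusion-count formulas", {
  m <- evaluate_metrics(tp = 30, tn = 40, fp = 20, fn = 10)
  expect_equal(m$acc, 70.0)
  expect_equal(m$sen, 75.0)
  expect_equal(m$spe, 200 / 3, tolerance = 1e-10)

  perfect <- evaluate_metrics(tp = 50, tn = 50, fp = 0, fn = 0)
  expect_equal(unlist(perfect), c(acc = 100, sen = 100, spe = 100))

  expect_warning(deg <- evaluate_metrics(tp = 0, tn = 100, fp = 0, fn = 0),
                 "Sensitivity undefined")
  expect_equal(deg$spe, 100)
  expect_true(is.na(deg$sen))
})

test_that("balanced k-class macro metrics obey Spe = 100 - (100 - Acc)/(k - 1)", {
  set.seed(31)
  for (k in 2:4) {
    n <- 60 * k
    truth <- rep(letters[1:k], each = 60)
    pred <- truth
    flip <- sample(n, round(0.3 * n))
    pred[flip] <- vapply(truth[flip], function(cl) {
      sample(setdiff(letters[1:k], cl), 1)
    }, character(1))
    cm <- as.matrix(table(factor(truth, levels = letters[1:k]),
                          factor(pred, levels = letters[1:k])))
    m <- blinkfuse:::confusion_macro(cm)
    expect_equal(m$spe, 100 - (100 - m$acc) / (k - 1), tolerance = 1e-10)
    expect_equal(m$sen, m$acc, tolerance = 1e-10)  # balanced classes
  }
})

test_that("perfectly separable classes decode at 100% in every repetition", {
  set.seed(17)
  x <- rbind(matrix(rnorm(40 * 3, mean = 5), 40),
             matrix(rnorm(40 * 3, mean = -5), 40))
  res <- cross_validated_decode(t(x), rep(c("A", "B"), each = 40), seed = 2L)
  expect_equal(res$acc, 100)
  expect_equal(attr(res, "per_rep")$acc, rep(100, 5))
})

test_that("decoding permuted labels stays inside the binomial chance band", {
  set.seed(23)
  n <- 150  # 3 classes x 50 trials, 30 test trials per repetition
  x <- matrix(rnorm(n * 6), n, 6)
  labs <- sample(rep(c("a", "b", "c"), each = 50))
  res <- cross_validated_decode(t(x), labs, repetitions = 5, seed = 4L)
  n_test <- 5 * 30
  band <- 100 * qbinom(c(0.025, 0.975), n_test, 1 / 3) / n_test
  expect_gte(res$acc, band[1] - 1e-9)
  expect_lte(res$acc, band[2] + 1e-9)
})

test_that("decoding is deterministic under a fixed seed", {
  set.seed(5)
  x <- matrix(rnorm(60 * 4), 60, 4)
  labs <- rep(c("A", "B"), 30)
  r1 <- cross_validated_decode(t(x), labs, seed = 11L)
  r2 <- cross_validated_decode(t(x), labs, seed = 11L)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("test-set normalization uses train-set parameters only", {
  set.seed(9)
  x <- matrix(rnorm(60 * 4), 60, 4)
  labs <- rep(c("A", "B"), 30)
  folds <- blinkfuse:::make_folds(labs, 5, 0.2, 1L)
  r1 <- cross_validated_decode(t(x), labs, folds = folds)
  # corrupt the scale of one fold's test trials: that fold's train-set
  # normalization parameters must not move
  x2 <- x
  x2[folds[[1]]$test, ] <- x2[folds[[1]]$test, ] * 100
  r2 <- cross_validated_decode(t(x2), labs, folds = folds[1])
  expect_identical(attr(r1, "scalers")[[1]], attr(r2, "scalers")[[1]])
})

test_that("zero-variance features are scaled by 1, not dropped", {
  set.seed(13)
  x <- cbind(matrix(rnorm(40 * 2), 40, 2), 7)  # constant third feature
  labs <- rep(c("A", "B"), 20)
  res <- cross_validated_decode(t(x), labs, seed = 1L)
  expect_true(all(vapply(attr(res, "scalers"),
                         function(s) s$n_flat_features == 1L, logical(1))))
  expect_true(is.finite(res$acc))
})

test_that("TGM diagonal equals the sliding-window curve under shared folds", {
  cfg <- quick_config(n_channels = 6, evoked_lag = c(A = 120, B = 200),
                      snr = 2, seed = 51L)
  out <- simulate_epochset(cfg, 20)
  pcs <- fit_pca_select(out$eeg)
  folds <- blinkfuse:::make_folds(out$eeg$labels, 3, 0.2, 7L)
  curve <- decode_timecourse(pcs$pc_epochs, step_samples = 40, folds = folds)
  tg <- temporal_generalization(pcs$pc_epochs, step_samples = 40, folds = folds)
  expect_equal(diag(tg$scores), curve$acc, tolerance = 1e-10)
  expect_equal(tg$center_ms, curve$center_ms)
})

test_that("a time-locked effect concentrates TGM scores near the diagonal band", {
  cfg <- quick_config(n_channels = 6,
                      evoked_lag = c(A = 150, B = 200),
                      evoked_amp_by_condition = c(A = 1, B = 1.5),
                      snr = 4, seed = 61L)
  out <- simulate_epochset(cfg, 40)
  pcs <- fit_pca_select(out$eeg)
  tg <- temporal_generalization(pcs$pc_epochs, step_samples = 25,
                                repetitions = 3, seed = 5L)
  on_effect <- tg$center_ms >= 100 & tg$center_ms <= 250
  off_effect <- tg$center_ms <= -100
  diag_scores <- diag(tg$scores)
  expect_gt(mean(diag_scores[on_effect]), mean(diag_scores[off_effect]) + 10)
  # off-diagonal far cells show no generalization from the effect band
  far <- tg$scores[on_effect, off_effect]
  expect_lt(mean(far), mean(diag_scores[on_effect]) - 10)
})

test_that("one-vs-rest pooling relabels and balances after pooling", {
  labs <- rep(c("stand", "walk", "obstacles"), each = 30)
  pooled <- pool_rest(labs, "stand")
  expect_equal(sum(pooled == "stand"), 30)
  expect_equal(sum(pooled == "rest"), 60)
  kept <- balance_classes(pooled, seed = 1L)
  expect_equal(as.integer(table(pooled[kept])), c(30L, 30L))
  expect_error(pool_rest(labs, "run"), "not among")
})
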