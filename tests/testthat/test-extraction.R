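test_that("band-pass attenuates a 50 Hz tone by more than 20 dB", {
  fs <- 500
  t <- seq(0, 10, by = 1 / fs)
  tone <- sin(2 * pi * 50 * t)
  rec <- continuous_recording(rbind(tone, tone + rnorm(length(t), sd = 1e-6)),
                              fs, c("Fp1", "Fp2"))
  out <- preprocess(rec, 0.1, 40, target_fs = fs, corr_min = 0)
  # compare RMS in the steady-state middle to avoid filter edge transients
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  ratio <- sqrt(mean(out$data[1, mid]^2)) / sqrt(mean(tone[mid]^2))
  expect_lt(20 * log10(ratio), -20)
})

test_that("decimation from 500 to 250 Hz keeps ceil(n/2) samples", {
  fs <- 500
  n <- 1001
  rec <- continuous_recording(matrix(rnorm(2 * n), 2), fs, c("Fp1", "Fp2"))
  out <- preprocess(rec, 0.1, 40, target_fs = 250, corr_min = 0)
  expect_equal(ncol(out$data), ceiling(n / 2))
  expect_equal(out$fs, 250)
})

test_that("a constant channel is flagged as flatline", {
  fs <- 250
  n <- 2500
  dat <- rbind(rnorm(n), rnorm(n), rep(100, n))
  rec <- continuous_recording(dat, fs, c("Fp1", "Fp2", "Cz"))
  out <- preprocess(rec, 0.1, 40, target_fs = fs, corr_min = 0)
  expect_equal(attr(out, "flagged_channels")$flatline, "Cz")
  # flagged but retained by default; dropping is opt-in
  expect_equal(nrow(out$data), 3)
  out2 <- preprocess(rec, 0.1, 40, target_fs = fs, corr_min = 0,
                     drop_flagged = TRUE)
  expect_equal(nrow(out2$data), 2)
})

test_that("preprocessing applies a common average reference", {
  rec <- continuous_recording(matrix(rnorm(3 * 2500), 3), 250,
                              c("Fp1", "Fp2", "Cz"))
  out <- preprocess(rec, 0.1, 40, target_fs = 250, corr_min = 0)
  expect_lt(max(abs(colMeans(out$data))), 1e-10)
})

test_that("blink component wins the left/right anterior correlation contest", {
  n <- 5000
  set.seed(1)
  blink_act <- pmax(0, sin(seq(0, 40 * pi, length.out = n)))^3
  sacc_act <- rnorm(n)
  acts <- rbind(blink_act, sacc_act)
  # blink drives Fp1/Fp2 with equal sign; saccade with opposite signs
  mixing <- cbind(c(1, 0.9, 0.3, 0.1), c(0.8, -0.8, 0.05, 0))
  unmixing <- MASS::ginv(mixing)
  dec <- component_decomposition(unmixing, mixing, acts,
                                 eye_candidate_flags = c(TRUE, TRUE),
                                 channel_labels = c("Fp1", "Fp2", "F3", "F4"))
  expect_equal(identify_blink_component(dec), 1L)

  # back-projected correlations computed directly: +1 for blink, -1 for saccade
  r_blink <- cor(mixing[1, 1] * blink_act, mixing[2, 1] * blink_act)
  r_sacc <- cor(mixing[1, 2] * sacc_act, mixing[2, 2] * sacc_act)
  expect_gt(r_blink, 0.9)
  expect_lt(r_sacc, -0.7)

  # single candidate returns that candidate
  dec1 <- component_decomposition(unmixing, mixing, acts,
                                  eye_candidate_flags = c(TRUE, FALSE),
                                  channel_labels = c("Fp1", "Fp2", "F3", "F4"))
  expect_equal(identify_blink_component(dec1), 1L)

  # all-negative correlations -> no blink component
  dec2 <- component_decomposition(unmixing, mixing, acts,
                                  eye_candidate_flags = c(FALSE, TRUE),
                                  channel_labels = c("Fp1", "Fp2", "F3", "F4"))
  expect_error(identify_blink_component(dec2), "positive")
})

test_that("identify_blink_component recovers the true blink source on simulations", {
  cfg <- quick_config(duration = 30, seed = 5L)
  out <- simulate_recording(cfg)
  unmix <- MASS::ginv(out$truth$mixing)
  dec <- component_decomposition(unmix, out$truth$mixing,
                                 unmix %*% out$recording$data,
                                 channel_labels = out$recording$channel_labels)
  expect_equal(identify_blink_component(dec), 1L)  # column 1 is the blink source
})

test_that("threshold detector finds inserted pulses and nothing else", {
  fs <- 250
  expect_equal(nrow(detect_blinks(rep(3, 1000), fs)), 0)  # zero variance

  set.seed(2)
  x <- rnorm(5000)
  pulse <- 10 * sin(seq(0, pi, length.out = 50))  # 200 ms supra-threshold pulse
  x[1001:1050] <- x[1001:1050] + pulse
  x[3001:3050] <- x[3001:3050] + pulse
  ev <- detect_blinks(x, fs)
  expect_equal(nrow(ev), 2)
  # brute-force check: each event is the max sample of its pulse
  expect_equal(ev$peak_sample[1], 1000 + which.max(x[1001:1050]))
  expect_equal(ev$peak_sample[2], 3000 + which.max(x[3001:3050]))

  # a pulse below mean + 1.5 SD yields nothing
  y <- rnorm(5000)
  thr <- mean(y) + 1.5 * sd(y)
  y[2001:2050] <- thr - 0.01  # long plateau just below threshold
  expect_equal(nrow(detect_blinks(y, fs)), sum(FALSE))
})

test_that("detector hits ground-truth blinks with precision and recall >= 0.95", {
  cfg <- quick_config(duration = 120, snr = 5, seed = 9L)
  out <- simulate_recording(cfg)
  unmix <- MASS::ginv(out$truth$mixing)
  bc <- (unmix %*% out$recording$data)[1, ]
  ev <- detect_blinks(bc, out$recording$fs)
  tol <- 0.020 * out$recording$fs  # 20 ms
  hits <- vapply(out$truth$blink_peak_samples, function(p) {
    any(abs(ev$peak_sample - p) <= tol)
  }, logical(1))
  matched <- vapply(ev$peak_sample, function(p) {
    any(abs(out$truth$blink_peak_samples - p) <= tol)
  }, logical(1))
  expect_gte(mean(hits), 0.95)     # recall
  expect_gte(mean(matched), 0.95)  # precision
})

test_that("epoch windows are inclusive and boundary events are dropped", {
  fs <- 250
  mat <- matrix(rnorm(2 * 2000), 2)
  es <- epoch_blink_locked(mat, c(10L, 1000L, 1990L), fs = fs)
  # only the event at 1000 allows the full -500..1000 ms window
  expect_equal(dim(es$data)[1], 1)
  expect_equal(attr(es, "n_dropped"), 2)
  expect_equal(dim(es$data)[3], 376)  # 875..1250 inclusive
  expect_equal(es$data[1, 1, ], mat[1, 875:1250])
  expect_equal(es$time_ms[1], -500)
  expect_equal(es$time_ms[376], 1000)

  es3 <- epoch_blink_locked(mat, c(600L, 900L, 700L), fs = fs)
  expect_equal(dim(es3$data)[1], 3)
  expect_error(epoch_blink_locked(mat, c(5L), fs = fs), "empty")
})

test_that("epoch rejection applies both rules, the iteration cap, and is idempotent", {
  set.seed(3)
  arr <- array(rnorm(20 * 3 * 50, sd = 20), dim = c(20, 3, 50))
  es <- toy_epochs(arr)
  clean <- reject_epochs(es)
  expect_equal(dim(clean$epochs$data), dim(es$data))  # all clean: no-op
  expect_equal(nrow(clean$log), 0)

  # one epoch with a 600 uV sample is removed by the absolute rule
  arr2 <- arr
  arr2[7, 2, 25] <- 600
  r2 <- reject_epochs(toy_epochs(arr2))
  expect_equal(r2$log$epoch, 7)
  expect_equal(r2$log$rule, "absolute")
  expect_equal(dim(r2$epochs$data)[1], 19)

  # 100 epochs with 30 absolute violators: caps 10, 9, 8, ... per iteration
  set.seed(4)
  arr3 <- array(rnorm(100 * 2 * 30, sd = 20), dim = c(100, 2, 30))
  arr3[1:30, 1, 1] <- 700 + (1:30)
  r3 <- reject_epochs(toy_epochs(arr3))
  removed_per_iter <- table(r3$log$iteration)
  expect_equal(as.integer(removed_per_iter[1:3]), c(10L, 9L, 8L))
  expect_true(all(!(1:30 %in% seq_len(100)[-r3$log$epoch])))
  expect_equal(dim(r3$epochs$data)[1], 100 - nrow(r3$log))

  # idempotence and label registration
  labs <- rep(c("A", "B"), 50)
  es4 <- toy_epochs(arr3, labels = labs)
  r4 <- reject_epochs(es4)
  expect_equal(r4$epochs$labels, labs[-sort(r4$log$epoch)])
  r5 <- reject_epochs(r4$epochs)
  expect_equal(nrow(r5$log), 0)
  expect_identical(r5$epochs$data, r4$epochs$data)
})
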