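#' Simulation configuration for synthetic blink-locked EEG
#'
#' Describes a synthetic mobile-EEG recording: a frontal eye-blink source
#' emitting stereotyped unipolar pulses, a posterior evoked source emitting a
#' blink-locked oscillatory burst whose global-field-power (GFP) peak lags the
#' blink peak by a condition-specific offset, additive channel noise, and a
#' block-interleaved condition schedule.
#'
#' The defaults emulate the recording setup the package targets: a 30-channel
#' 10-20 montage sampled at 250 Hz, a spontaneous blink rate of 12 per minute,
#' ~100 uV frontal blink pulses with a fast (100 ms) rise and slower (200 ms)
#' fall, and evoked GFP peak lags in the mid-100 ms range, bracketing typical
#' post-blink decoding apex times.
#'
#' @param n_channels number of scalp channels (default 30).
#' @param fs sampling rate in Hz (default 250).
#' @param duration seconds of recording per condition (default 300).
#' @param conditions character vector of condition names.
#' @param blink_rate blinks per minute (default 12).
#' @param blink_amp blink pulse peak amplitude in uV at the maximal channel.
#' @param blink_rise_ms,blink_fall_ms rise/fall of the asymmetric blink pulse.
#' @param blink_amp_cv lognormal coefficient of variation of per-blink
#'   amplitude (default 0.1).
#' @param blink_amp_by_condition optional named multipliers on blink amplitude
#'   per condition (default all 1: no condition information in the blink).
#' @param evoked_lag named numeric, ms between blink peak and evoked GFP peak
#'   per condition; must lie inside the epoch window.
#' @param evoked_amp evoked burst peak amplitude in uV at the maximal channel.
#' @param evoked_amp_by_condition optional named multipliers per condition.
#' @param evoked_freq carrier frequency of the evoked burst in Hz.
#' @param evoked_dur_ms duration of the Hann-windowed evoked burst in ms.
#' @param snr evoked-to-noise amplitude ratio: `evoked_amp` divided by the
#'   average per-channel noise SD.
#' @param noise_model `"pink"` (1/f-shaped, default) or `"white"`.
#' @param bg_sources number of spatially structured background sources with
#'   random fixed topographies (default 6); real EEG background is spatially
#'   low-rank, which is what lets a 95%-variance PCA rule retain few
#'   components. Set to 0 for spatially white noise.
#' @param bg_decay geometric amplitude decay across background sources
#'   (default 0.75).
#' @param sensor_noise_frac relative amplitude of the spatially white sensor
#'   noise floor (default 0.05).
#' @param block_s length in seconds of each condition block (default 60).
#' @param seed integer seed fixing all randomness.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_channels = 30, fs = 250, duration = 300,
                       conditions = c("stand", "walk", "obstacles"),
                       blink_rate = 12, blink_amp = 100,
                       blink_rise_ms = 100, blink_fall_ms = 200,
                       blink_amp_cv = 0.1, blink_amp_by_condition = NULL,
                       evoked_lag = NULL, evoked_amp = 5,
                       evoked_amp_by_condition = NULL,
                       evoked_freq = 10, evoked_dur_ms = 120,
                       snr = 5, noise_model = c("pink", "white"),
                       bg_sources = 6, bg_decay = 0.75,
                       sensor_noise_frac = 0.05,
                       block_s = 60, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (fs <= 0) abort("`fs` must be positive.")
  if (blink_rate <= 0) abort("`blink_rate` must be positive.")
  if (snr <= 0) abort("`snr` must be positive.")
  if (n_channels < 2) abort("Need at least 2 channels.")
  if (is.null(evoked_lag)) {
    # grid-aligned at 250 Hz, bracketing typical post-blink decoding apexes
    evoked_lag <- seq(148, by = 20, length.out = length(conditions))
    names(evoked_lag) <- conditions
  }
  evoked_lag <- normalize_by_condition(evoked_lag, conditions, "evoked_lag")
  if (any(evoked_lag < -500 + evoked_dur_ms / 2) ||
      any(evoked_lag > 1000 - evoked_dur_ms / 2)) {
    abort("`evoked_lag` must place the evoked burst inside the -500..1000 ms epoch window.")
  }
  blink_amp_by_condition <- normalize_by_condition(
    blink_amp_by_condition %||% rep(1, length(conditions)), conditions,
    "blink_amp_by_condition")
  evoked_amp_by_condition <- normalize_by_condition(
    evoked_amp_by_condition %||% rep(1, length(conditions)), conditions,
    "evoked_amp_by_condition")
  structure(list(
    n_channels = n_channels, fs = fs, duration = duration,
    conditions = conditions, blink_rate = blink_rate,
    blink_amp = blink_amp, blink_rise_ms = blink_rise_ms,
    blink_fall_ms = blink_fall_ms, blink_amp_cv = blink_amp_cv,
    blink_amp_by_condition = blink_amp_by_condition,
    evoked_lag = evoked_lag, evoked_amp = evoked_amp,
    evoked_amp_by_condition = evoked_amp_by_condition,
    evoked_freq = evoked_freq, evoked_dur_ms = evoked_dur_ms,
    snr = snr, noise_model = noise_model,
    bg_sources = bg_sources, bg_decay = bg_decay,
    sensor_noise_frac = sensor_noise_frac, block_s = block_s,
    seed = as.integer(seed)
  ), class = "sim_config")
}

normalize_by_condition <- function(x, conditions, what) {
  if (is.null(names(x))) {
    if (length(x) == 1) x <- rep(x, length(conditions))
    if (length(x) != length(conditions)) {
      abort(sprintf("`%s` must have one value per condition.", what))
    }
    names(x) <- conditions
  }
  if (!all(conditions %in% names(x))) {
    abort(sprintf("`%s` must name every condition.", what))
  }
  x[conditions]
}

# approximate 30-label 10-20 montage ordered anterior -> posterior
montage_labels <- function(n) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
            "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
            "PO7", "PO3", "POz", "PO4", "O1")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("EX%02d", seq_len(n - length(base))))
}

# anterior-posterior coordinate in [0, 1] per channel index
ap_coord <- function(n) (seq_len(n) - 1) / max(1, n - 1)

# frontal-weighted blink topography, same sign left/right (unit max)
blink_topography <- function(n) {
  w <- exp(-4 * ap_coord(n))
  w / max(abs(w))
}

# posterior-weighted evoked topography; anterior L/R weights have opposite
# signs so the evoked component can never masquerade as the blink component
# under the left/right anterior correlation rule
evoked_topography <- function(n) {
  w <- sin(pi * ap_coord(n))^2
  w[1] <- -0.05
  w[2] <- 0.05
  w / max(abs(w))
}

# asymmetric unipolar blink pulse sampled at fs, peak exactly at t = 0
blink_pulse <- function(fs, rise_ms = 100, fall_ms = 200) {
  dt <- 1000 / fs
  t <- seq(-rise_ms, fall_ms, by = dt)
  v <- ifelse(t <= 0,
              0.5 * (1 + cos(pi * t / rise_ms)),
              0.5 * (1 + cos(pi * t / fall_ms)))
  list(t_ms = t, v = v, peak_idx = which.max(v))
}

# Hann-windowed cosine burst; global maximum exactly at the window center
evoked_burst <- function(fs, dur_ms = 120, freq = 10) {
  dt <- 1000 / fs
  t <- seq(-dur_ms / 2, dur_ms / 2, by = dt)
  env <- 0.5 * (1 + cos(2 * pi * t / dur_ms))
  v <- env * cos(2 * pi * freq * t / 1000)
  list(t_ms = t, v = v, peak_idx = which.max(v))
}

# n samples of unit-SD noise; "pink" shapes amplitude as f^(-1/2)
noise_series <- function(n, model = "pink") {
  x <- rnorm(n)
  if (model == "white") return(x)
  xf <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  shape[1] <- 0                       # drop DC
  y <- Re(fft(xf * shape, inverse = TRUE)) / n
  y / sd(y)
}

noise_matrix <- function(n_channels, n_samples, model) {
  t(vapply(seq_len(n_channels), function(i) noise_series(n_samples, model),
           numeric(n_samples)))
}

# random unit-norm topographies for the background sources, fixed per call
bg_topographies <- function(n_channels, n_src) {
  if (n_src == 0) return(matrix(0, n_channels, 0))
  b <- matrix(rnorm(n_channels * n_src), n_channels, n_src)
  sweep(b, 2, sqrt(colSums(b^2)), "/")
}

# spatially low-rank background + white sensor floor, scaled so the average
# per-channel SD is exactly 1 in expectation
structured_noise <- function(config, n_channels, n, topo) {
  n_src <- ncol(topo)
  amps <- config$bg_decay^(seq_len(n_src) - 1)
  sf <- config$sensor_noise_frac
  chan_sd <- sqrt(drop(topo^2 %*% amps^2) + sf^2)
  out <- sf * noise_matrix(n_channels, n, config$noise_model)
  if (n_src > 0) {
    src <- t(vapply(seq_len(n_src),
                    function(j) noise_series(n, config$noise_model),
                    numeric(n)))
    out <- out + topo %*% (src * amps)
  }
  out / mean(chan_sd)
}

#' Continuous multichannel recording container
#'
#' @param data numeric matrix `channels x samples` in uV.
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names (10-20 labels for simulated data).
#' @param participant_id identifier string.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_labels = NULL,
                                 participant_id = "P01") {
  data <- as.matrix(data)
  if (is.null(channel_labels)) channel_labels <- montage_labels(nrow(data))
  if (anyNA(data)) abort("Recording contains NaN/NA values.")
  if (nrow(data) < 2) abort("Recording must have at least 2 channels.")
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 participant_id = participant_id),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording: %d channels x %d samples @ %g Hz (%s)>\n",
              nrow(x$data), ncol(x$data), x$fs, x$participant_id))
  invisible(x)
}

# block-interleaved condition schedule; returns condition name per sample
condition_schedule <- function(config, n_samples) {
  block_n <- round(config$block_s * config$fs)
  n_cond <- length(config$conditions)
  blocks_per_cond <- ceiling(n_samples / (block_n * n_cond))
  sched <- rep(rep(config$conditions, times = blocks_per_cond), each = block_n)
  sched[seq_len(n_samples)]
}

#' Simulate a continuous blink-embedded EEG recording
#'
#' Generates `mixing %*% sources + noise`: a frontal blink source firing
#' asymmetric unipolar pulses at roughly `blink_rate` per minute, and a
#' posterior evoked source firing a Hann-windowed burst `delta_t_true` ms
#' after each blink peak, with the lag set by the condition active at that
#' blink. Ground truth lists every blink peak sample, its condition, the
#' mixing matrix, and the true lags.
#'
#' @param config a [sim_config()].
#' @param participant_id identifier recorded in the output.
#' @return A list with elements `recording` (a [continuous_recording()]) and
#'   `truth` (list: `blink_peak_samples`, `condition_of_blink`, `mixing`,
#'   `delta_t_true`, `sources`).
#' @export
simulate_recording <- function(config, participant_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  with_rng(config$seed, {
    fs <- config$fs
    n_samples <- round(config$duration * length(config$conditions) * fs)
    sched <- condition_schedule(config, n_samples)

    # renewal process: refractory gap + exponential wait, targeting blink_rate
    gap_s <- 1.5
    mean_wait <- max(0.5, 60 / config$blink_rate - gap_s)
    times <- c()
    t_cur <- gap_s + rexp(1, 1 / mean_wait)
    while (t_cur < n_samples / fs - 1.2) {
      times <- c(times, t_cur)
      t_cur <- t_cur + gap_s + rexp(1, 1 / mean_wait)
    }
    peaks <- round(times * fs) + 1L
    peaks <- peaks[peaks > fs & peaks <= n_samples - fs]
    cond_of_blink <- sched[peaks]

    pulse <- blink_pulse(fs, config$blink_rise_ms, config$blink_fall_ms)
    burst <- evoked_burst(fs, config$evoked_dur_ms, config$evoked_freq)

    blink_src <- numeric(n_samples)
    evoked_src <- numeric(n_samples)
    amp_jit <- if (config$blink_amp_cv > 0) {
      rlnorm(length(peaks), -config$blink_amp_cv^2 / 2, config$blink_amp_cv)
    } else rep(1, length(peaks))
    for (i in seq_along(peaks)) {
      cond <- cond_of_blink[i]
      b_amp <- config$blink_amp * config$blink_amp_by_condition[[cond]] * amp_jit[i]
      idx <- peaks[i] + seq_along(pulse$v) - pulse$peak_idx
      ok <- idx >= 1 & idx <= n_samples
      blink_src[idx[ok]] <- blink_src[idx[ok]] + b_amp * pulse$v[ok]

      lag_n <- round(config$evoked_lag[[cond]] * fs / 1000)
      e_amp <- config$evoked_amp * config$evoked_amp_by_condition[[cond]]
      jdx <- peaks[i] + lag_n + seq_along(burst$v) - burst$peak_idx
      ok <- jdx >= 1 & jdx <= n_samples
      evoked_src[jdx[ok]] <- evoked_src[jdx[ok]] + e_amp * burst$v[ok]
    }

    mixing <- cbind(blink = blink_topography(config$n_channels),
                    evoked = evoked_topography(config$n_channels))
    noise_sd <- config$evoked_amp / config$snr
    topo <- bg_topographies(config$n_channels, config$bg_sources)
    data <- mixing %*% rbind(blink_src, evoked_src) +
      noise_sd * structured_noise(config, config$n_channels, n_samples, topo)

    rec <- continuous_recording(data, fs, montage_labels(config$n_channels),
                                participant_id)
    truth <- list(blink_peak_samples = peaks,
                  condition_of_blink = cond_of_blink,
                  mixing = mixing,
                  delta_t_true = config$evoked_lag,
                  sources = rbind(blink = blink_src, evoked = evoked_src))
    list(recording = rec, truth = truth)
  })
}

#' Simulate blink-locked epochs directly
#'
#' Emits blink-locked epochs without going through continuous simulation and
#' blink detection, so downstream stages (synchronization, fusion, decoding)
#' can be unit-tested in isolation. The EEG epochs represent the
#' post-component-cleaning view (evoked response + noise; the ocular artifact
#' itself lives in the separate blink-component epochs), mirroring a pipeline
#' in which non-brain components are removed from the EEG stream while the
#' blink component is retained as its own signal.
#'
#' @param config a [sim_config()].
#' @param n_epochs_per_condition epochs to generate per condition.
#' @param window_ms epoch window in ms relative to the blink peak.
#' @param participant_id identifier attached to outputs.
#' @return A list: `eeg` (channel-space [epoch_set()]), `blink`
#'   (blink-component [epoch_set()], 1 series), `truth` (list with `mixing`,
#'   `delta_t_true`, `labels`).
#' @export
simulate_epochset <- function(config, n_epochs_per_condition = 100,
                              window_ms = c(-500, 1000),
                              participant_id = "P01") {
  stopifnot(inherits(config, "sim_config"))
  if (n_epochs_per_condition < 1) abort("Need at least one epoch per condition.")
  with_rng(config$seed, {
    fs <- config$fs
    dt <- 1000 / fs
    t_ms <- seq(window_ms[1], window_ms[2], by = dt)
    n_t <- length(t_ms)
    n_cond <- length(config$conditions)
    n_ep <- n_epochs_per_condition * n_cond
    labels <- rep(config$conditions, times = n_epochs_per_condition)

    pulse <- blink_pulse(fs, config$blink_rise_ms, config$blink_fall_ms)
    burst <- evoked_burst(fs, config$evoked_dur_ms, config$evoked_freq)
    mixing <- cbind(blink = blink_topography(config$n_channels),
                    evoked = evoked_topography(config$n_channels))
    noise_sd <- config$evoked_amp / config$snr
    topo <- bg_topographies(config$n_channels, config$bg_sources)

    # waveforms placed on the epoch grid
    place <- function(wave, t_wave, center_ms) {
      out <- numeric(n_t)
      idx <- round((t_wave + center_ms - window_ms[1]) / dt) + 1L
      ok <- idx >= 1 & idx <= n_t
      out[idx[ok]] <- wave[ok]
      out
    }
    blink_shape <- place(pulse$v, pulse$t_ms, 0)

    eeg <- array(0, dim = c(n_ep, config$n_channels, n_t))
    blk <- array(0, dim = c(n_ep, 1, n_t))
    amp_jit <- if (config$blink_amp_cv > 0) {
      rlnorm(n_ep, -config$blink_amp_cv^2 / 2, config$blink_amp_cv)
    } else rep(1, n_ep)
    for (i in seq_len(n_ep)) {
      cond <- labels[i]
      e_amp <- config$evoked_amp * config$evoked_amp_by_condition[[cond]]
      evoked_shape <- place(burst$v, burst$t_ms, config$evoked_lag[[cond]])
      eeg[i, , ] <- mixing[, "evoked"] %o% (e_amp * evoked_shape) +
        noise_sd * structured_noise(config, config$n_channels, n_t, topo)
      b_amp <- config$blink_amp * config$blink_amp_by_condition[[cond]] * amp_jit[i]
      blk[i, 1, ] <- b_amp * blink_shape + noise_sd * noise_series(n_t, config$noise_model)
    }

    list(
      eeg = epoch_set(eeg, t_ms, labels, fs, "channels",
                      montage_labels(config$n_channels)),
      blink = epoch_set(blk, t_ms, labels, fs, "blink", "BC"),
      truth = list(mixing = mixing, delta_t_true = config$evoked_lag,
                   labels = labels, participant_id = participant_id)
    )
  })
}
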