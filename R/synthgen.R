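#' Simulation configuration for synthetic EEG cohorts
#'
#' Defines the generative model used to test the pipeline end to end:
#' object-specific, band-limited oscillatory bursts with random per-trial
#' phase (induced power), loading on a posterior channel subset, embedded in
#' 1/f background noise plus an unspecific broad 10 Hz alpha background.
#' The same per-object channel pattern drives both tasks ("shared
#' representation"), with task-specific latency windows.
#'
#' @param n_participants cohort size.
#' @param n_channels number of channels; 63 uses the full
#'   [easycap_montage()], smaller values use a balanced anterior/posterior
#'   subset of its channel names.
#' @param n_objects number of object conditions (default 12).
#' @param trials_per_object_per_task trials per condition and task.
#' @param sampling_rate Hz (default 1000).
#' @param perception_window,imagery_window epoch extents in ms relative to
#'   stimulus/word onset; both must include >= 600 ms pre-stimulus padding.
#' @param shared_band `c(lo, hi)` Hz of the planted oscillation; each trial
#'   draws its carrier frequency uniformly in this band.
#' @param perception_latency,imagery_latency ms windows where the planted
#'   envelope is nonzero.
#' @param snr per-channel amplitude ratio of the planted oscillation to the
#'   unit-RMS background noise on signal-carrying channels.
#' @param posterior_fraction fraction of channels carrying the pattern;
#'   carriers are drawn from posterior-only montage channels (occipital
#'   backwards-first).
#' @param phase_locked if `TRUE` the burst has a fixed phase across trials
#'   (evoked regime); default `FALSE` (induced regime).
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param alpha_background amplitude of the spatially broad, random-phase
#'   10 Hz background common to all channels.
#' @param ramp_ms Hann ramp length at the latency-window edges (default 50).
#' @param seed base RNG seed; participant k uses a seed derived from
#'   `seed` and `k`, so any participant is reproducible in isolation.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_participants = 10,
                       n_channels = 63,
                       n_objects = 12,
                       trials_per_object_per_task = 40,
                       sampling_rate = 1000,
                       perception_window = c(-600, 1100),
                       imagery_window = c(-600, 3100),
                       shared_band = c(8, 13),
                       perception_latency = c(50, 750),
                       imagery_latency = c(600, 2300),
                       snr = 0.7,
                       posterior_fraction = 0.4,
                       phase_locked = FALSE,
                       noise_exponent = 1,
                       alpha_background = 0.5,
                       ramp_ms = 250,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$snr < 0) stop("snr must be >= 0")
  if (cfg$posterior_fraction <= 0 || cfg$posterior_fraction > 1)
    stop("posterior_fraction must be in (0, 1]")
  if (perception_window[1] > -600 || imagery_window[1] > -600)
    stop("epoch windows must include at least 600 ms pre-stimulus padding")
  check_lat <- function(lat, win, nm) {
    if (lat[1] < win[1] || lat[2] > win[2] || lat[1] >= lat[2])
      stop(nm, " latency window must lie inside the epoch window")
  }
  check_lat(perception_latency, perception_window, "perception")
  check_lat(imagery_latency, imagery_window, "imagery")
  cfg$channels <- default_channels(n_channels)
  structure(cfg, class = "sim_config")
}

#' Default channel-name subset for simulations
#'
#' The full montage for 63 channels; otherwise alternates posterior-only
#' (back to front) and anterior-only (front to back) montage names so both
#' scalp halves are represented at any size.
#' @param n number of channels.
#' @return character vector of channel names.
#' @export
default_channels <- function(n) {
  m <- easycap_montage()
  if (n == nrow(m)) return(m$channel)
  if (n > nrow(m)) stop("n_channels cannot exceed the 63-channel montage")
  post <- rev(m$channel[m$posterior & !m$anterior])   # O, PO, P, ... first
  ant <- m$channel[m$anterior & !m$posterior]
  k_post <- ceiling(n / 2); k_ant <- n - k_post
  if (k_post > length(post) || k_ant > length(ant))
    stop("requested subset larger than available exclusive-half channels")
  c(post[seq_len(k_post)], ant[seq_len(k_ant)])
}

# Gaussian 1/f^beta noise, unit RMS, synthesized in the frequency domain.
# Returns an n x m matrix (m independent channels).
pink_noise <- function(n, m, beta, sampling_rate) {
  nf <- n %/% 2
  f <- seq_len(nf) * sampling_rate / n
  amp <- f^(-beta / 2)
  spec <- matrix(0i, n, m)
  re <- matrix(stats::rnorm(nf * m), nf, m)
  im <- matrix(stats::rnorm(nf * m), nf, m)
  spec[2:(nf + 1), ] <- (re + 1i * im) * amp
  # hermitian symmetry for a real signal
  spec[n:(n - nf + 2), ] <- Conj(spec[2:(nf), ])
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

# Envelope: 1 inside the latency window with Hann ramps of ramp_ms at both
# edges, 0 outside.
burst_envelope <- function(times, latency, ramp_ms) {
  env <- numeric(length(times))
  inside <- times >= latency[1] & times <= latency[2]
  env[inside] <- 1
  up <- times >= latency[1] & times < latency[1] + ramp_ms
  env[up] <- 0.5 * (1 - cos(pi * (times[up] - latency[1]) / ramp_ms))
  dn <- times > latency[2] - ramp_ms & times <= latency[2]
  env[dn] <- 0.5 * (1 - cos(pi * (latency[2] - times[dn]) / ramp_ms))
  env
}

# Object x channel loading matrix: standard-normal on the signal channels,
# zero elsewhere, rows unit-normalized. When model features are supplied the
# rows are linear images of the standardized feature rows under a random
# orthonormal map, so pattern correlations approximate the model geometry.
draw_patterns <- function(n_objects, n_channels, signal_idx,
                          model_features = NULL) {
  ns <- length(signal_idx)
  p <- matrix(0, n_objects, n_channels)
  if (is.null(model_features)) {
    p[, signal_idx] <- matrix(stats::rnorm(n_objects * ns), n_objects, ns)
  } else {
    z <- t(scale(t(model_features)))          # standardize feature rows
    k <- ncol(z)
    if (k > ns)
      stop("model feature dimension exceeds the number of signal channels")
    q <- qr.Q(qr(matrix(stats::rnorm(ns * k), ns, k)))
    p[, signal_idx] <- z %*% t(q)
  }
  p / sqrt(rowSums(p^2))
}

#' Simulate one participant's epochs for both tasks
#'
#' Each trial is 1/f^beta channel noise + a broad random-phase 10 Hz
#' background + an object-specific band-limited burst whose phase is
#' uniformly random per trial (unless `phase_locked`), whose Hann-ramped
#' envelope is nonzero only inside the task's latency window, and whose
#' channel loading is the participant's unit-norm object pattern on the
#' designated posterior channels. Identical patterns drive both tasks.
#' Deterministic given `(config$seed, participant_index)`.
#'
#' @param config a [sim_config()].
#' @param participant_index 1-based participant number.
#' @param model_features optional object x feature matrix whose row
#'   correlation geometry the patterns should approximate.
#' @return list with `epochs` (named list of `epoch_set`: `perception`,
#'   `imagery`) and `ground_truth` (patterns, band, latencies, signal
#'   channels).
#' @export
simulate_participant <- function(config, participant_index,
                                 model_features = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed %% 100000L) * 10007L + participant_index)
  m <- easycap_montage()
  post_only <- rev(m$channel[m$posterior & !m$anterior])
  avail <- config$channels[config$channels %in% post_only]
  n_sig <- max(1L, round(config$posterior_fraction * config$n_channels))
  if (n_sig > length(avail))
    stop("posterior_fraction asks for more signal channels than the ",
         "channel set provides")
  signal_idx <- match(intersect(post_only, avail)[seq_len(n_sig)],
                      config$channels)
  patterns <- draw_patterns(config$n_objects, config$n_channels, signal_idx,
                            model_features)
  alpha_load <- abs(stats::rnorm(config$n_channels, 1, 0.2))

  make_task <- function(task, window, latency) {
    fs <- config$sampling_rate
    times <- seq(window[1], window[2] - 1000 / fs, by = 1000 / fs)
    n <- length(times)
    ntr <- config$n_objects * config$trials_per_object_per_task
    obj <- rep(seq_len(config$n_objects), each = config$trials_per_object_per_task)
    env <- burst_envelope(times, latency, config$ramp_ms)
    dat <- array(0, dim = c(ntr, config$n_channels, n))
    tsec <- times / 1000
    for (tr in seq_len(ntr)) {
      x <- pink_noise(n, config$n_channels, config$noise_exponent, fs)
      phi_bg <- stats::runif(1, 0, 2 * pi)
      x <- x + config$alpha_background *
        outer(cos(2 * pi * 10 * tsec + phi_bg), alpha_load)
      # carrier peaked at band center (alpha peaks cluster near 10 Hz, they
      # are not uniform over the band); truncation keeps it band-limited
      f <- band_center <- mean(config$shared_band)
      bw <- diff(config$shared_band)
      if (bw > 0) {
        repeat {
          f <- stats::rnorm(1, band_center, bw / 8)
          if (f >= config$shared_band[1] && f <= config$shared_band[2]) break
        }
      }
      phi <- if (config$phase_locked) 0 else stats::runif(1, 0, 2 * pi)
      osc <- env * cos(2 * pi * f * tsec + phi)
      amp <- config$snr * sqrt(length(signal_idx))
      x <- x + amp * outer(osc, patterns[obj[tr], ])
      dat[tr, , ] <- t(x)
    }
    structure(list(data = dat, task = rep(task, ntr), object = obj,
                   times = times, channels = config$channels,
                   sampling_rate = fs),
              class = "epoch_set")
  }
  epochs <- list(
    perception = make_task("perception", config$perception_window,
                           config$perception_latency),
    imagery = make_task("imagery", config$imagery_window,
                        config$imagery_latency))
  gt <- list(object_patterns = patterns,
             shared_band = config$shared_band,
             latency = list(perception = config$perception_latency,
                            imagery = config$imagery_latency),
             signal_channels = config$channels[signal_idx])
  list(epochs = epochs, ground_truth = gt)
}

#' Simulate a cohort of independent participants
#'
#' @inheritParams simulate_participant
#' @return list of length `config$n_participants`, each element as returned
#'   by [simulate_participant()].
#' @export
simulate_cohort <- function(config, model_features = NULL) {
  stopifnot(inherits(config, "sim_config"), config$n_participants >= 1)
  lapply(seq_len(config$n_participants), function(k)
    simulate_participant(config, k, model_features))
}
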