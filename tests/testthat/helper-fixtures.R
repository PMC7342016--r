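# Small constructors used across test files. Everything is generated in code;
# no binary fixtures.

# trial x feature x time array of iid Gaussian features with condition labels
gauss_features <- function(n_per_cond = 8, n_cond = 4, n_feat = 10,
                           times = c(0, 20), seed = 1) {
  set.seed(seed)
  n <- n_per_cond * n_cond
  x <- array(rnorm(n * n_feat * length(times)),
             dim = c(n, n_feat, length(times)))
  structure(x, times = times, object = rep(seq_len(n_cond), each = n_per_cond),
            task = rep("perception", n), channels = paste0("ch", 1:n_feat))
}

# single-channel epoch_set holding an arbitrary waveform per trial
waveform_epochs <- function(waves, sampling_rate = 250, t0 = -600) {
  n <- ncol(waves)
  times <- seq(t0, by = 1000 / sampling_rate, length.out = n)
  dat <- array(0, dim = c(nrow(waves), 1, n))
  dat[, 1, ] <- waves
  structure(list(data = dat, task = rep("perception", nrow(waves)),
                 object = rep(1L, nrow(waves)), times = times,
                 channels = "Oz", sampling_rate = sampling_rate),
            class = "epoch_set")
}

# hand-built tf_epochs with explicit power values
manual_tf <- function(power, times, normalized = FALSE) {
  n_bins <- dim(power)[3]
  grid <- if (n_bins >= 2) log_spaced_grid(5, 31, n_bins) else
    structure(list(bin_centers = 10, range = c(10, 10), spacing = "custom"),
              class = "freq_grid")
  structure(list(power = power, times = times, grid = grid,
                 channels = paste0("ch", seq_len(dim(power)[2])),
                 task = rep("perception", dim(power)[1]),
                 object = rep(1L, dim(power)[1]),
                 sampling_rate = 1000 / diff(times[1:2]),
                 normalized = normalized, baseline_window = NULL),
            class = "tf_epochs")
}

# hand-built timegen object from a per-pair accuracy array
manual_timegen <- function(per_pair, pt, it) {
  n_obj <- dim(per_pair)[3]
  acc <- apply(per_pair, c(1, 2), function(m) {
    mm <- matrix(m, n_obj, n_obj)
    mean(mm[lower.tri(mm)])
  })
  structure(list(accuracy = acc, per_pair = per_pair,
                 perception_times = pt, imagery_times = it,
                 objects = seq_len(n_obj), n_repeats = 1, band = "alpha"),
            class = "timegen")
}

# block-structured model features: two clusters of mutually similar objects
two_cluster_features <- function(n_obj = 12, n_feat = 5, seed = 3) {
  set.seed(seed)
  proto <- matrix(rnorm(2 * n_feat), 2, n_feat)
  half <- n_obj / 2
  base <- proto[rep(1:2, each = half), ]
  base + 0.25 * matrix(rnorm(n_obj * n_feat), n_obj, n_feat)
}
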