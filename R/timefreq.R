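#' Logarithmically spaced frequency grid
#'
#' Builds the analysis grid used for the Morlet decomposition: `n_bins`
#' centers spaced with a constant ratio between `f_min` and `f_max`, so bin
#' i (0-based) sits at `f_min * (f_max/f_min)^(i/(n_bins-1))`. The canonical
#' grid is 20 bins between 5 and 31 Hz.
#'
#' @param f_min,f_max grid endpoints in Hz; `0 < f_min < f_max`.
#' @param n_bins number of bin centers (>= 2).
#' @return An object of class `freq_grid`: list with `bin_centers` (Hz),
#'   `range`, and `spacing = "logarithmic"`.
#' @export
#' @examples
#' g <- log_spaced_grid(5, 31, 20)
#' round(g$bin_centers, 2)
log_spaced_grid <- function(f_min = 5, f_max = 31, n_bins = 20) {
  if (!is.finite(f_min) || !is.finite(f_max) || f_min <= 0 || f_max <= f_min)
    stop("invalid frequency range: need 0 < f_min < f_max")
  if (n_bins < 2) stop("n_bins must be >= 2")
  i <- seq_len(n_bins) - 1
  centers <- f_min * (f_max / f_min)^(i / (n_bins - 1))
  structure(list(bin_centers = centers, range = c(f_min, f_max),
                 spacing = "logarithmic"),
            class = "freq_grid")
}

#' Canonical frequency-band definitions
#'
#' Nominal integer ranges for the three bands analysed: theta 5-7 Hz,
#' alpha 8-13 Hz, beta 14-31 Hz.
#' @return Named list of length-2 numeric ranges.
#' @export
canonical_bands <- function() {
  list(theta = c(5, 7), alpha = c(8, 13), beta = c(14, 31))
}

#' Assign frequency bins to discrete bands
#'
#' Each bin center is rounded to the nearest integer Hz and assigned to the
#' band whose nominal range contains the rounded value. On the canonical
#' 20-bin grid this yields 5 theta, 6 alpha and 9 beta members.
#'
#' @param grid a [log_spaced_grid()] object.
#' @param nominal_ranges named list of `c(lo, hi)` integer ranges in Hz
#'   (default [canonical_bands()]).
#' @return Named list of `band_spec` objects with fields `name`,
#'   `nominal_range` and `member_bins` (indices into the grid).
#' @export
assign_bands <- function(grid, nominal_ranges = canonical_bands()) {
  stopifnot(inherits(grid, "freq_grid"))
  rounded <- round(grid$bin_centers)
  members <- lapply(nominal_ranges, function(r)
    which(rounded >= r[1] & rounded <= r[2]))
  hit <- sort(unlist(members, use.names = FALSE))
  if (length(hit) != length(rounded) || any(duplicated(hit)))
    stop("nominal ranges must partition the grid: every rounded bin center ",
         "must fall in exactly one range")
  if (any(vapply(members, length, 1L) == 0L))
    stop("a band ended up with no member bins")
  out <- mapply(function(nm, r, m)
    structure(list(name = nm, nominal_range = r, member_bins = m),
              class = "band_spec"),
    names(nominal_ranges), nominal_ranges, members, SIMPLIFY = FALSE)
  out
}

# Complex Morlet wavelet with fixed temporal support: Gaussian envelope
# truncated at +/- length/2 with the edge at 3 sigma.
morlet_wavelet <- function(freq, sampling_rate, wavelet_length = 600) {
  half <- wavelet_length / 2 / 1000                   # seconds
  t <- seq(-half, half, by = 1 / sampling_rate)
  sigma <- half / 3
  env <- exp(-t^2 / (2 * sigma^2))
  w <- env * exp(2i * pi * freq * t)
  w / sum(env)                                        # unit envelope gain
}

#' Morlet time-frequency decomposition of epoched EEG
#'
#' Convolves every trial and channel with complex Morlet wavelets of constant
#' temporal support (default 600 ms; Gaussian envelope truncated at 3 sigma)
#' at each bin of `grid`, and returns the magnitude of the complex
#' coefficient ("absolute power") per trial, channel, frequency bin and time
#' point. No averaging across trials takes place, so non-phase-locked
#' (induced) activity is retained.
#'
#' @param epochs an `epoch_set` (see [simulate_participant()] /
#'   [read_epochs()]).
#' @param grid a [log_spaced_grid()] object.
#' @param wavelet_length wavelet support in ms; must fit inside the epoch
#'   padding on both sides of the analysis window.
#' @return A `tf_epochs` object: list with `power` (trial x channel x bin x
#'   time), `times`, `grid`, `sampling_rate`, `normalized = FALSE`.
#' @export
morlet_power <- function(epochs, grid, wavelet_length = 600) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(grid, "freq_grid"))
  fs <- epochs$sampling_rate
  x <- epochs$data                       # trial x channel x time
  nt <- dim(x)[3]
  half_samp <- round(wavelet_length / 2 / 1000 * fs)
  if (2 * half_samp + 1 > nt)
    stop("wavelet support (", wavelet_length, " ms) exceeds the epoch length")
  nbin <- length(grid$bin_centers)
  ntrial <- dim(x)[1]; nchan <- dim(x)[2]
  nfft <- stats::nextn(nt + 2 * half_samp, 2)
  # wavelet spectra, centered so "same" convolution keeps time alignment
  wf <- matrix(0i, nfft, nbin)
  for (b in seq_len(nbin)) {
    w <- morlet_wavelet(grid$bin_centers[b], fs, wavelet_length)
    buf <- complex(length.out = nfft)
    buf[seq_along(w)] <- w
    wf[, b] <- stats::fft(buf)
  }
  pow <- array(0, dim = c(ntrial, nchan, nbin, nt))
  for (ch in seq_len(nchan)) {
    sig <- matrix(0, nfft, ntrial)
    sig[seq_len(nt), ] <- t(x[, ch, , drop = FALSE][, 1, ])
    sf <- stats::mvfft(sig)
    for (b in seq_len(nbin)) {
      conv <- stats::mvfft(sf * wf[, b], inverse = TRUE) / nfft
      # wavelet peak is at sample half_samp+1; shift back to align
      pow[, ch, b, ] <- t(Mod(conv[half_samp + seq_len(nt), , drop = FALSE]))
    }
  }
  structure(list(power = pow, times = epochs$times, grid = grid,
                 channels = epochs$channels, task = epochs$task,
                 object = epochs$object, sampling_rate = fs,
                 normalized = FALSE, baseline_window = NULL),
            class = "tf_epochs")
}

#' Baseline normalization of induced power (dB)
#'
#' Expresses power relative to the pre-stimulus baseline:
#' `10 * log10(power / mean(power over baseline))`, separately per trial,
#' channel and frequency bin.
#'
#' @param tf a `tf_epochs` object from [morlet_power()].
#' @param baseline_window `c(lo, hi)` in ms (default -500 to -300).
#' @return `tf_epochs` with dB power and `normalized = TRUE`.
#' @export
baseline_normalize <- function(tf, baseline_window = c(-500, -300)) {
  stopifnot(inherits(tf, "tf_epochs"))
  idx <- which(tf$times >= baseline_window[1] & tf$times <= baseline_window[2])
  if (length(idx) == 0) stop("baseline window outside the epoch")
  d <- dim(tf$power)
  base <- rowMeans(matrix(tf$power[, , , idx, drop = FALSE],
                          prod(d[1:3]), length(idx)))
  if (any(base <= 0))
    stop("nonpositive baseline mean; cannot form dB ratio")
  tf$power <- array(10 * log10(matrix(tf$power, prod(d[1:3]), d[4]) / base),
                    dim = d)
  tf$normalized <- TRUE
  tf$baseline_window <- baseline_window
  tf
}

#' Temporal downsampling by bin averaging
#'
#' Averages the time axis in non-overlapping bins of `1000/target_rate` ms.
#' Bins are left-closed/right-open and anchored at t = 0 ms, so a bin
#' boundary always coincides with stimulus onset; output timestamps are bin
#' starts. Incomplete leading/trailing bins are dropped.
#'
#' @param tf a `tf_epochs` object.
#' @param target_rate output rate in Hz (default 50, i.e. 20 ms bins).
#' @return `tf_epochs` on the coarser time axis.
#' @export
downsample_tf <- function(tf, target_rate = 50) {
  stopifnot(inherits(tf, "tf_epochs"))
  step <- 1000 / tf$sampling_rate
  width <- 1000 / target_rate
  n_per <- width / step
  if (abs(n_per - round(n_per)) > 1e-8)
    stop("original rate must be divisible by target rate")
  n_per <- round(n_per)
  bin_id <- floor(round(tf$times / step) / n_per)      # anchored at t = 0
  keep_bins <- as.numeric(names(which(table(bin_id) == n_per)))
  keep <- bin_id %in% keep_bins
  bid <- bin_id[keep]
  ub <- sort(unique(bid))
  d <- dim(tf$power)
  flat <- matrix(tf$power, prod(d[1:3]), d[4])
  out <- array(0, dim = c(d[1], d[2], d[3], length(ub)))
  for (k in seq_along(ub)) {
    sel <- which(keep)[bid == ub[k]]
    out[, , , k] <- rowMeans(flat[, sel, drop = FALSE])
  }
  tf$power <- out
  tf$times <- ub * width
  tf$sampling_rate <- target_rate
  tf
}

#' Band-resolved response vectors
#'
#' Collapses the frequency dimension of a `tf_epochs` into per-trial pattern
#' vectors for one band: `mode = "average"` averages over the band's member
#' bins (one value per electrode, e.g. a 63-element vector for a 63-channel
#' montage), `mode = "concatenate"` stacks the member bins (bins x channels
#' features).
#'
#' @param tf a `tf_epochs` object.
#' @param band a `band_spec` from [assign_bands()].
#' @param mode `"average"` or `"concatenate"`.
#' @return trial x feature x time numeric array with attributes
#'   `times`, `task`, `object`, `channels`.
#' @export
band_vectors <- function(tf, band, mode = c("average", "concatenate")) {
  stopifnot(inherits(tf, "tf_epochs"), inherits(band, "band_spec"))
  mode <- match.arg(mode)
  m <- band$member_bins
  if (length(m) == 0) stop("band has no member bins")
  sub <- tf$power[, , m, , drop = FALSE]
  d <- dim(sub)                               # trial x chan x bins x time
  if (mode == "average") {
    out <- array(0, dim = c(d[1], d[2], d[4]))
    for (b in seq_len(d[3]))
      out <- out + array(sub[, , b, , drop = FALSE], dim = c(d[1], d[2], d[4]))
    out <- out / d[3]
  } else {
    out <- array(sub, dim = c(d[1], d[2] * d[3], d[4]))
  }
  structure(out, times = tf$times, task = tf$task, object = tf$object,
            channels = tf$channels, band = band$name, mode = mode)
}
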