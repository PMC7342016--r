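#!/usr/bin/env Rscript
# Time-frequency decomposition of the simulated epochs: 600 ms Morlet
# wavelets on the 20-bin log grid (5-31 Hz), absolute power, dB baseline
# normalization (-500..-300 ms), downsampling to 50 Hz, aggregation into
# theta/alpha/beta band feature arrays. Band arrays are cached as RDS under
# results/bands/ for the decoding stage; a grand-average spectrogram over
# the signal channels goes to results/tf_grand_average.csv.

suppressPackageStartupMessages(library(alphashare))
dir.create("results/bands", recursive = TRUE, showWarnings = FALSE)

grid <- log_spaced_grid(5, 31, 20)
bands <- assign_bands(grid, canonical_bands())
cat("frequency grid:", paste(round(grid$bin_centers, 2), collapse = " "), "\n")
cat("band sizes:",
    paste(names(bands), vapply(bands, function(b) length(b$member_bins), 1L),
          collapse = ", "), "\n")

subs <- sort(unique(sub("_(perception|imagery)\\.h5$", "",
                        list.files("results/epochs", pattern = "\\.h5$"))))
spect <- NULL
for (s in subs) {
  out <- list()
  for (task in c("perception", "imagery")) {
    ep <- read_epochs(sprintf("results/epochs/%s_%s.h5", s, task))
    tf <- downsample_tf(baseline_normalize(morlet_power(ep, grid)), 50)
    out[[task]] <- lapply(bands, band_vectors, tf = tf, mode = "average")
    if (task == "perception") {
      truth <- jsonlite::read_json(sprintf("results/epochs/%s_truth.json", s),
                                   simplifyVector = TRUE)
      sig <- match(truth$signal_channels, ep$channels)
      m <- apply(tf$power[, sig, , ], c(3, 4), mean)
      spect <- if (is.null(spect)) m else spect + m
      tf_times <- tf$times
    }
  }
  saveRDS(out, sprintf("results/bands/%s.rds", s))
  cat("decomposed", s, "\n")
}
spect <- spect / length(subs)
utils::write.csv(
  data.frame(freq_hz = rep(grid$bin_centers, ncol(spect)),
             time_ms = rep(tf_times, each = nrow(spect)),
             power_db = as.vector(spect)),
  "results/tf_grand_average.csv", row.names = FALSE)
cat("grand-average signal-channel spectrogram -> results/tf_grand_average.csv\n")
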