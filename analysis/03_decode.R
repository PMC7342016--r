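#!/usr/bin/env Rscript
# Cross-task time-generalization decoding per frequency band: pairwise
# linear SVMs (c = 1) on pseudo-trials, 20 repeats, both train-test
# directions averaged onto the perception-time x imagery-time plane, plus
# the posterior/anterior electrode-half variants for the alpha band and the
# broadband (raw voltage) control. Per-participant maps go to
# results/decoding/.

suppressPackageStartupMessages(library(alphashare))
dir.create("results/decoding", recursive = TRUE, showWarnings = FALSE)

pt <- seq(0, 800, by = 100)
it <- seq(0, 2400, by = 200)
n_repeats <- 20

subs <- sort(unique(sub("\\.rds$", "", list.files("results/bands"))))
for (s in subs) {
  bands <- readRDS(sprintf("results/bands/%s.rds", s))
  res <- list()
  for (b in names(bands$perception)) {
    res[[b]] <- cross_task_timegen(bands$perception[[b]], bands$imagery[[b]],
                                   pt, it, n_repeats = n_repeats,
                                   seed = 100 + match(s, subs))
  }
  for (h in c("posterior", "anterior")) {
    res[[paste0("alpha_", h)]] <- cross_task_timegen(
      electrode_subset(bands$perception$alpha, h),
      electrode_subset(bands$imagery$alpha, h),
      pt, it, n_repeats = n_repeats, seed = 100 + match(s, subs))
  }
  epp <- read_epochs(sprintf("results/epochs/%s_perception.h5", s))
  epi <- read_epochs(sprintf("results/epochs/%s_imagery.h5", s))
  res$broadband <- cross_task_timegen(
    broadband_vectors(epp), broadband_vectors(epi),
    pt, it, n_repeats = n_repeats, seed = 100 + match(s, subs))
  saveRDS(res, sprintf("results/decoding/%s.rds", s))
  cat(s, ": peak alpha accuracy",
      sprintf("%.1f%%", max(res$alpha$accuracy)), "\n")
}
cat("decoded", length(subs), "participants; maps in results/decoding/\n")
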