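# Shared desk-scale demo cohort for the recovery and calibration suites.
# Built once per test run and cached; only the band-resolved feature arrays
# are kept so memory stays modest.

.demo_cache <- new.env(parent = emptyenv())

demo_grids <- function() {
  list(pt = seq(0, 800, by = 100), it = seq(0, 2400, by = 200))
}

# slice a trial x feature x time array down to the analysis grid
slice_times <- function(bv, keep) {
  at <- attributes(bv)
  idx <- match(keep, at$times)
  out <- bv[, , idx, drop = FALSE]
  for (nm in setdiff(names(at), c("dim", "times"))) attr(out, nm) <- at[[nm]]
  attr(out, "times") <- keep
  out
}

demo_cohort_config <- function() {
  sim_config(n_participants = 10, n_channels = 16, n_objects = 6,
             trials_per_object_per_task = 12, sampling_rate = 250,
             posterior_fraction = 0.5, seed = 7)
}

demo_data <- function() {
  if (!is.null(.demo_cache$data)) return(.demo_cache$data)
  cfg <- demo_cohort_config()
  g <- log_spaced_grid(5, 31, 20)
  bands <- assign_bands(g)
  grids <- demo_grids()
  per_participant <- lapply(seq_len(cfg$n_participants), function(k) {
    p <- simulate_participant(cfg, k)
    tfp <- downsample_tf(baseline_normalize(
      morlet_power(p$epochs$perception, g)), 50)
    tfi <- downsample_tf(baseline_normalize(
      morlet_power(p$epochs$imagery, g)), 50)
    bv <- lapply(bands, function(b) list(
      p = band_vectors(tfp, b, "average"),
      i = band_vectors(tfi, b, "average")))
    bv$broadband <- list(
      p = slice_times(broadband_vectors(p$epochs$perception), grids$pt),
      i = slice_times(broadband_vectors(p$epochs$imagery), grids$it))
    list(bv = bv, ground_truth = p$ground_truth)
  })
  .demo_cache$data <- list(cfg = cfg, bands = bands, grids = grids,
                           participants = per_participant)
  .demo_cache$data
}

# group cluster inference on a list of timegen results
demo_group_cluster <- function(tgs, grids, bonferroni = 3, n_perm = 1000,
                               seed = 11) {
  maps <- t(vapply(tgs, function(tg) as.vector(tg$accuracy),
                   numeric(length(tgs[[1]]$accuracy))))
  perm <- sign_permutation_p(maps, n_perm = n_perm, chance_level = 50,
                             seed = seed)
  cluster_correct(perm, c(length(grids$pt), length(grids$it)),
                  bonferroni_factor = bonferroni)
}
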