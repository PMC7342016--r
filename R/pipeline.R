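#' Epoch container I/O (HDF5)
#'
#' Writes/reads an `epoch_set` to the package's HDF5 layout: `/data`
#' (trial x channel x time), `/times` (ms), `/channels`, `/labels/task`,
#' `/labels/object`, with `sampling_rate` (Hz) and `units` (µV) as root
#' attributes. Round trips are bit-identical.
#'
#' @param epochs an `epoch_set`.
#' @param path HDF5 file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns an
#'   `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(epochs$data, path, "data")
  rhdf5::h5write(epochs$times, path, "times")
  rhdf5::h5write(epochs$channels, path, "channels")
  rhdf5::h5createGroup(path, "labels")
  rhdf5::h5write(epochs$task, path, "labels/task")
  rhdf5::h5write(as.integer(epochs$object), path, "labels/object")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(epochs$sampling_rate, fid, "sampling_rate")
  rhdf5::h5writeAttribute("uV", fid, "units")
  rhdf5::H5Fclose(fid)
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls <- rhdf5::h5ls(path)
  present <- file.path(ifelse(ls$group == "/", "", ls$group), ls$name)
  present <- sub("^/", "", sub("^//", "", present))
  need <- c("data", "times", "channels", "labels/task", "labels/object")
  missing <- setdiff(need, present)
  if (length(missing) > 0)
    stop("epoch container schema violation: missing ",
         paste(missing, collapse = ", "))
  data <- rhdf5::h5read(path, "data")
  times <- as.vector(rhdf5::h5read(path, "times"))
  channels <- as.vector(rhdf5::h5read(path, "channels"))
  task <- as.vector(rhdf5::h5read(path, "labels/task"))
  object <- as.vector(rhdf5::h5read(path, "labels/object"))
  sr <- rhdf5::h5readAttributes(path, "/")$sampling_rate
  rhdf5::h5closeAll()
  if (is.null(sr))
    stop("epoch container schema violation: missing sampling_rate attribute")
  if (dim(data)[1] != length(task) || dim(data)[1] != length(object))
    stop("epoch container schema violation: trial count mismatch between ",
         "/data and /labels")
  if (dim(data)[2] != length(channels))
    stop("epoch container schema violation: channel count mismatch")
  if (dim(data)[3] != length(times))
    stop("epoch container schema violation: time axis length mismatch")
  structure(list(data = data, task = task, object = object, times = times,
                 channels = channels, sampling_rate = as.numeric(sr)),
            class = "epoch_set")
}

#' Realign imagery epochs to word offset
#'
#' Shifts each trial's time axis so that 0 marks the offset of the spoken
#' cue word (per-trial duration), then crops all trials to the common valid
#' window. Shifts are rounded to whole samples.
#'
#' @param epochs an `epoch_set` (imagery task).
#' @param word_duration_ms per-trial cue durations in ms (>= 0).
#' @return realigned, cropped `epoch_set`.
#' @export
align_to_offset <- function(epochs, word_duration_ms) {
  stopifnot(inherits(epochs, "epoch_set"),
            length(word_duration_ms) == dim(epochs$data)[1])
  if (any(word_duration_ms < 0)) stop("durations must be nonnegative")
  fs <- epochs$sampling_rate
  n <- length(epochs$times)
  k <- round(word_duration_ms * fs / 1000)
  if (any(k >= n)) stop("a word duration exceeds the epoch length")
  kmin <- min(k); kmax <- max(k)
  n2 <- n - (kmax - kmin)
  step <- 1000 / fs
  out <- array(0, dim = c(dim(epochs$data)[1], dim(epochs$data)[2], n2))
  for (tr in seq_len(dim(epochs$data)[1])) {
    idx <- seq_len(n2) + (k[tr] - kmin)
    out[tr, , ] <- epochs$data[tr, , idx]
  }
  epochs$data <- out
  epochs$times <- epochs$times[seq_len(n2)] - kmin * step
  epochs
}

#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis. Defaults are the
#' full-scale study parameters (100 pseudo-trial repeats, 10,000
#' permutations, 20 ms analysis grid over perception 0-800 ms and imagery
#' 0-2,500 ms, Bonferroni x3 over bands); pass coarser grids and smaller
#' counts for desk-scale runs.
#'
#' @param sim a [sim_config()] describing the synthetic cohort (or `NULL`
#'   when epochs are supplied to [run_pipeline()] directly).
#' @param bands band definitions ([canonical_bands()]).
#' @param mode frequency aggregation mode for [band_vectors()].
#' @param n_pseudo,n_repeats,cost decoding parameters.
#' @param perception_times,imagery_times analysis grids in ms.
#' @param wavelet_length,baseline_window,target_rate decomposition settings.
#' @param n_perm,cluster_def_p,cluster_p,bonferroni_factor,connectivity
#'   statistics settings.
#' @param run_within,run_broadband,run_halves optional analysis variants.
#' @param models optional named list of model families, each a named list of
#'   object x feature matrices (or an `rdm` directly) for RSA.
#' @param seed master seed; stage seeds are derived from it.
#' @return `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       bands = canonical_bands(),
                       mode = "average",
                       n_pseudo = 4, n_repeats = 100, cost = 1,
                       perception_times = seq(0, 800, by = 20),
                       imagery_times = seq(0, 2500, by = 20),
                       wavelet_length = 600,
                       baseline_window = c(-500, -300),
                       target_rate = 50,
                       n_perm = 10000, cluster_def_p = 0.05,
                       cluster_p = 0.05, bonferroni_factor = 3,
                       connectivity = 8,
                       run_within = FALSE, run_broadband = FALSE,
                       run_halves = FALSE,
                       models = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

# time-frequency front end shared by the pipeline stages
.tf_pipeline <- function(epochs, grid, cfg) {
  tf <- morlet_power(epochs, grid, cfg$wavelet_length)
  tf <- baseline_normalize(tf, cfg$baseline_window)
  downsample_tf(tf, cfg$target_rate)
}

# cross-task decoding of one participant for one feature array pair
.decode_participant <- function(bvp, bvi, cfg, seed) {
  cross_task_timegen(bvp, bvi, cfg$perception_times, cfg$imagery_times,
                     n_pseudo = cfg$n_pseudo, n_repeats = cfg$n_repeats,
                     cost = cfg$cost, seed = seed)
}

# group stats on a list of timegen results -> cluster_result
.group_cluster <- function(tgs, cfg, seed) {
  maps <- t(vapply(tgs, function(tg) as.vector(tg$accuracy),
                   numeric(length(tgs[[1]]$accuracy))))
  perm <- sign_permutation_p(maps, n_perm = cfg$n_perm, tail = "right",
                             chance_level = 50, seed = seed)
  cluster_correct(perm, dim(tgs[[1]]$accuracy),
                  cluster_def_p = cfg$cluster_def_p,
                  cluster_p = cfg$cluster_p,
                  bonferroni_factor = cfg$bonferroni_factor,
                  connectivity = cfg$connectivity)
}

#' Run the end-to-end analysis on a synthetic cohort
#'
#' Orchestrates the full graph: simulation (or supplied epochs) -> Morlet
#' decomposition, dB baseline, 50 Hz downsampling -> band-resolved
#' cross-task time-generalization decoding per participant -> group
#' sign-permutation + cluster-size statistics per band -> (optionally)
#' within-task decoding, broadband decoding, electrode-half decoding ->
#' representational similarity analysis of the alpha cluster against model
#' RDMs with FDR correction per model family.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-generated cohort (list as returned by
#'   [simulate_cohort()]); generated from `cfg$sim` when `NULL`.
#' @param out_dir optional directory for CSV/JSON artifacts.
#' @return result bundle: list with `timegen` (band -> list of per
#'   participant `timegen`), `stats` (band -> `cluster_result`), and when
#'   requested `within`, `broadband`, `halves`, `rsa`; plus `config`.
#' @export
run_pipeline <- function(cfg, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(cfg$sim)
  n_sub <- length(cohort)
  grid <- log_spaced_grid(5, 31, 20)
  bands <- assign_bands(grid, cfg$bands)
  tfs <- lapply(cohort, function(p)
    list(perception = .tf_pipeline(p$epochs$perception, grid, cfg),
         imagery = .tf_pipeline(p$epochs$imagery, grid, cfg)))

  res <- list(config = cfg)
  res$timegen <- lapply(bands, function(band) {
    lapply(seq_len(n_sub), function(k) {
      bvp <- band_vectors(tfs[[k]]$perception, band, cfg$mode)
      bvi <- band_vectors(tfs[[k]]$imagery, band, cfg$mode)
      .decode_participant(bvp, bvi, cfg, seed = cfg$seed + 101L * k)
    })
  })
  res$stats <- lapply(names(bands), function(nm)
    .group_cluster(res$timegen[[nm]], cfg, seed = cfg$seed + 7L))
  names(res$stats) <- names(bands)

  if (cfg$run_within) {
    res$within <- lapply(bands, function(band) {
      lapply(seq_len(n_sub), function(k) {
        bvp <- band_vectors(tfs[[k]]$perception, band, cfg$mode)
        within_task_cv(bvp, cfg$perception_times, cfg$n_pseudo,
                       cfg$n_repeats, cfg$cost, seed = cfg$seed + 211L * k)
      })
    })
  }
  if (cfg$run_broadband) {
    res$broadband <- lapply(seq_len(n_sub), function(k) {
      bvp <- broadband_vectors(cohort[[k]]$epochs$perception)
      bvi <- broadband_vectors(cohort[[k]]$epochs$imagery)
      pt <- intersect(cfg$perception_times, attr(bvp, "times"))
      it <- intersect(cfg$imagery_times, attr(bvi, "times"))
      cross_task_timegen(bvp, bvi, pt, it, cfg$n_pseudo, cfg$n_repeats,
                         cfg$cost, seed = cfg$seed + 307L * k)
    })
    res$stats$broadband <- .group_cluster(res$broadband, cfg,
                                          seed = cfg$seed + 7L)
  }
  if (cfg$run_halves) {
    res$halves <- lapply(c(anterior = "anterior", posterior = "posterior"),
                         function(h) {
      lapply(seq_len(n_sub), function(k) {
        bvp <- electrode_subset(
          band_vectors(tfs[[k]]$perception, bands$alpha, cfg$mode), h)
        bvi <- electrode_subset(
          band_vectors(tfs[[k]]$imagery, bands$alpha, cfg$mode), h)
        .decode_participant(bvp, bvi, cfg, seed = cfg$seed + 401L * k)
      })
    })
    for (h in names(res$halves))
      res$stats[[paste0("alpha_", h)]] <-
        .group_cluster(res$halves[[h]], cfg, seed = cfg$seed + 7L)
  }
  if (!is.null(cfg$models)) {
    res$rsa <- run_rsa(res$timegen$alpha, res$stats$alpha$significant_mask,
                       cfg$models, n_perm = cfg$n_perm,
                       seed = cfg$seed + 13L)
  }
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Representational similarity analysis stage
#'
#' Builds per-participant neural RDMs from the time points of a significant
#' cross-decoding cluster and correlates them (Spearman) with every model
#' RDM, testing the group of coefficients against zero with sign
#' permutations and FDR-correcting across RDMs within each model family.
#'
#' @param tgs list of per-participant `timegen` objects (alpha band).
#' @param cluster_mask logical map of the significant cluster.
#' @param models named list of families; each family is a named list whose
#'   elements are either object x feature matrices or `rdm` objects.
#' @param n_perm permutations for the group test.
#' @param seed RNG seed.
#' @return list per family: data.frame with `rdm`, `mean_r`, `p`,
#'   `p_fdr`, `significant`; plus `neural_rdms`.
#' @export
run_rsa <- function(tgs, cluster_mask, models, n_perm = 10000, seed = 1L) {
  neural <- lapply(tgs, neural_rdm_from_cluster, cluster_mask = cluster_mask)
  fam_res <- lapply(models, function(family) {
    rs <- lapply(family, function(m) {
      rdm <- if (inherits(m, "rdm")) m else model_rdm(m)
      compare_rdms(neural, rdm)
    })
    p <- vapply(rs, function(r)
      sign_permutation_p(matrix(r, ncol = 1), n_perm = n_perm,
                         tail = "right", chance_level = 0,
                         seed = seed)$p_obs,
      numeric(1))
    fdr <- fdr_correct(p)
    data.frame(rdm = names(family),
               mean_r = vapply(rs, mean, numeric(1)),
               p = p, p_fdr = fdr$adjusted,
               significant = fdr$significant,
               row.names = NULL)
  })
  list(families = fam_res, neural_rdms = neural)
}

#' Write pipeline artifacts
#'
#' Exports group-mean accuracy maps and cluster summaries as CSV/JSON under
#' `out_dir`, together with a manifest of file checksums.
#'
#' @param res a [run_pipeline()] result bundle.
#' @param out_dir output directory (created if needed).
#' @return invisible vector of file paths written.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(res$timegen)) {
    grand <- Reduce(`+`, lapply(res$timegen[[nm]], `[[`, "accuracy")) /
      length(res$timegen[[nm]])
    p <- file.path(out_dir, paste0("timegen_", nm, ".csv"))
    utils::write.csv(data.frame(
      perception_ms = rep(res$timegen[[nm]][[1]]$perception_times,
                          times = ncol(grand)),
      imagery_ms = rep(res$timegen[[nm]][[1]]$imagery_times,
                       each = nrow(grand)),
      accuracy = as.vector(grand)), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  summ <- lapply(res$stats, function(cr) list(
    sizes = cr$sizes, significant = cr$significant,
    size_threshold = cr$size_threshold,
    cluster_p_values = cr$cluster_p_values,
    n_permutations = cr$n_permutations))
  p <- file.path(out_dir, "cluster_summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  if (!is.null(res$rsa)) {
    for (fam in names(res$rsa$families)) {
      p <- file.path(out_dir, paste0("rsa_", fam, ".csv"))
      utils::write.csv(res$rsa$families[[fam]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  mp <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(c(paths, mp))
}
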