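#' Pseudo-trial averaging
#'
#' Raises SNR before classification by averaging random disjoint shares of
#' same-condition trials: each condition's trials are randomly partitioned
#' into `n_pseudo` equal groups (default 4, i.e. 25% shares) and each
#' pseudo-trial is the mean of one group. Trials that do not divide evenly
#' are dropped at random. Partitions are meant to be redrawn on every
#' decoding repeat.
#'
#' @param x trial x feature x time array as returned by [band_vectors()] or
#'   [broadband_vectors()]; needs an `object` attribute with per-trial
#'   condition labels.
#' @param n_pseudo number of pseudo-trials per condition.
#' @return list with `vectors` (condition x pseudo x feature x time array),
#'   `n_pseudo`, `objects` (condition labels in row order).
#' @export
make_pseudotrials <- function(x, n_pseudo = 4) {
  obj <- attr(x, "object")
  stopifnot(!is.null(obj), length(obj) == dim(x)[1])
  conds <- sort(unique(obj))
  d <- dim(x)
  out <- array(0, dim = c(length(conds), n_pseudo, d[2], d[3]))
  for (ci in seq_along(conds)) {
    idx <- which(obj == conds[ci])
    share <- length(idx) %/% n_pseudo
    if (share < 1)
      stop("condition ", conds[ci], " has fewer than n_pseudo trials")
    idx <- sample(idx, share * n_pseudo)          # drops remainder at random
    grp <- rep(seq_len(n_pseudo), each = share)
    for (p in seq_len(n_pseudo)) {
      sel <- idx[grp == p]
      out[ci, p, , ] <- colMeans(matrix(x[sel, , , drop = FALSE],
                                        length(sel), d[2] * d[3]))
    }
  }
  list(vectors = out, n_pseudo = n_pseudo, objects = conds)
}

#' Train a pairwise linear maximum-margin classifier
#'
#' Linear C-SVC with cost 1 (libsvm via e1071), no feature scaling. The
#' returned decision rule is `score(x) = x . weights + bias`, positive for
#' class A (the first argument).
#'
#' @param class_a,class_b exemplar x feature matrices.
#' @param cost SVM cost parameter (default 1).
#' @return list with `weights`, `bias`; `score > 0` predicts `class_a`.
#' @export
train_pair_classifier <- function(class_a, class_b, cost = 1) {
  if (nrow(class_a) < 1 || nrow(class_b) < 1)
    stop("need at least one exemplar per class")
  x <- rbind(class_a, class_b)
  y <- factor(rep(c("a", "b"), c(nrow(class_a), nrow(class_b))),
              levels = c("a", "b"))
  m <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  # libsvm's positive decision value corresponds to the first label seen in
  # the training data, i.e. class_a given the rbind order above
  list(weights = w, bias = -m$rho)
}

# exemplar slab for one condition/time: pseudo x feature matrix
.pt_slice <- function(ps, cond, t_idx) {
  matrix(ps$vectors[cond, , , t_idx], ps$n_pseudo, dim(ps$vectors)[3])
}

# all test times at once: (pseudo * n_times) x feature matrix, time-major
.pt_stack <- function(ps, cond, t_idx) {
  v <- ps$vectors[cond, , , t_idx, drop = FALSE]     # 1 x pseudo x feat x nt
  d <- dim(v)
  matrix(aperm(array(v, d[2:4]), c(1, 3, 2)), d[2] * d[4], d[3])
}

#' Cross-task time-generalization decoding
#'
#' For every unordered object pair, every repeat (fresh pseudo-trial
#' partitions), and every combination of a perception time and an imagery
#' time, trains a pairwise linear SVM on all pseudo-trials of one task and
#' tests it on all pseudo-trials of the other. Both train-test directions
#' are run and averaged onto the same perception-time x imagery-time cell,
#' so the axes are always oriented perception x imagery regardless of
#' direction. Accuracy is the fraction of the 2 x `n_pseudo` test
#' pseudo-trials classified correctly, averaged over pairs, repeats and
#' directions.
#'
#' @param bv_perception,bv_imagery trial x feature x time arrays
#'   ([band_vectors()] output) for the two tasks; must share the feature
#'   dimension.
#' @param perception_times,imagery_times analysis time points in ms; must be
#'   present on the respective arrays' time axes.
#' @param n_pseudo pseudo-trials per condition (default 4).
#' @param n_repeats pseudo-trial assignment repeats (default 100).
#' @param cost SVM cost parameter.
#' @param seed RNG seed for the pseudo-trial partitions.
#' @param directions which train-test directions to run and average
#'   (default both).
#' @return `timegen` object: list with `accuracy` (perception-time x
#'   imagery-time %, mean over pairs), `per_pair` (perception-time x
#'   imagery-time x object x object %, symmetric, NA diagonal),
#'   `perception_times`, `imagery_times`, `objects`, `n_repeats`.
#' @export
cross_task_timegen <- function(bv_perception, bv_imagery,
                               perception_times, imagery_times,
                               n_pseudo = 4, n_repeats = 100, cost = 1,
                               seed = 1L,
                               directions = c("train_perception",
                                              "train_imagery")) {
  directions <- match.arg(directions, several.ok = TRUE,
                          choices = c("train_perception", "train_imagery"))
  tp_idx <- match(perception_times, attr(bv_perception, "times"))
  ti_idx <- match(imagery_times, attr(bv_imagery, "times"))
  if (anyNA(tp_idx) || anyNA(ti_idx))
    stop("requested analysis times not on the data's time axis")
  if (dim(bv_perception)[2] != dim(bv_imagery)[2])
    stop("tasks must share the feature dimension")
  objs <- sort(unique(attr(bv_perception, "object")))
  n_obj <- length(objs)
  pairs <- utils::combn(n_obj, 2)
  npt <- length(tp_idx); nit <- length(ti_idx)
  acc_pair <- array(0, dim = c(npt, nit, ncol(pairs)))
  set.seed(seed)
  for (rep_i in seq_len(n_repeats)) {
    ps_p <- make_pseudotrials(bv_perception, n_pseudo)
    ps_i <- make_pseudotrials(bv_imagery, n_pseudo)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if ("train_perception" %in% directions) {
        test_x <- rbind(.pt_stack(ps_i, i, ti_idx), .pt_stack(ps_i, j, ti_idx))
        truth <- rep(c(TRUE, FALSE), each = n_pseudo * nit)
        for (a in seq_len(npt)) {
          fit <- train_pair_classifier(.pt_slice(ps_p, i, tp_idx[a]),
                                       .pt_slice(ps_p, j, tp_idx[a]), cost)
          sc <- drop(test_x %*% fit$weights) + fit$bias
          ok <- matrix((sc > 0) == truth, n_pseudo, 2 * nit)
          hits <- colMeans(ok)
          acc_pair[a, , k] <- acc_pair[a, , k] +
            (hits[seq_len(nit)] + hits[nit + seq_len(nit)]) / 2
        }
      }
      if ("train_imagery" %in% directions) {
        test_x <- rbind(.pt_stack(ps_p, i, tp_idx), .pt_stack(ps_p, j, tp_idx))
        truth <- rep(c(TRUE, FALSE), each = n_pseudo * npt)
        for (b in seq_len(nit)) {
          fit <- train_pair_classifier(.pt_slice(ps_i, i, ti_idx[b]),
                                       .pt_slice(ps_i, j, ti_idx[b]), cost)
          sc <- drop(test_x %*% fit$weights) + fit$bias
          ok <- matrix((sc > 0) == truth, n_pseudo, 2 * npt)
          hits <- colMeans(ok)
          acc_pair[, b, k] <- acc_pair[, b, k] +
            (hits[seq_len(npt)] + hits[npt + seq_len(npt)]) / 2
        }
      }
    }
  }
  acc_pair <- 100 * acc_pair / (n_repeats * length(directions))
  per_pair <- array(NA_real_, dim = c(npt, nit, n_obj, n_obj))
  for (k in seq_len(ncol(pairs))) {
    per_pair[, , pairs[1, k], pairs[2, k]] <- acc_pair[, , k]
    per_pair[, , pairs[2, k], pairs[1, k]] <- acc_pair[, , k]
  }
  structure(list(accuracy = apply(acc_pair, c(1, 2), mean),
                 per_pair = per_pair,
                 perception_times = perception_times,
                 imagery_times = imagery_times,
                 objects = objs, n_repeats = n_repeats,
                 band = attr(bv_perception, "band")),
            class = "timegen")
}

#' Within-task decoding time course (leave-one-pseudo-trial-out)
#'
#' Pairwise classification within one task with training and testing times
#' yoked. Per repeat and pair, each of the `n_pseudo` folds holds out one
#' pseudo-trial per condition for testing and trains on the rest; fold,
#' pair and repeat accuracies are averaged.
#'
#' @param bv trial x feature x time array for one task.
#' @param times analysis time points (ms).
#' @inheritParams cross_task_timegen
#' @return `within_timecourse` object: list with `accuracy` (time vector,
#'   %), `per_pair` (time x object x object), `times`, `objects`.
#' @export
within_task_cv <- function(bv, times, n_pseudo = 4, n_repeats = 100,
                           cost = 1, seed = 1L) {
  t_idx <- match(times, attr(bv, "times"))
  if (anyNA(t_idx)) stop("requested analysis times not on the data's time axis")
  objs <- sort(unique(attr(bv, "object")))
  n_obj <- length(objs)
  pairs <- utils::combn(n_obj, 2)
  nt <- length(t_idx)
  acc_pair <- array(0, dim = c(nt, ncol(pairs)))
  set.seed(seed)
  for (rep_i in seq_len(n_repeats)) {
    ps <- make_pseudotrials(bv, n_pseudo)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      for (a in seq_len(nt)) {
        xi <- .pt_slice(ps, i, t_idx[a])
        xj <- .pt_slice(ps, j, t_idx[a])
        hits <- 0
        for (fold in seq_len(n_pseudo)) {
          fit <- train_pair_classifier(xi[-fold, , drop = FALSE],
                                       xj[-fold, , drop = FALSE], cost)
          sc <- drop(rbind(xi[fold, ], xj[fold, ]) %*% fit$weights) + fit$bias
          hits <- hits + mean((sc > 0) == c(TRUE, FALSE))
        }
        acc_pair[a, k] <- acc_pair[a, k] + hits / n_pseudo
      }
    }
  }
  acc_pair <- 100 * acc_pair / n_repeats
  per_pair <- array(NA_real_, dim = c(nt, n_obj, n_obj))
  for (k in seq_len(ncol(pairs))) {
    per_pair[, pairs[1, k], pairs[2, k]] <- acc_pair[, k]
    per_pair[, pairs[2, k], pairs[1, k]] <- acc_pair[, k]
  }
  structure(list(accuracy = rowMeans(acc_pair), per_pair = per_pair,
                 times = times, objects = objs, n_repeats = n_repeats),
            class = "within_timecourse")
}

# ad-hoc frequency grid at arbitrary centers (used for the 1 Hz-resolution
# individual-alpha decomposition)
freq_grid_at <- function(centers) {
  structure(list(bin_centers = centers, range = range(centers),
                 spacing = "custom"),
            class = "freq_grid")
}

#' Participant-specific peak alpha frequency and band
#'
#' Runs a 1 Hz-resolution Morlet decomposition on the integer grid 7-14 Hz,
#' then for every candidate frequency f in 8..13 Hz performs within-task
#' perception decoding on the 3-bin band {f-1, f, f+1}. The peak alpha
#' frequency is the candidate with the highest time-averaged accuracy (ties
#' broken toward the lowest frequency); the participant's band is
#' {peak-1, peak, peak+1} Hz.
#'
#' @param perception_epochs `epoch_set` for the perception task.
#' @param times analysis time points (ms, on the downsampled axis).
#' @param candidates integer candidate frequencies (default 8:13).
#' @param wavelet_length,baseline_window,target_rate decomposition settings
#'   as in [morlet_power()] / [baseline_normalize()] / [downsample_tf()].
#' @inheritParams cross_task_timegen
#' @return list with `peak` (Hz), `band` (`c(peak-1, peak+1)`), `accuracy`
#'   (per candidate, time-averaged %).
#' @export
peak_alpha_band <- function(perception_epochs, times, candidates = 8:13,
                            wavelet_length = 600,
                            baseline_window = c(-500, -300),
                            target_rate = 50,
                            n_pseudo = 4, n_repeats = 20, cost = 1,
                            seed = 1L) {
  grid <- freq_grid_at(seq(min(candidates) - 1, max(candidates) + 1))
  tf <- morlet_power(perception_epochs, grid, wavelet_length)
  tf <- baseline_normalize(tf, baseline_window)
  tf <- downsample_tf(tf, target_rate)
  acc <- vapply(candidates, function(f) {
    band <- structure(list(name = paste0("alpha", f),
                           nominal_range = c(f - 1, f + 1),
                           member_bins = match((f - 1):(f + 1),
                                               grid$bin_centers)),
                      class = "band_spec")
    bv <- band_vectors(tf, band, "average")
    mean(within_task_cv(bv, times, n_pseudo, n_repeats, cost, seed)$accuracy)
  }, numeric(1))
  peak <- candidates[which.max(acc)]          # which.max -> lowest on ties
  list(peak = peak, band = c(peak - 1, peak + 1),
       accuracy = stats::setNames(acc, candidates))
}

#' Split perception trials by net alpha power change
#'
#' Classifies every trial as alpha-enhanced (mean baseline-normalized alpha
#' power over the post-stimulus window and all channels > 0 dB) or
#' alpha-suppressed, then randomly subsamples the larger class to the
#' smaller one's size so downstream decoding is unbiased.
#'
#' @param tf baseline-normalized `tf_epochs` for the perception task.
#' @param alpha_band `band_spec` for the alpha band.
#' @param window post-stimulus window (ms) for the per-trial statistic
#'   (default the full 0-800 ms perception window).
#' @param seed RNG seed for the subsampling.
#' @return list with `enhanced`, `suppressed` (trial indices),
#'   `equalized` (both sets after subsampling) and `stat` (per-trial dB).
#' @export
alpha_power_split <- function(tf, alpha_band, window = c(0, 800), seed = 1L) {
  stopifnot(inherits(tf, "tf_epochs"), isTRUE(tf$normalized))
  t_idx <- which(tf$times >= window[1] & tf$times <= window[2])
  sub <- tf$power[, , alpha_band$member_bins, t_idx, drop = FALSE]
  stat <- apply(sub, 1, mean)
  enhanced <- which(stat > 0)
  suppressed <- which(stat <= 0)
  if (length(enhanced) == 0 || length(suppressed) == 0)
    stop("alpha power split produced an empty class (",
         length(enhanced), " enhanced, ", length(suppressed),
         " suppressed)")
  set.seed(seed)
  n <- min(length(enhanced), length(suppressed))
  list(enhanced = enhanced, suppressed = suppressed,
       equalized = list(enhanced = sort(sample(enhanced, n)),
                        suppressed = sort(sample(suppressed, n))),
       stat = stat)
}

#' Broadband voltage patterns for decoding
#'
#' Returns raw per-trial voltage patterns (trial x channel x time) at the
#' acquisition resolution, optionally baseline-corrected by subtracting each
#' channel's pre-stimulus mean per trial, in the same layout that
#' [band_vectors()] produces, so the identical pseudo-trial and
#' classification machinery applies without any frequency decomposition.
#'
#' @param epochs an `epoch_set`.
#' @param baseline_correct subtract per-trial/channel pre-stimulus mean.
#' @param baseline_window window for the correction (ms).
#' @return trial x feature x time array with `times`, `object`, `task`,
#'   `channels` attributes.
#' @export
broadband_vectors <- function(epochs, baseline_correct = TRUE,
                              baseline_window = c(-600, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  x <- epochs$data
  if (baseline_correct) {
    idx <- which(epochs$times >= baseline_window[1] &
                 epochs$times < baseline_window[2])
    base <- apply(x[, , idx, drop = FALSE], c(1, 2), mean)
    x <- x - as.vector(base)
  }
  structure(x, times = epochs$times, task = epochs$task,
            object = epochs$object, channels = epochs$channels,
            band = "broadband", mode = "broadband")
}
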