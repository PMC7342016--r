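#' Group-level sign-permutation test
#'
#' Nonparametric test of a group mean against chance: under the null each
#' participant's whole (chance-centered) map is equally likely to carry
#' either sign, so the null distribution is built by flipping every
#' participant's map by an independent +/-1 and recomputing the group mean.
#' One seeded permutation schedule (with the identity permutation included
#' as the first sample) is shared across all map cells, and the permuted
#' maps are converted to p-values against the same empirical distribution,
#' as required for cluster-size inference.
#'
#' @param values participant x cell matrix (flatten a map over its cells);
#'   a plain vector is treated as a single-cell sample, one value per
#'   participant.
#' @param n_perm number of random sign flips (default 10000); the identity
#'   is added on top, so the minimum attainable p is `1/(n_perm + 1)`.
#' @param tail `"right"` (directional, default) or `"two"`.
#' @param chance_level value subtracted from every cell before testing
#'   (50 for accuracies, 0 for correlations).
#' @param seed RNG seed for the permutation schedule.
#' @return list with `p_obs` (per-cell p-values), `stat_obs` (observed group
#'   means, chance-centered), `p_perm` ((n_perm+1) x cell matrix of
#'   p-values, row 1 = observed) and `n_samples = n_perm + 1`.
#' @export
sign_permutation_p <- function(values, n_perm = 10000,
                               tail = c("right", "two"),
                               chance_level = 0, seed = 1L) {
  tail <- match.arg(tail)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (!all(is.finite(values))) stop("nonfinite values in group sample")
  if (nrow(values) < 2) stop("need at least 2 participants")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  v <- values - chance_level
  n <- nrow(v)
  set.seed(seed)
  signs <- rbind(rep(1, n),
                 matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                        n_perm, n))
  s <- (signs %*% v) / n
  if (tail == "two") s <- abs(s)
  nr <- nrow(s)
  p <- apply(s, 2, function(col) {
    (nr - rank(col, ties.method = "min") + 1) / nr
  })
  p <- matrix(p, nrow = nr)
  list(p_obs = p[1, ], stat_obs = s[1, ], p_perm = p, n_samples = nr)
}

#' Cluster-size inference on permutation p-maps
#'
#' Thresholds the observed and every permuted p-map at the
#' cluster-definition threshold, groups supra-threshold cells by contiguity
#' (1-D: adjacent samples; 2-D: 8-connectivity by default), builds the
#' empirical distribution of the maximum cluster size across permutations,
#' and reports observed clusters whose size exceeds the
#' `1 - cluster_p / bonferroni_factor` quantile of that distribution. The
#' Bonferroni factor accounts for tests run in parallel (3 for the three
#' frequency bands).
#'
#' @param perm a result of [sign_permutation_p()] computed on the flattened
#'   map.
#' @param map_dim `c(nrow, ncol)` of the map (use `c(n, 1)` for a time
#'   course).
#' @param cluster_def_p cluster-definition threshold (default 0.05).
#' @param cluster_p cluster-size threshold (default 0.05).
#' @param bonferroni_factor divide `cluster_p` by this (default 1).
#' @param connectivity 4 or 8 (2-D maps only; default 8).
#' @return `cluster_result`: list with `p_map`, `clusters` (list of cell
#'   index vectors), `sizes`, `null_max_sizes`, `size_threshold`,
#'   `significant` (per cluster), `significant_mask` (map-shaped logical),
#'   `cluster_p_values`.
#' @export
cluster_correct <- function(perm, map_dim, cluster_def_p = 0.05,
                            cluster_p = 0.05, bonferroni_factor = 1,
                            connectivity = 8) {
  stopifnot(is.list(perm), !is.null(perm$p_perm))
  cells <- prod(map_dim)
  if (ncol(perm$p_perm) != cells)
    stop("map_dim does not match the permutation p-map width")
  obs_mask <- perm$p_obs < cluster_def_p
  lab <- .label_clusters(obs_mask, map_dim[1], map_dim[2], connectivity)
  null_max <- .max_cluster_sizes(perm$p_perm < cluster_def_p,
                                 map_dim[1], map_dim[2], connectivity)
  alpha <- cluster_p / bonferroni_factor
  size_threshold <- stats::quantile(null_max, 1 - alpha, type = 1,
                                    names = FALSE)
  sizes <- lab$sizes
  clusters <- lapply(seq_along(sizes), function(k) which(lab$labels == k))
  significant <- sizes > size_threshold
  cl_p <- vapply(sizes, function(s) mean(null_max >= s), numeric(1))
  mask <- matrix(FALSE, map_dim[1], map_dim[2])
  for (k in which(significant)) mask[clusters[[k]]] <- TRUE
  structure(list(p_map = matrix(perm$p_obs, map_dim[1], map_dim[2]),
                 clusters = clusters, sizes = sizes,
                 null_max_sizes = null_max,
                 size_threshold = size_threshold,
                 significant = significant,
                 significant_mask = mask,
                 cluster_p_values = cl_p,
                 n_permutations = perm$n_samples - 1),
            class = "cluster_result")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control at level `q` (default 0.05), used across RDMs within
#' each model family.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `adjusted` p-values and logical `significant`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) stop("empty p-value list")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= q, q = q)
}

#' Peak decoding latency with bootstrap confidence interval
#'
#' Peak = argmax of the group-mean accuracy marginal along each task axis of
#' a time-generalization map; 95% CI by seeded percentile bootstrap over
#' participants.
#'
#' @param maps participant x perception-time x imagery-time array.
#' @param perception_times,imagery_times time axes in ms.
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list with `perception` and `imagery`, each `list(peak, ci)`.
#' @export
peak_latency_ci <- function(maps, perception_times, imagery_times,
                            n_boot = 1000, conf = 0.95, seed = 1L) {
  stopifnot(length(dim(maps)) == 3, dim(maps)[1] >= 2)
  grand <- apply(maps, c(2, 3), mean)
  if (diff(range(grand)) == 0)
    stop("flat accuracy map: peak latency undefined")
  peak_of <- function(m) {
    c(perception = perception_times[which.max(rowMeans(m))],
      imagery = imagery_times[which.max(colMeans(m))])
  }
  obs <- peak_of(grand)
  n <- dim(maps)[1]
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    peak_of(apply(maps[idx, , , drop = FALSE], c(2, 3), mean))
  })
  lo <- (1 - conf) / 2
  list(perception = list(peak = obs[["perception"]],
                         ci = unname(stats::quantile(boots["perception", ],
                                                     c(lo, 1 - lo)))),
       imagery = list(peak = obs[["imagery"]],
                      ci = unname(stats::quantile(boots["imagery", ],
                                                  c(lo, 1 - lo)))))
}
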