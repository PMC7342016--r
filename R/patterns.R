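#' Transform classifier weights into an activation pattern
#'
#' Linear-classifier weights are extraction filters and not directly
#' interpretable over sensors; multiplying them with the covariance of the
#' training data yields the corresponding activation pattern, whose
#' magnitude reflects how strongly each sensor expresses the discriminated
#' signal. The covariance is the pooled, class-mean-removed estimator with
#' 1/(n-1) normalization, computed over the exact exemplars the classifier
#' was trained on.
#'
#' @param weights feature-length weight vector.
#' @param training_data exemplar x feature matrix the classifier saw.
#' @param classes optional per-exemplar class labels; when given, each
#'   class's mean is removed before the covariance (pooled estimator),
#'   otherwise the grand mean is removed.
#' @return numeric activation pattern, same length as `weights`.
#' @export
weights_to_pattern <- function(weights, training_data, classes = NULL) {
  x <- as.matrix(training_data)
  if (nrow(x) < 2) stop("covariance undefined for a single training exemplar")
  if (length(weights) != ncol(x))
    stop("weights and training features disagree in length")
  if (is.null(classes)) {
    res <- scale(x, center = TRUE, scale = FALSE)
  } else {
    stopifnot(length(classes) == nrow(x))
    res <- x
    for (cl in unique(classes)) {
      sel <- classes == cl
      res[sel, ] <- scale(x[sel, , drop = FALSE], center = TRUE, scale = FALSE)
    }
  }
  covm <- crossprod(res) / (nrow(x) - 1)
  drop(covm %*% weights)
}

#' Sensor-space summary of activation patterns
#'
#' Averages the absolute activation patterns from many pairwise classifiers
#' over pairs, per channel and training time: the table a scalp topography
#' would be rendered from. Done separately for classifiers trained on
#' perception and on imagery.
#'
#' @param patterns pair x channel x time array (or channel x time matrix for
#'   a single classifier) of activation patterns.
#' @param channels channel names.
#' @param times training time points (ms).
#' @param task label recorded in the output (`"perception"` or
#'   `"imagery"`).
#' @return data.frame with columns `channel`, `time`, `mean_abs_pattern`,
#'   `task`.
#' @export
pattern_topography <- function(patterns, channels, times, task = "perception") {
  if (length(dim(patterns)) == 2)
    patterns <- array(patterns, dim = c(1, dim(patterns)))
  stopifnot(dim(patterns)[2] == length(channels),
            dim(patterns)[3] == length(times))
  m <- apply(abs(patterns), c(2, 3), mean)     # abs first, then average
  data.frame(channel = rep(channels, times = length(times)),
             time = rep(times, each = length(channels)),
             mean_abs_pattern = as.vector(m),
             task = task)
}

#' Activation patterns for every pairwise classifier at given times
#'
#' Convenience driver: for each unordered object pair and each requested
#' training time, fits the pairwise classifier on that time's pseudo-trials
#' and converts its weights into an activation pattern.
#'
#' @param bv trial x feature x time array for the training task
#'   (band-averaged, so features are channels).
#' @param times training time points (ms).
#' @param n_repeats pseudo-trial assignment repeats to average over.
#' @inheritParams cross_task_timegen
#' @return pair x channel x time array of activation patterns (mean over
#'   repeats).
#' @export
pairwise_patterns <- function(bv, times, n_pseudo = 4, n_repeats = 5,
                              cost = 1, seed = 1L) {
  t_idx <- match(times, attr(bv, "times"))
  if (anyNA(t_idx)) stop("requested times not on the data's time axis")
  objs <- sort(unique(attr(bv, "object")))
  pairs <- utils::combn(length(objs), 2)
  set.seed(seed)
  out <- array(0, dim = c(ncol(pairs), dim(bv)[2], length(times)))
  for (rep_i in seq_len(n_repeats)) {
    ps <- make_pseudotrials(bv, n_pseudo)
    for (k in seq_len(ncol(pairs))) {
      for (a in seq_along(t_idx)) {
        xi <- .pt_slice(ps, pairs[1, k], t_idx[a])
        xj <- .pt_slice(ps, pairs[2, k], t_idx[a])
        fit <- train_pair_classifier(xi, xj, cost)
        out[k, , a] <- out[k, , a] +
          weights_to_pattern(fit$weights, rbind(xi, xj),
                             rep(c(1, 2), each = n_pseudo))
      }
    }
  }
  out / n_repeats
}
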