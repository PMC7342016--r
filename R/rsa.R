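#' Neural RDM from a decoding cluster
#'
#' Pairwise decoding accuracy is a dissimilarity measure: the more
#' dissimilar two conditions' patterns, the easier they are to classify.
#' This extracts the full object x object matrix of pairwise accuracies at
#' every (train-time, test-time) cell inside a significant cluster and
#' averages over cells, yielding one representational dissimilarity matrix
#' per participant.
#'
#' @param tg a `timegen` object (see [cross_task_timegen()]).
#' @param cluster_mask logical perception-time x imagery-time matrix.
#' @param labels optional object names for dimnames.
#' @return `rdm` object: symmetric matrix with NA diagonal.
#' @export
neural_rdm_from_cluster <- function(tg, cluster_mask, labels = NULL) {
  stopifnot(inherits(tg, "timegen"))
  stopifnot(all(dim(cluster_mask) == dim(tg$accuracy)))
  cells <- which(cluster_mask, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty cluster mask")
  n_obj <- dim(tg$per_pair)[3]
  m <- matrix(0, n_obj, n_obj)
  for (r in seq_len(nrow(cells)))
    m <- m + tg$per_pair[cells[r, 1], cells[r, 2], , ]
  m <- m / nrow(cells)
  diag(m) <- NA
  as_rdm(m, labels, source = "neural_cross",
         dissimilarity_kind = "decoding accuracy")
}

#' Neural RDM from a within-task decoding cluster
#'
#' Same as [neural_rdm_from_cluster()] for the 1-D within-task time course:
#' averages the per-pair accuracy slices over the time points in the
#' within-task classification cluster.
#'
#' @param wt a `within_timecourse` object ([within_task_cv()]).
#' @param cluster_mask logical vector over the time axis.
#' @param labels optional object names.
#' @return `rdm` object.
#' @export
within_task_rdm <- function(wt, cluster_mask, labels = NULL) {
  stopifnot(inherits(wt, "within_timecourse"),
            length(cluster_mask) == length(wt$times))
  sel <- which(cluster_mask)
  if (length(sel) == 0) stop("empty cluster mask")
  m <- apply(wt$per_pair[sel, , , drop = FALSE], c(2, 3), mean)
  diag(m) <- NA
  as_rdm(m, labels, source = "neural_within",
         dissimilarity_kind = "decoding accuracy")
}

as_rdm <- function(m, labels = NULL, source = "model",
                   dissimilarity_kind = "1 - Pearson") {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  structure(m, class = c("rdm", "matrix"), source = source,
            dissimilarity_kind = dissimilarity_kind)
}

#' Model RDM from a feature matrix
#'
#' Dissimilarity between conditions i and j is 1 minus the Pearson
#' correlation of their feature rows.
#'
#' @param features condition x feature matrix (>= 2 columns); row names are
#'   used as condition labels when present.
#' @return `rdm` object.
#' @export
model_rdm <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) < 2)
    stop("need at least 2 feature columns for correlation")
  v <- apply(features, 1, stats::var)
  if (any(v == 0)) stop("zero-variance feature row; correlation undefined")
  m <- 1 - stats::cor(t(features))
  diag(m) <- NA
  as_rdm(m, rownames(features), source = "model",
         dissimilarity_kind = "1 - Pearson")
}

#' Binary superordinate-category model RDM
#'
#' Objects of the same category are coded as similar (-1) and objects of
#' different categories as dissimilar (+1). The canonical design has 4
#' categories (animals, body parts, plants, man-made objects) with 3 objects
#' each.
#'
#' @param category_assignment named vector/factor mapping each object to its
#'   category; `NA` entries are rejected.
#' @return `rdm` object with entries in {-1, +1}.
#' @export
category_rdm <- function(category_assignment) {
  if (anyNA(category_assignment)) stop("unassigned object in category model")
  cats <- as.character(category_assignment)
  m <- ifelse(outer(cats, cats, "=="), -1, 1)
  diag(m) <- NA
  as_rdm(m, names(category_assignment), source = "model",
         dissimilarity_kind = "binary +/-1")
}

#' Canonical 12-object category assignment
#'
#' Animals (butterfly, chicken, sheep), body parts (ear, eye, hand), plants
#' (apple, carrot, rose), man-made objects (car, chair, violin).
#' @return named character vector of length 12.
#' @export
canonical_categories <- function() {
  c(butterfly = "animal", chicken = "animal", sheep = "animal",
    ear = "body part", eye = "body part", hand = "body part",
    apple = "plant", carrot = "plant", rose = "plant",
    car = "man-made", chair = "man-made", violin = "man-made")
}

#' Aggregate 19 VGG-19 layer RDMs into 8 stage RDMs
#'
#' Convolutional layers between successive max-pooling stages are averaged
#' (layers 1-2, 3-4, 5-8, 9-12, 13-16); the three fully connected layers
#' (17, 18, 19) are kept individually.
#'
#' @param layer_rdms list of exactly 19 RDMs in architecture order.
#' @return list of 8 `rdm` objects named `conv1_2`, `conv3_4`, `conv5_8`,
#'   `conv9_12`, `conv13_16`, `fc17`, `fc18`, `fc19`.
#' @export
aggregate_vgg_rdms <- function(layer_rdms) {
  if (length(layer_rdms) != 19)
    stop("expected exactly 19 layer RDMs, got ", length(layer_rdms))
  groups <- list(conv1_2 = 1:2, conv3_4 = 3:4, conv5_8 = 5:8,
                 conv9_12 = 9:12, conv13_16 = 13:16,
                 fc17 = 17L, fc18 = 18L, fc19 = 19L)
  lapply(groups, function(g) {
    m <- Reduce(`+`, lapply(layer_rdms[g], unclass)) / length(g)
    as_rdm(m, rownames(layer_rdms[[g[1]]]), source = "model",
           dissimilarity_kind = attr(layer_rdms[[g[1]]],
                                     "dissimilarity_kind"))
  })
}

#' Auditory model RDMs from per-stage feature sets
#'
#' One 1-Pearson RDM per stage: 2 stages for the spectrotemporal model
#' (auditory spectrogram, cortical spectrotemporal features) and 11 layers
#' for the two-branch auditory DNN (3 early shared convolutional layers plus
#' 4 layers along each of the genre and word branches).
#'
#' @param spectrotemporal named list of 2 feature matrices.
#' @param dnn named list of 11 feature matrices (3 shared + 4 + 4).
#' @return list with `spectrotemporal` (2 RDMs) and `dnn` (11 RDMs).
#' @export
auditory_model_rdms <- function(spectrotemporal, dnn) {
  if (length(spectrotemporal) != 2)
    stop("spectrotemporal model must have exactly 2 stages, got ",
         length(spectrotemporal))
  if (length(dnn) != 11)
    stop("auditory DNN must have exactly 11 layers (3 shared + 4 + 4), got ",
         length(dnn))
  list(spectrotemporal = lapply(spectrotemporal, model_rdm),
       dnn = lapply(dnn, model_rdm))
}

#' Lower-triangle entries of an RDM
#'
#' @param rdm a symmetric RDM.
#' @return numeric vector (66 entries for 12 conditions).
#' @export
rdm_lower <- function(rdm) {
  m <- unclass(rdm)
  m[lower.tri(m)]
}

#' Compare neural RDMs against a model RDM
#'
#' Spearman rank correlation (average ranks on ties) over the lower-triangle
#' entries, per participant. The per-participant coefficients are the input
#' to the group-level sign-permutation test; FDR correction across RDMs
#' within a model family is applied downstream.
#'
#' @param neural_rdms list of per-participant `rdm` objects.
#' @param model an `rdm` object of matching size (and labels, if both sides
#'   are labeled).
#' @return numeric vector of per-participant Spearman coefficients.
#' @export
compare_rdms <- function(neural_rdms, model) {
  mv <- rdm_lower(model)
  vapply(neural_rdms, function(r) {
    if (!is.null(rownames(r)) && !is.null(rownames(model)) &&
        !identical(rownames(r), rownames(model)))
      stop("RDM condition labels do not match")
    nv <- rdm_lower(r)
    if (length(nv) != length(mv)) stop("RDM sizes do not match")
    stats::cor(nv, mv, method = "spearman")
  }, numeric(1))
}

#' Read / write labeled RDM CSV files
#'
#' Layout: square numeric matrix with a header row and a leading column of
#' condition names.
#' @param rdm an `rdm` object.
#' @param path file path.
#' @return `write_rdm_csv` returns `path` invisibly; `read_rdm_csv` returns
#'   an `rdm`.
#' @export
write_rdm_csv <- function(rdm, path) {
  m <- unclass(rdm)
  if (is.null(rownames(m))) dimnames(m) <- list(paste0("obj", seq_len(nrow(m))),
                                                paste0("obj", seq_len(nrow(m))))
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  as_rdm(m, rownames(m))
}
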