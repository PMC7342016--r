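#' EASYCAP 64-channel montage with anterior/posterior halves
#'
#' Loads the montage fixture shipped with the package: 63 data channels of a
#' standard 10-10 EASYCAP-64 layout (Fz is the online reference and carries
#' no data), each tagged by its channel group (Fp, AF, F, FT, FC, T, C, CP,
#' P, TP, PO, O) and by membership in the anterior (35 channels: frontal,
#' fronto-temporal, fronto-central, temporal and central groups) and
#' posterior (37 channels: central, temporal, centro-parietal, parietal,
#' temporo-parietal, parieto-occipital and occipital groups) scalp halves.
#' Central and temporal channels belong to both halves.
#'
#' @return data.frame with columns `channel`, `group`, `anterior`,
#'   `posterior`.
#' @export
easycap_montage <- function() {
  path <- system.file("extdata", "montage_easycap64.csv",
                      package = "alphashare")
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  m$anterior <- as.logical(m$anterior)
  m$posterior <- as.logical(m$posterior)
  m
}

#' Restrict data to one half of the electrode montage
#'
#' Filters the channel dimension of an `epoch_set`, `tf_epochs` or band
#' array to the anterior or posterior electrode half.
#'
#' @param x an `epoch_set`, `tf_epochs`, or array returned by
#'   [band_vectors()] with `mode = "average"`.
#' @param subset `"anterior"` or `"posterior"`.
#' @param montage membership table (default [easycap_montage()]).
#' @return same class as `x` with channels filtered.
#' @export
electrode_subset <- function(x, subset = c("anterior", "posterior"),
                             montage = easycap_montage()) {
  subset <- match.arg(subset)
  chans <- if (inherits(x, c("epoch_set", "tf_epochs"))) x$channels
           else attr(x, "channels")
  unknown <- setdiff(chans, montage$channel)
  if (length(unknown) > 0)
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  keep <- chans %in% montage$channel[montage[[subset]]]
  if (!any(keep)) stop("no channels left in the ", subset, " half")
  if (inherits(x, "epoch_set")) {
    x$data <- x$data[, keep, , drop = FALSE]
    x$channels <- chans[keep]
  } else if (inherits(x, "tf_epochs")) {
    x$power <- x$power[, keep, , , drop = FALSE]
    x$channels <- chans[keep]
  } else {
    at <- attributes(x)
    x <- x[, keep, , drop = FALSE]
    for (nm in setdiff(names(at), c("dim", "channels")))
      attr(x, nm) <- at[[nm]]
    attr(x, "channels") <- chans[keep]
  }
  x
}
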