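# Marker segmentation and enrichment/depletion over compaction classes.

#' Segment a marker channel inside the nuclear mask
#'
#' Threshold = `threshold_factor` x Otsu threshold of the in-mask marker
#' intensities; voxels strictly above are retained with their intensities.
#' The factor stands in for the interactive tuning of a semi-automatic
#' thresholding step while keeping the operation reproducible.
#'
#' @param marker a [voxel_grid()] congruent with `mask`.
#' @param mask a [nucleus_mask()].
#' @param threshold_factor multiplier on the Otsu threshold.
#' @return a `marker_segmentation`: list with `voxels` (linear indices into
#'   the grid), `intensities`, `threshold`, `marker` name.
#' @export
segment_marker <- function(marker, mask, threshold_factor = 1.0) {
  check_congruent(marker, mask)
  vals <- marker$data[mask$mask]
  if (all(vals == 0)) {
    warning("marker channel is all zero inside the mask")
    return(structure(list(voxels = integer(), intensities = numeric(),
                          threshold = Inf, marker = marker$channel),
                     class = "marker_segmentation"))
  }
  thr <- threshold_factor * otsu_threshold(vals)
  idx <- which(mask$mask & marker$data > thr)
  structure(list(voxels = idx, intensities = marker$data[idx], threshold = thr,
                 marker = marker$channel),
            class = "marker_segmentation")
}

#' Enrichment/depletion profile of a marker over compaction classes
#'
#' For each class k the DAPI baseline `f_k` is the unweighted share of
#' in-mask voxels in class k, and the marker share `m_k` is the
#' intensity-weighted share of marker-positive voxels mapped to class k
#' (both normalized to 1 per nucleus). The profile reports
#' `delta_k = 100 * (m_k - f_k)` percentage points: positive values mean
#' relative enrichment (over-representation) of the marker in that class
#' versus the null hypothesis of a random distribution, negative values
#' relative depletion. The deltas sum to zero by construction.
#'
#' @param seg a `marker_segmentation` sharing the mask with `field`.
#' @param field a `class_field` from [fit_hmrf()].
#' @param intensity_weighted weight marker voxels by intensity (default) or
#'   count each retained voxel once.
#' @return an `enrichment_profile`: data.frame `class`, `dapi_fraction`,
#'   `marker_fraction`, `delta`, with attribute `marker`.
#' @export
enrichment_profile <- function(seg, field, intensity_weighted = TRUE) {
  if (length(seg$voxels) == 0) stop("no marker signal")
  K <- field$params$K
  f <- class_profile(field)
  lab <- field$labels[seg$voxels]
  if (any(lab == 0))
    stop("marker segmentation extends outside the class-field mask")
  w <- if (intensity_weighted) seg$intensities else rep(1, length(lab))
  m <- vapply(seq_len(K), function(k) sum(w[lab == k]), numeric(1))
  m <- m / sum(m)
  out <- data.frame(class = seq_len(K), dapi_fraction = as.numeric(f),
                    marker_fraction = m, delta = 100 * (m - as.numeric(f)))
  attr(out, "marker") <- seg$marker
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Aggregate enrichment profiles across nuclei
#'
#' Per-class mean and SEM of the percentage-point deltas over nuclei, plus
#' the mean DAPI baseline fractions (the reference the deltas are measured
#' against).
#'
#' @param profiles list of `enrichment_profile`s with identical K.
#' @return data.frame `class`, `mean_delta`, `sem_delta`, `mean_dapi_fraction`,
#'   `n`.
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) == 0) stop("need at least one profile")
  Ks <- vapply(profiles, nrow, 1L)
  if (length(unique(Ks)) != 1) stop("profiles have mixed K")
  deltas <- do.call(rbind, lapply(profiles, `[[`, "delta"))
  fs <- do.call(rbind, lapply(profiles, `[[`, "dapi_fraction"))
  n <- nrow(deltas)
  data.frame(class = seq_len(Ks[1]),
             mean_delta = colMeans(deltas),
             sem_delta = if (n > 1) apply(deltas, 2, stats::sd) / sqrt(n) else rep(0, Ks[1]),
             mean_dapi_fraction = colMeans(fs),
             n = n)
}
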