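# Replication-domain segmentation, counts/volumes and the rank-sum / Holm
# statistics used to compare conditions.

#' Segment replication domains in 3D
#'
#' Fixed intensity threshold at `lower/255` of the channel's nominal maximum
#' (the published operating point on an 8-bit scale, generalized to other
#' dynamic ranges), restriction to the nuclear mask, connected components,
#' separation of touching objects by a distance-transform split (seeds are
#' local maxima of the Euclidean distance transform, greedily pruned so that
#' no two seeds lie within the radius of a sphere of volume `size_guide`;
#' component voxels are then assigned to the nearest seed), and finally size
#' exclusion of objects smaller than `min_volume`.
#'
#' @param rd_channel a [voxel_grid()] (its `scale_max` defines the dtype
#'   maximum the threshold fraction refers to).
#' @param mask a [nucleus_mask()].
#' @param lower threshold on the 0-255 scale (voxels at or above are kept).
#' @param size_guide um^3; minimum object scale used to prune split seeds.
#' @param min_volume um^3; objects below are excluded.
#' @param nucleus_id id recorded per object.
#' @param condition condition label recorded per object.
#' @return an `rd_table` data.frame: `id`, `volume_um3`, `x`, `y`, `z`
#'   (centroid, um), `nucleus_id`, `condition`.
#' @export
segment_rds <- function(rd_channel, mask, lower = 32, size_guide = 0.002,
                        min_volume = 0.005, nucleus_id = 1L,
                        condition = "control") {
  check_congruent(rd_channel, mask)
  if (!any(mask$mask)) stop("empty nuclear mask")
  vs_um <- rd_channel$voxel_size / 1000
  thr <- lower / 255 * rd_channel$scale_max
  fg <- as_3d(rd_channel$data >= thr & mask$mask)
  empty <- data.frame(id = integer(), volume_um3 = numeric(), x = numeric(),
                      y = numeric(), z = numeric(), nucleus_id = integer(),
                      condition = character())
  class(empty) <- c("rd_table", "data.frame")
  if (!any(fg)) return(empty)

  comp <- label_components(fg)
  dist <- edt(fg, vs_um)
  r_guide <- (3 * size_guide / (4 * pi))^(1/3)
  seeds <- which(local_maxima(dist, fg))
  d <- dim(fg)
  seed_xyz <- (row_col_slice(seeds, d) - 0.5) %*% diag(vs_um)
  seed_comp <- comp[seeds]
  # greedy pruning, strongest (deepest) seeds first, within each component
  ord <- order(-dist[seeds])
  keep <- logical(length(seeds))
  for (i in ord) {
    prev <- which(keep & seed_comp == seed_comp[i])
    if (length(prev) == 0 ||
        min(sqrt(colSums((t(seed_xyz[prev, , drop = FALSE]) - seed_xyz[i, ])^2))) >= r_guide)
      keep[i] <- TRUE
  }
  seeds <- seeds[keep]
  seed_xyz <- seed_xyz[keep, , drop = FALSE]
  seed_comp <- seed_comp[keep]

  vox <- which(fg)
  vox_xyz <- (row_col_slice(vox, d) - 0.5) %*% diag(vs_um)
  vox_comp <- comp[vox]
  obj <- integer(length(vox))
  for (cid in unique(vox_comp)) {
    sv <- which(seed_comp == cid)
    vv <- which(vox_comp == cid)
    if (length(sv) <= 1L) {
      obj[vv] <- if (length(sv) == 1L) sv else NA_integer_
      next
    }
    # nearest-seed assignment splits the touching objects
    dmat <- outer(rowSums(vox_xyz[vv, , drop = FALSE]^2),
                  rowSums(seed_xyz[sv, , drop = FALSE]^2), "+") -
      2 * vox_xyz[vv, , drop = FALSE] %*% t(seed_xyz[sv, , drop = FALSE])
    obj[vv] <- sv[max.col(-dmat, ties.method = "first")]
  }
  ok <- !is.na(obj)
  vox <- vox[ok]; vox_xyz <- vox_xyz[ok, , drop = FALSE]; obj <- obj[ok]

  vox_um3 <- voxel_volume_um3(rd_channel$voxel_size)
  rows <- lapply(sort(unique(obj)), function(o) {
    sel <- obj == o
    vol <- sum(sel) * vox_um3
    if (vol < min_volume) return(NULL)
    data.frame(volume_um3 = vol, x = mean(vox_xyz[sel, 1]),
               y = mean(vox_xyz[sel, 2]), z = mean(vox_xyz[sel, 3]))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(empty)
  out <- cbind(data.frame(id = seq_len(nrow(rows))), rows,
               nucleus_id = nucleus_id, condition = condition)
  class(out) <- c("rd_table", "data.frame")
  out
}

#' Per-nucleus counts and pooled volume summaries
#'
#' Boxplot-ready summaries matching the plotting convention used for RD
#' statistics: the middle line is the median, the hinges are the Tukey
#' (inclusive) 25/75% quartiles, the whiskers extend to the most extreme
#' values within 1.5 x IQR of the hinges.
#'
#' @param table an `rd_table` (objects from one or more nuclei/conditions).
#' @return list with `counts` (data.frame `condition`, `nucleus_id`, `n`) and
#'   `volume_summary` (per condition: median, hinges, whiskers, n objects).
#' @export
rd_counts_and_volumes <- function(table) {
  if (nrow(table) == 0) stop("empty RD table")
  counts <- stats::aggregate(list(n = table$id),
                             by = list(condition = table$condition,
                                       nucleus_id = table$nucleus_id),
                             FUN = length)
  vol_sum <- do.call(rbind, lapply(split(table, table$condition), function(df) {
    fn <- stats::fivenum(df$volume_um3)
    iqr <- fn[4] - fn[2]
    v <- df$volume_um3
    data.frame(condition = df$condition[1], n_objects = nrow(df),
               median = fn[3], hinge_lo = fn[2], hinge_hi = fn[4],
               whisker_lo = min(v[v >= fn[2] - 1.5 * iqr]),
               whisker_hi = max(v[v <= fn[4] + 1.5 * iqr]))
  }))
  rownames(vol_sum) <- NULL
  list(counts = counts, volume_summary = vol_sum)
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction. When every value in both samples is identical the p-value
#' is 1.
#'
#' @param sample_a,sample_b numeric samples (non-empty).
#' @return list with `U` (statistic for `sample_a`) and `p`.
#' @export
mann_whitney_two_sided <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) stop("empty sample")
  if (length(unique(c(sample_a, sample_b))) == 1L) {
    return(list(U = length(sample_a) * length(sample_b) / 2, p = 1))
  }
  ties <- any(duplicated(c(sample_a, sample_b)))
  exact <- !ties && (length(sample_a) + length(sample_b)) <= 12
  wt <- suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Holm step-down adjustment of p-values
#'
#' @param p_values numeric vector in `[0, 1]`; input order is preserved.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}

#' Pairwise condition contrasts with Holm correction
#'
#' Runs [mann_whitney_two_sided()] on every pair of conditions for the given
#' metric and applies [holm_adjust()] across the family of contrasts.
#'
#' @param values numeric metric values.
#' @param condition condition label per value.
#' @return data.frame `a`, `b`, `U`, `p`, `p_holm`.
#' @export
pairwise_condition_tests <- function(values, condition) {
  conds <- unique(condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  res <- do.call(rbind, lapply(pairs, function(pr) {
    t <- mann_whitney_two_sided(values[condition == pr[1]],
                                values[condition == pr[2]])
    data.frame(a = pr[1], b = pr[2], U = t$U, p = t$p)
  }))
  res$p_holm <- holm_adjust(res$p)
  res
}
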