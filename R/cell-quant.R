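# Nucleus segmentation, nuclear volume, integrated DNA content and
# degradation-kinetics trace processing.

#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, automatic (Otsu) threshold, connected components,
#' then the classic clean-up recipe: dilate, fill holes, erode (the same
#' number of iterations each way), drop objects below the minimum volume and
#' objects touching the XY image border. Anisotropic voxel size is honored in
#' the um^3 conversion.
#'
#' @param dapi a [voxel_grid()], single channel.
#' @param min_volume minimum object volume, um^3.
#' @param smooth_sigma Gaussian smoothing sigma in nm.
#' @param dilate_erode_iters iterations of dilation then erosion.
#' @return list of [nucleus_mask()], border-touching nuclei excluded.
#' @export
segment_nuclei <- function(dapi, min_volume = 200, smooth_sigma = 100,
                           dilate_erode_iters = 15L) {
  a <- as_3d(dapi$data)
  vs <- if (length(dapi$voxel_size) == 2L) c(dapi$voxel_size, 1) else dapi$voxel_size
  if (all(a == a[1])) return(list())
  sm <- gaussian_blur(a, smooth_sigma / vs)
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  if (!any(fg)) return(list())
  fg <- binary_dilate(fg, dilate_erode_iters)
  fg <- fill_holes(fg)
  fg <- binary_erode(fg, dilate_erode_iters)
  lab <- label_components(fg)
  vox_um3 <- voxel_volume_um3(dapi$voxel_size)
  d <- dim(a)
  out <- list()
  for (id in setdiff(sort(unique(as.integer(lab))), 0L)) {
    m <- lab == id
    if (sum(m) * vox_um3 < min_volume) next
    on_border <- any(m[1, , ]) || any(m[d[1], , ]) || any(m[, 1, ]) || any(m[, d[2], ])
    if (on_border) next
    dim(m) <- dim(dapi$data)
    out[[length(out) + 1L]] <- nucleus_mask(m, dapi$voxel_size,
                                            nucleus_id = length(out) + 1L)
  }
  out
}

#' Nuclear volume in cubic micrometres
#'
#' @param mask a [nucleus_mask()].
#' @export
nuclear_volume <- function(mask) {
  sum(mask$mask) * voxel_volume_um3(mask$voxel_size)
}

#' Integrated DNA content of a segmented nucleus
#'
#' Sum over the mask of background-subtracted intensities, with the
#' background estimated as the modal gray value of the full frame and
#' negative differences clipped at zero. Arbitrary units; proportional to
#' DNA content for a stoichiometric stain, so a 4n nucleus reads twice a 2n
#' nucleus.
#'
#' @param dapi a [voxel_grid()].
#' @param mask a [nucleus_mask()] congruent with `dapi`.
#' @export
integrated_dna_content <- function(dapi, mask) {
  check_congruent(dapi, mask)
  if (!any(mask$mask)) return(0)
  bg <- modal_value(as.numeric(dapi$data))
  sum(pmax(dapi$data[mask$mask] - bg, 0))
}

#' Filter and normalize degradation traces
#'
#' Applies the published trace-quality rules: (1) cells whose starting
#' intensity is not above `min_start` counts are excluded; (2) retained
#' traces are normalized to their first value; (3) a per-cell fluctuation
#' score is computed as the maximum relative deviation from the cell's own
#' centered rolling mean of `window` timepoints (truncated at the trace
#' ends), and cells strictly exceeding the across-cell `quantile` of that
#' score are excluded.
#'
#' @param traces data.frame with `cell_id`, `t_index`, `intensity`.
#' @param min_start minimum starting intensity in counts.
#' @param window rolling-mean window (timepoints).
#' @param quantile across-cell fluctuation quantile above which cells drop.
#' @return list with `traces` (normalized, retained cells), `exclusions`
#'   (data.frame `cell_id`, `reason`), and `fluctuation` per retained-at-step-1
#'   cell.
#' @export
filter_and_normalize_traces <- function(traces, min_start = 50, window = 5L,
                                        quantile = 0.90) {
  if (nrow(traces) == 0) stop("no traces supplied")
  traces <- traces[order(traces$cell_id, traces$t_index), ]
  cells <- split(traces, traces$cell_id)
  excl <- data.frame(cell_id = integer(), reason = character())
  kept <- list()
  fluct <- numeric()
  for (cl in cells) {
    id <- cl$cell_id[1]
    if (cl$intensity[1] <= min_start) {
      excl <- rbind(excl, data.frame(cell_id = id, reason = "start_below_min"))
      next
    }
    v <- cl$intensity / cl$intensity[1]
    rm_ <- rolling_mean_centered(v, window)
    fl <- max(abs(v - rm_) / pmax(abs(rm_), .Machine$double.eps))
    kept[[as.character(id)]] <- transform(cl, normalized = v)
    fluct[as.character(id)] <- fl
  }
  if (length(kept) == 0)
    return(list(traces = traces[0, ], exclusions = excl, fluctuation = fluct))
  cutoff <- stats::quantile(fluct, quantile)
  drop <- names(fluct)[fluct > cutoff]
  if (length(drop))
    excl <- rbind(excl, data.frame(cell_id = as.integer(drop),
                                   reason = "fluctuation_above_quantile"))
  out <- do.call(rbind, kept[setdiff(names(kept), drop)])
  rownames(out) <- NULL
  list(traces = out, exclusions = excl, fluctuation = fluct)
}

# centered rolling mean, window truncated at the ends (no padding)
rolling_mean_centered <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
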