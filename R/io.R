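# File interchange: multi-page TIFF stacks with a JSON metadata sidecar,
# scene truth as JSON, traces as CSV.

#' Write a voxel grid as a multi-page TIFF
#'
#' Intensities are stored as 16-bit pages (z slices); the physical voxel
#' size, channel name and intensity scale go to a JSON sidecar at
#' `<path>.json` so the grid round-trips.
#'
#' @param grid a [voxel_grid()].
#' @param path output TIFF path.
#' @export
write_voxel_grid <- function(grid, path) {
  a <- as_3d(grid$data)
  pages <- lapply(seq_len(dim(a)[3]), function(z) {
    pmin(pmax(a[, , z] / grid$scale_max, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size_nm = grid$voxel_size,
                            channel = grid$channel,
                            scale_max = grid$scale_max,
                            dim = dim(grid$data)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#' @param path TIFF path (expects the `<path>.json` sidecar).
#' @export
read_voxel_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- simplify2array(pages) * meta$scale_max
  dim(a) <- meta$dim
  voxel_grid(a, meta$voxel_size_nm, channel = meta$channel,
             scale_max = meta$scale_max)
}

#' Write scene ground truth as JSON
#' @param truth a `scene_truth` from [generate_nucleus_scene()].
#' @param path output path (the voxel-level label field and mask are stored
#'   as run-length-free integer vectors with dimensions).
#' @export
write_scene_truth <- function(truth, path) {
  jsonlite::write_json(list(
    dim = dim(truth$label_field),
    label_field = as.integer(truth$label_field),
    mask = as.integer(truth$mask),
    true_class_fractions = truth$true_class_fractions,
    marker_truth = lapply(truth$marker_truth, function(mt)
      list(class_fractions = mt$class_fractions)),
    rd_truth = truth$rd_truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write traces as CSV (`cell_id`, `t_index`, `intensity`)
#' @param traces data.frame.
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces[, c("cell_id", "t_index", "intensity")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a traces CSV
#' @param path CSV with `cell_id`, `t_index`, `intensity`.
#' @export
read_traces <- function(path) utils::read.csv(path)
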