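#' Voxel grid container
#'
#' A `voxel_grid` is the carrier of all image data in nucarch: a 2D or 3D
#' numeric intensity array together with its physical voxel dimensions in
#' nanometres and a channel identity. Intensities are floating point on a
#' nominal `[0, scale_max]` scale; `scale_max` records the dynamic range the
#' channel was rendered on (65535 for DAPI/marker channels, 255 for the
#' 8-bit replication-domain channel whose segmentation threshold is defined
#' on that scale).
#'
#' @param data numeric array, 2 or 3 dimensions (x, y\[, z\]).
#' @param voxel_size numeric vector of nm per axis, same length as `dim(data)`.
#' @param channel channel name, e.g. `"DAPI"`, `"SC35"`, `"RD"`.
#' @param scale_max nominal intensity maximum of the channel.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, channel = "DAPI", scale_max = 65535) {
  if (!is.array(data) && !is.matrix(data)) stop("`data` must be an array or matrix")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("`data` must be 2D or 3D")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, nd)
  if (length(voxel_size) != nd) stop("`voxel_size` must match dimensionality")
  if (any(voxel_size <= 0)) stop("`voxel_size` must be positive")
  structure(list(data = data, voxel_size = voxel_size, channel = channel,
                 scale_max = scale_max),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> channel %s, %s voxels, voxel size %s nm, range [%.3g, %.3g]\n",
              x$channel, paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param voxel_size nm per axis (length 2 gives an area in um^2).
#' @export
voxel_volume_um3 <- function(voxel_size) prod(voxel_size / 1000)

#' Nucleus mask
#'
#' Boolean grid delimiting one segmented nucleus, with identity and a flag
#' marking nuclei that touch the XY image border (such nuclei are excluded
#' from quantification).
#'
#' @param mask logical array congruent with the source grid.
#' @param voxel_size nm per axis.
#' @param nucleus_id integer id.
#' @param border_touching does the mask touch the XY border?
#' @export
nucleus_mask <- function(mask, voxel_size, nucleus_id = 1L, border_touching = FALSE) {
  stopifnot(is.logical(mask))
  structure(list(mask = mask, voxel_size = as.numeric(voxel_size),
                 nucleus_id = as.integer(nucleus_id),
                 border_touching = isTRUE(border_touching)),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> id %d, %d voxels (%.2f um^3)%s\n", x$nucleus_id,
              sum(x$mask), sum(x$mask) * voxel_volume_um3(x$voxel_size),
              if (x$border_touching) ", touches XY border" else ""))
  invisible(x)
}

# shared validation: grid and mask must live on the same lattice
check_congruent <- function(grid, mask) {
  if (!identical(dim(grid$data), dim(mask$mask)))
    stop("grid and mask dimensions differ")
  invisible(TRUE)
}
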