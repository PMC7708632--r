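# DNA-halo loop-size quantification.

#' Segment scaffold and total areas in a halo image
#'
#' Automated stand-in for manual two-level segmentation: a two-level Otsu
#' partition of the image histogram into background | halo | scaffold gives a
#' low and a high threshold; the total area `At` is everything above the low
#' threshold, the scaffold area `As` everything above the high one. Both
#' masks are hole-filled before the areas are measured.
#'
#' @param image 2D [voxel_grid()] of one extracted cell.
#' @return list with `At` and `As` in um^2 (plus the two masks).
#' @export
segment_halo <- function(image) {
  a <- image$data
  if (length(dim(a)) != 2L) stop("halo images must be 2D")
  px_um2 <- prod(image$voxel_size / 1000)
  if (diff(range(a)) == 0) {
    warning("uniform image: no halo structure found")
    return(list(At = 0, As = 0, total_mask = a > Inf, scaffold_mask = a > Inf))
  }
  ts <- multi_otsu_two(as.numeric(a))
  m1 <- mean(a[a <= ts[1]])
  m2 <- mean(a[a > ts[1] & a <= ts[2]])
  m3 <- mean(a[a > ts[2]])
  if (!is.finite(m2) || min(m2 - m1, m3 - m2) < 0.15 * (m3 - m1)) {
    # effectively bimodal image (core only, no halo ring): fall back to a
    # single threshold, giving At = As and a zero halo
    t1 <- otsu_threshold(as.numeric(a))
    total <- scaffold <- fill_holes(a > t1)
  } else {
    total <- fill_holes(a > ts[1])
    scaffold <- fill_holes(a > ts[2])
  }
  At <- sum(total) * px_um2
  As <- sum(scaffold) * px_um2
  if (As > At) stop("inconsistent thresholds: scaffold area exceeds total area")
  list(At = At, As = As, total_mask = total, scaffold_mask = scaffold)
}

#' Halo radius from total and scaffold areas
#'
#' The halo area is `Ah = At - As` and the halo radius follows as
#' `R = sqrt(Ah / pi)` -- the radius of the disc-equivalent ring of extruded
#' chromatin loops.
#'
#' @param At total area, um^2.
#' @param As scaffold area, um^2.
#' @param cell_id,condition metadata carried on the measurement.
#' @return a `halo_measurement` data.frame row: `At`, `As`, `Ah`, `R`,
#'   `cell_id`, `condition`.
#' @export
halo_radius <- function(At, As, cell_id = 1L, condition = "control") {
  if (At < As) stop("At must be >= As")
  Ah <- At - As
  data.frame(At = At, As = As, Ah = Ah, R = sqrt(Ah / pi),
             cell_id = cell_id, condition = condition)
}

#' Compare halo radii between two conditions
#'
#' Two-sided Wilcoxon rank-sum comparison of per-cell halo radii.
#'
#' @param measurements data.frame with `R` and `condition` (exactly two
#'   conditions).
#' @return list with `U`, `p`, and per-condition medians.
#' @export
compare_halo <- function(measurements) {
  conds <- unique(measurements$condition)
  if (length(conds) != 2) stop("need exactly two conditions")
  a <- measurements$R[measurements$condition == conds[1]]
  b <- measurements$R[measurements$condition == conds[2]]
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  t <- mann_whitney_two_sided(a, b)
  list(U = t$U, p = t$p,
       medians = stats::setNames(c(stats::median(a), stats::median(b)), conds))
}
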