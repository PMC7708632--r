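# Synthetic DNA-halo images and degradation-kinetics traces.

#' Generate a synthetic DNA-halo image
#'
#' Renders a single extracted cell as seen in a halo assay: a bright central
#' scaffold disc (residual protein scaffold after high-salt histone
#' extraction) inside a fainter halo disc of extruded chromatin loops whose
#' intensity fades towards the halo edge. The analytic truth areas
#' `At = pi * halo_radius^2` and `As = pi * core_radius^2` are returned with
#' the image.
#'
#' @param core_radius scaffold radius in um.
#' @param halo_radius total (scaffold + halo) radius in um; must be >=
#'   `core_radius`.
#' @param pixel_size um per pixel.
#' @param noise_sd additive Gaussian noise on the unit intensity scale.
#' @param seed optional seed.
#' @return list with `image` (2D [voxel_grid()], unit intensity scale),
#'   `truth` (`At`, `As`, `Ah`, `R` in um^2 / um).
#' @export
generate_halo_scene <- function(core_radius, halo_radius, pixel_size = 0.065,
                                noise_sd = 0.02, seed = NULL) {
  if (core_radius <= 0 || halo_radius <= 0) stop("radii must be positive")
  if (halo_radius < core_radius) stop("halo_radius must be >= core_radius")
  with_seed(seed, {
    ext <- 2 * halo_radius + max(1, 0.4 * halo_radius)
    n <- ceiling(ext / pixel_size)
    ctr <- ext / 2
    xs <- (seq_len(n) - 0.5) * pixel_size - ctr
    r <- sqrt(outer(xs^2, xs^2, "+"))
    img <- matrix(0.02, n, n)
    in_halo <- r <= halo_radius & r > core_radius
    if (halo_radius > core_radius) {
      frac <- (r[in_halo] - core_radius) / (halo_radius - core_radius)
      img[in_halo] <- 0.45 - 0.2 * frac  # fading loop halo
    }
    img[r <= core_radius] <- 1.0
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    At <- pi * halo_radius^2
    As <- pi * core_radius^2
    list(image = voxel_grid(img, rep(pixel_size * 1000, 2), channel = "halo",
                            scale_max = 1),
         truth = list(At = At, As = As, Ah = At - As, R = sqrt((At - As) / pi)))
  })
}

#' Generate degradation-kinetics traces
#'
#' Emulates per-cell time-lapse fluorescence of a degron-tagged protein after
#' induction: responders decay exponentially with the given half-life, a
#' small non-responder fraction keeps its starting intensity (cells escaping
#' induced degradation), and additive Gaussian noise is applied to every
#' reading. Time points are spaced `dt_min` minutes apart.
#'
#' @param n_cells number of cells (0 gives an empty table).
#' @param half_life half-life of responder decay, minutes.
#' @param nonresponder_fraction probability a cell escapes degradation.
#' @param start_range range of starting intensities (counts), drawn uniformly.
#' @param noise_sd additive noise (counts).
#' @param n_timepoints trace length.
#' @param dt_min sampling interval, minutes.
#' @param seed optional seed.
#' @return list with `traces` (data.frame `cell_id`, `t_index` (0-based),
#'   `intensity`) and `truth` (`responder` logical per cell, `start` counts).
#' @export
generate_decay_traces <- function(n_cells, half_life = 35,
                                  nonresponder_fraction = 0.04,
                                  start_range = c(100, 500), noise_sd = 3,
                                  n_timepoints = 48, dt_min = 15, seed = NULL) {
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1)
    stop("nonresponder_fraction must be in [0, 1]")
  if (n_cells == 0) {
    return(list(traces = data.frame(cell_id = integer(), t_index = integer(),
                                    intensity = numeric()),
                truth = data.frame(cell_id = integer(), responder = logical(),
                                   start = numeric())))
  }
  with_seed(seed, {
    start <- stats::runif(n_cells, start_range[1], start_range[2])
    responder <- stats::runif(n_cells) >= nonresponder_fraction
    t_idx <- 0:(n_timepoints - 1)
    minutes <- t_idx * dt_min
    vals <- lapply(seq_len(n_cells), function(i) {
      v <- if (responder[i]) start[i] * 2^(-minutes / half_life) else rep(start[i], n_timepoints)
      if (noise_sd > 0) v <- v + stats::rnorm(n_timepoints, sd = noise_sd)
      v
    })
    list(traces = data.frame(cell_id = rep(seq_len(n_cells), each = n_timepoints),
                             t_index = rep(t_idx, n_cells),
                             intensity = unlist(vals)),
         truth = data.frame(cell_id = seq_len(n_cells), responder = responder,
                            start = start))
  })
}
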