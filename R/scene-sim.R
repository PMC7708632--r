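# Synthetic 3D-SIM-like nucleus scenes with exported ground truth.
# The generator is first-class, tested code: every downstream module is
# exercised against the truth these functions export.

# evaluate `code` under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic nucleus scene
#'
#' Describes a nucleus rendered into a 3D voxel grid at SIM-like sampling
#' (default 40x40x125 nm): the nuclear shape (one smoothed ellipsoid, or a
#' union of `n_lobes` randomly oriented ellipsoids emulating the
#' multilobulated nuclei that arise after endomitosis under cohesin
#' depletion), a spatially coherent 7-class chromatin-compaction label field
#' sampled from a Potts model, a compacted high-class rim at the nuclear
#' border, carved class-1 interchromatin channels, equal-variance Gaussian
#' emission per class, optional separable-Gaussian PSF blur and noise, plus
#' optional marker channels and a replication-domain channel.
#'
#' @param grid_shape voxel counts per axis (x, y, z).
#' @param voxel_size nm per axis; default matches SIM sampling.
#' @param n_lobes number of nuclear lobes (1 = normal nucleus, >1 = MLN-like).
#' @param nucleus_scale multiplies the nuclear semi-axes (volume scales with
#'   its cube).
#' @param class_means K strictly increasing emission means.
#' @param class_sigma shared emission standard deviation (equal variance
#'   across classes).
#' @param class_weights target class proportions used to initialize and bias
#'   the Potts field (hump-shaped by default, resembling measured DAPI class
#'   profiles).
#' @param potts_beta Potts spatial coupling, >= 0.
#' @param rim_thickness nm of compacted (class 6-7) lamina-associated rim.
#' @param ic_channel_fraction target fraction of in-mask voxels carved into
#'   class-1 interchromatin channels.
#' @param markers list of marker specs, each a list with `name`, per-class
#'   relative emission `weights` (length K), `density` (expected fraction of
#'   in-mask voxels that are marker positive), optional `intensity` and
#'   `noise_sd`.
#' @param rd `NULL` or a list with `pattern` in `"early"`, `"mid"`, `"late"`,
#'   `n_objects`, `mean_volume` (um^3), `cv` (volume coefficient of
#'   variation), optional `separation` (um, minimum center-to-center spacing).
#' @param psf_fwhm nm, lateral/lateral/axial; `NULL` disables PSF blur.
#' @param noise_sd additive Gaussian readout noise (intensity units).
#' @param poisson_scale if > 0, photon shot noise: intensities are replaced
#'   by `rpois(I / s) * s`.
#' @param seed integer seed; identical (spec, seed) give bit-identical scenes.
#' @return a `nucleus_scene_spec` list.
#' @export
nucleus_scene_spec <- function(grid_shape = c(128, 128, 32),
                               voxel_size = c(40, 40, 125),
                               n_lobes = 1L,
                               nucleus_scale = 1,
                               class_means = seq(6000, 60000, length.out = 7),
                               class_sigma = 2300,
                               class_weights = c(0.10, 0.16, 0.20, 0.19, 0.15, 0.12, 0.08),
                               potts_beta = 2,
                               rim_thickness = 160,
                               ic_channel_fraction = 0.12,
                               markers = list(),
                               rd = NULL,
                               psf_fwhm = NULL,
                               noise_sd = 0,
                               poisson_scale = 0,
                               seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = as.numeric(voxel_size),
               n_lobes = as.integer(n_lobes), nucleus_scale = nucleus_scale,
               class_means = as.numeric(class_means), class_sigma = class_sigma,
               class_weights = class_weights / sum(class_weights),
               potts_beta = potts_beta, rim_thickness = rim_thickness,
               ic_channel_fraction = ic_channel_fraction, markers = markers,
               rd = rd, psf_fwhm = psf_fwhm, noise_sd = noise_sd,
               poisson_scale = poisson_scale, seed = seed)
  class(spec) <- "nucleus_scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  K <- length(spec$class_means)
  if (K < 2) stop("need at least 2 classes")
  if (any(diff(spec$class_means) <= 0)) stop("class_means must be strictly increasing")
  if (length(spec$class_weights) != K) stop("class_weights length must equal K")
  if (any(spec$class_weights < 0)) stop("class weights must be >= 0")
  if (spec$potts_beta < 0) stop("potts_beta must be >= 0")
  if (spec$n_lobes < 1) stop("n_lobes must be >= 1")
  if (spec$ic_channel_fraction < 0 || spec$ic_channel_fraction > 0.9)
    stop("ic_channel_fraction out of range")
  for (m in spec$markers) {
    if (length(m$weights) != K) stop("marker weights length must equal K")
    if (any(m$weights < 0)) stop("marker weights must be >= 0")
  }
  invisible(spec)
}

# physical coordinate grids in um, voxel centers
coord_grids <- function(grid_shape, voxel_size) {
  d <- grid_shape
  vs <- voxel_size / 1000
  list(x = array(rep((seq_len(d[1]) - 0.5) * vs[1], times = d[2] * d[3]), d),
       y = array(rep(rep((seq_len(d[2]) - 0.5) * vs[2], each = d[1]), times = d[3]), d),
       z = array(rep((seq_len(d[3]) - 0.5) * vs[3], each = d[1] * d[2]), d))
}

rotation_matrix <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# union of smoothed ellipsoidal lobes; errors if a lobe cannot fit
build_nuclear_mask <- function(spec) {
  d <- spec$grid_shape
  vs <- spec$voxel_size / 1000
  ext <- d * vs
  cg <- coord_grids(d, spec$voxel_size)
  base_ax <- c(0.40, 0.36, 0.38) * ext * spec$nucleus_scale
  if (spec$n_lobes > 1) base_ax <- base_ax * (1 / spec$n_lobes)^(1/3) * 1.1
  mask <- array(FALSE, d)
  for (l in seq_len(spec$n_lobes)) {
    if (spec$n_lobes == 1) {
      ctr <- ext / 2
      R <- diag(3)
    } else {
      ang0 <- 2 * pi * (l - 1) / spec$n_lobes
      off <- 0.35 * max(base_ax)
      ctr <- ext / 2 + c(off * cos(ang0), off * sin(ang0), 0)
      R <- rotation_matrix(stats::runif(3, 0, pi))
    }
    reach <- if (spec$n_lobes == 1) base_ax else rep(max(base_ax), 3)
    if (any(ctr - reach < 0) || any(ctr + reach > ext))
      stop("nucleus does not fit grid")
    dx <- cg$x - ctr[1]; dy <- cg$y - ctr[2]; dz <- cg$z - ctr[3]
    u <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
    v <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
    w <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
    mask <- mask | ((u / base_ax[1])^2 + (v / base_ax[2])^2 + (w / base_ax[3])^2 <= 1)
  }
  if (spec$n_lobes > 1) mask <- binary_erode(binary_dilate(mask, 2L), 2L)  # closing
  mask
}

# quantile-sliced smooth-noise initialization, then 30 Gibbs sweeps of the
# Potts model in the fixed-composition (exchange/Kawasaki) ensemble: label
# swaps conserve the planted class fractions exactly, while the Potts energy
# coarsens boundaries by an amount controlled by beta. A plain single-site
# chain would let small classes evaporate at appreciable coupling.
sample_label_field <- function(mask, spec, sweeps = 30L) {
  d <- dim(mask)
  K <- length(spec$class_means)
  g <- gaussian_blur(array(stats::rnorm(prod(d)), d), c(12, 12, 6))
  labels <- array(0L, d)
  qs <- stats::quantile(g[mask], cumsum(spec$class_weights)[-K])
  labels[mask] <- as.integer(1L + findInterval(g[mask], qs))
  labels[mask] <- cpp_swap_potts(as.integer(labels), d, as.logical(mask),
                                 spec$potts_beta, sweeps)[mask]
  labels
}

#' Generate a synthetic nucleus scene
#'
#' Renders the scene described by a [nucleus_scene_spec()]: nuclear mask,
#' true chromatin-compaction label field, DAPI channel, optional marker
#' channels and replication-domain channel, and returns the full ground
#' truth alongside.
#'
#' @param spec a [nucleus_scene_spec()].
#' @return a list with `channels` (named list of [voxel_grid()]s, always
#'   including `DAPI`) and `truth` (a `scene_truth` list with `label_field`,
#'   `true_class_fractions`, `mask`, `marker_truth`, `rd_truth`).
#' @export
generate_nucleus_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    d <- spec$grid_shape
    vs_um <- spec$voxel_size / 1000
    K <- length(spec$class_means)
    mask <- build_nuclear_mask(spec)
    depth <- edt(mask, vs_um)  # um to nuclear border, 0 outside
    rim_um <- spec$rim_thickness / 1000
    rim <- mask & depth > 0 & depth <= rim_um
    interior <- mask & !rim

    # calibrate the Potts target weights so the rim (class K) and carved IC
    # channels (class 1) leave the final class fractions at class_weights
    n_mask <- sum(mask)
    n_ic <- round(spec$ic_channel_fraction * sum(interior))
    n_free <- sum(interior) - n_ic
    w <- spec$class_weights * n_mask
    w[1] <- max(w[1] - n_ic, 0.005 * n_mask)
    w[K] <- max(w[K] - sum(rim), 0.005 * n_mask)
    spec_potts <- spec
    spec_potts$class_weights <- w / sum(w)
    labels <- sample_label_field(mask, spec_potts)

    if (any(rim)) labels[rim] <- K  # compacted heterochromatin shell at the lamina
    if (n_ic > 0) {
      f <- gaussian_blur(array(stats::rnorm(prod(d)), d), c(5, 5, 2.5))
      thr <- stats::quantile(f[interior], spec$ic_channel_fraction)
      labels[interior & f <= thr] <- 1L
    }

    fracs <- tabulate(labels[mask], K) / sum(mask)
    names(fracs) <- paste0("class", seq_len(K))

    dapi <- array(0, d)
    dapi[mask] <- spec$class_means[labels[mask]]
    if (spec$class_sigma > 0)
      dapi[mask] <- dapi[mask] + stats::rnorm(sum(mask), sd = spec$class_sigma)

    channels <- list()
    marker_truth <- list()
    for (m in spec$markers) {
      w <- as.numeric(m$weights)
      mean_w <- sum(fracs * w)
      if (mean_w <= 0) stop("marker weights are zero on all occupied classes")
      p <- array(0, d)
      p[mask] <- m$density * w[labels[mask]] / mean_w
      if (any(p > 1)) {
        warning("marker placement probabilities clipped at 1")
        p <- pmin(p, 1)
      }
      pos <- mask & (array(stats::runif(prod(d)), d) < p)
      intensity <- if (is.null(m$intensity)) 0.8 * 65535 else m$intensity
      ch <- array(0, d)
      ch[pos] <- intensity
      if (!is.null(m$noise_sd) && m$noise_sd > 0)
        ch <- ch + array(stats::rnorm(prod(d), sd = m$noise_sd), d)
      channels[[m$name]] <- voxel_grid(ch, spec$voxel_size, channel = m$name)
      cls <- tabulate(labels[pos], K)
      marker_truth[[m$name]] <- list(
        positive_voxels = which(pos),
        class_fractions = if (sum(cls) > 0) cls / sum(cls) else rep(NA_real_, K))
    }

    rd_truth <- NULL
    if (!is.null(spec$rd)) {
      rd_res <- place_rd_spheres(spec$rd, mask, labels, depth, rim_um, vs_um)
      channels[["RD"]] <- voxel_grid(rd_res$channel, spec$voxel_size,
                                     channel = "RD", scale_max = 255)
      rd_truth <- rd_res$truth
    }

    # PSF blur and readout noise apply to the recorded DAPI signal
    if (!is.null(spec$psf_fwhm)) {
      sig_vox <- (spec$psf_fwhm / 2.3548) / spec$voxel_size
      dapi <- gaussian_blur(dapi, sig_vox)
    }
    if (spec$noise_sd > 0)
      dapi <- dapi + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
    if (spec$poisson_scale > 0) {
      s <- spec$poisson_scale
      dapi <- array(stats::rpois(prod(d), pmax(dapi, 0) / s) * s, d)
    }
    dapi <- pmin(pmax(dapi, 0), 65535)
    channels <- c(list(DAPI = voxel_grid(dapi, spec$voxel_size, channel = "DAPI")),
                  channels)

    truth <- structure(list(label_field = labels,
                            true_class_fractions = fracs,
                            mask = mask,
                            marker_truth = marker_truth,
                            rd_truth = rd_truth),
                       class = "scene_truth")
    list(channels = channels, truth = truth, spec = spec)
  })
}

# spatial patterns of replication domains: early = interior low-compaction
# zones, mid = near the rim, late = few large blobs in high classes near rim
place_rd_spheres <- function(rd, mask, labels, depth, rim_um, vs_um) {
  d <- dim(mask)
  pattern <- match.arg(rd$pattern, c("early", "mid", "late"))
  cand <- switch(pattern,
    early = mask & labels %in% c(2L, 3L) & depth > rim_um + 0.2,
    mid   = mask & depth > 0 & depth <= max(rim_um + 0.4, 0.5),
    late  = mask & labels >= 5L & depth <= 1.0)
  if (!any(cand)) cand <- mask
  cv <- if (is.null(rd$cv)) 0.3 else rd$cv
  s2 <- log(1 + cv^2)
  vols <- stats::rlnorm(rd$n_objects, meanlog = log(rd$mean_volume) - s2 / 2,
                        sdlog = sqrt(s2))
  radii <- (3 * vols / (4 * pi))^(1/3)
  sep <- if (is.null(rd$separation)) 2.4 * max(radii) else rd$separation
  idx <- sample(which(cand))
  cx <- (row_col_slice(idx, d) - 0.5) %*% diag(vs_um)
  centers <- matrix(NA_real_, 0, 3)
  for (i in seq_along(idx)) {
    p <- cx[i, ]
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - p)^2))) >= sep) {
      centers <- rbind(centers, p)
      if (nrow(centers) == length(radii)) break
    }
  }
  n_placed <- nrow(centers)
  if (n_placed < length(radii)) {
    warning(sprintf("placed %d of %d RDs (candidate zone too small)",
                    n_placed, length(radii)))
    radii <- radii[seq_len(n_placed)]
    vols <- vols[seq_len(n_placed)]
  }
  channel <- render_spheres_into(array(0, d), centers, radii, vs_um, value = 200)
  list(channel = channel,
       truth = data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                          radius_um = radii, volume_um3 = vols,
                          pattern = rep(pattern, n_placed)))
}

row_col_slice <- function(idx, d) {
  idx0 <- idx - 1L
  cbind(idx0 %% d[1] + 1L,
        (idx0 %/% d[1]) %% d[2] + 1L,
        idx0 %/% (d[1] * d[2]) + 1L)
}

render_spheres_into <- function(a, centers, radii, vs_um, value = 200) {
  d <- dim(a)
  for (i in seq_len(nrow(centers))) {
    r <- radii[i]
    ctr <- centers[i, ]
    lo <- pmax(1L, floor((ctr - r) / vs_um - 1))
    hi <- pmin(d, ceiling((ctr + r) / vs_um + 1))
    if (any(lo > hi)) next
    xs <- (lo[1]:hi[1] - 0.5) * vs_um[1] - ctr[1]
    ys <- (lo[2]:hi[2] - 0.5) * vs_um[2] - ctr[2]
    zs <- (lo[3]:hi[3] - 0.5) * vs_um[3] - ctr[3]
    sub <- outer(xs^2, ys^2, "+")
    sub <- outer(sub, zs^2, "+") <= r^2
    blk <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    blk[sub] <- pmax(blk[sub], value)
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- blk
  }
  a
}

#' Render spheres into an empty voxel grid
#'
#' Convenience generator for segmentation tests and benchmarks: spheres of
#' known centers and radii rendered at a constant intensity on an 8-bit-like
#' scale.
#'
#' @param grid_shape voxel counts (x, y, z).
#' @param voxel_size nm per axis.
#' @param centers_um n x 3 matrix of sphere centers in um.
#' @param radii_um sphere radii in um (length n or 1).
#' @param value intensity of sphere voxels (scale 0-255).
#' @return a [voxel_grid()] with `scale_max = 255`.
#' @export
render_spheres <- function(grid_shape, voxel_size, centers_um, radii_um, value = 200) {
  centers_um <- matrix(centers_um, ncol = 3)
  radii_um <- rep_len(radii_um, nrow(centers_um))
  a <- render_spheres_into(array(0, as.integer(grid_shape)), centers_um, radii_um,
                           voxel_size / 1000, value = value)
  voxel_grid(a, voxel_size, channel = "RD", scale_max = 255)
}

#' Marker weights that plant a target class-share shift
#'
#' Given true class fractions `f`, returns per-class emission weights such
#' that the expected marker class share equals `f` shifted by `delta`
#' percentage points in `target_class`, compensated proportionally in the
#' remaining classes.
#'
#' @param fractions true class fractions (sum 1).
#' @param target_class class index receiving the enrichment.
#' @param delta planted enrichment in fractional units (0.15 = +15 points).
#' @export
marker_weights_for_delta <- function(fractions, target_class = 1L, delta = 0.15) {
  f <- fractions / sum(fractions)
  m <- f
  m[target_class] <- f[target_class] + delta
  rest <- setdiff(seq_along(f), target_class)
  m[rest] <- f[rest] - delta * f[rest] / sum(f[rest])
  if (any(m < 0)) stop("delta too large for these fractions")
  w <- ifelse(f > 0, m / f, 0)
  w / max(w)
}

#' 6-neighbor label agreement rate
#'
#' Fraction of 6-connected in-mask voxel pairs carrying the same label; the
#' spatial-coherence summary used to characterize Potts fields (for an
#' independent label field it approaches `sum(f_k^2)`).
#'
#' @param labels integer label array.
#' @param mask logical array of voxels to consider.
#' @export
neighbor_agreement <- function(labels, mask) {
  l3 <- as_3d(labels)
  cpp_neighbor_agreement(as.integer(l3), dim(l3), as.logical(as_3d(mask)))
}
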