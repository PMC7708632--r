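# Threshold-independent classification of in-mask DAPI voxels into K
# chromatin-compaction classes: an equal-variance Gaussian mixture coupled
# by a Potts spatial prior (a hidden Markov random field), fitted by ICM
# label updates alternating with closed-form M-steps.

#' HMRF parameters
#'
#' @param K class count (7 compaction classes by convention: class 1 is the
#'   DNA-sparse interchromatin compartment, class K the most compacted
#'   heterochromatin).
#' @param beta Potts coupling >= 0; `beta = 0` reduces the model to a plain
#'   equal-variance Gaussian mixture MAP classification.
#' @param max_iter maximum outer iterations (ICM phase + M-step).
#' @param tol stop when the fraction of in-mask voxels changing label in an
#'   outer iteration falls below this.
#' @param icm_sweeps maximum raster-order ICM sweeps per phase.
#' @export
hmrf_params <- function(K = 7L, beta = 0.5, max_iter = 60L, tol = 1e-4,
                        icm_sweeps = 1L) {
  if (K < 2) stop("K must be >= 2")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(K = as.integer(K), beta = beta, max_iter = as.integer(max_iter),
                 tol = tol, icm_sweeps = as.integer(icm_sweeps)),
            class = "hmrf_params")
}

#' Fit the HMRF compaction classifier
#'
#' Labels are initialized by K-quantile slicing of the in-mask intensities.
#' The fit then alternates (i) raster-order ICM sweeps minimizing the
#' posterior energy
#' `U(x) = sum_v [(I_v - mu_{x_v})^2 / (2 sigma^2) + log sigma - log pi_{x_v}]
#'  + beta * sum_{v~w} 1[x_v != x_w]`
#' over 6-connected in-mask neighbor pairs, and (ii) closed-form M-steps for
#' the class means, mixture weights and the single shared sigma ("equal
#' intensity variance"). Out-of-mask voxels take no part in either the
#' emission fit or the neighbor terms. Classes are relabeled in ascending
#' order of fitted mean, so class 1 always carries the lowest intensities.
#'
#' @param dapi a [voxel_grid()].
#' @param mask a [nucleus_mask()] congruent with `dapi`.
#' @param params an [hmrf_params()].
#' @return a `class_field`: list with `labels` (integer array, 0 outside the
#'   mask), `params` (fitted `mu`, `sigma`, `pi`, `beta`, `K`), `energy_trace`
#'   (data.frame `phase`, `sweep`, `energy`; energy is non-increasing within
#'   each phase), `mask`, `voxel_size`.
#' @export
fit_hmrf <- function(dapi, mask, params = hmrf_params()) {
  check_congruent(dapi, mask)
  m3 <- as_3d(mask$mask)
  a3 <- as_3d(dapi$data)
  d <- dim(m3)
  K <- params$K
  n_in <- sum(m3)
  if (n_in < K) stop("fewer in-mask voxels than classes")
  intens <- as.numeric(a3)
  maskv <- as.logical(m3)

  # K-quantile initialization
  labels <- integer(length(intens))
  qs <- stats::quantile(intens[maskv], seq_len(K - 1) / K)
  labels[maskv] <- 1L + findInterval(intens[maskv], qs)

  sigma_floor <- max(diff(range(intens[maskv])), 1) * 1e-9 + .Machine$double.eps
  # closed-form M-step from the current hard labels, with the standard
  # empty-cluster rescue: a dying component is reseated in the widest gap of
  # the surviving means so all K classes stay alive (as stats::kmeans does
  # for empty clusters)
  m_step <- function(lab) {
    li <- lab[maskv]
    iv <- intens[maskv]
    cnt <- tabulate(li, K)
    floor_n <- max(K, 1e-4 * length(li))
    mu <- vapply(seq_len(K), function(k) {
      if (cnt[k] > 0) mean(iv[li == k]) else NA_real_
    }, numeric(1))
    dead <- which(cnt < floor_n | is.na(mu))
    reseated <- dead
    for (k in dead) {
      alive <- sort(mu[setdiff(seq_len(K), dead)])
      if (length(alive) < 2) {
        mu[k] <- stats::quantile(iv, (k - 0.5) / K)
      } else {
        g <- which.max(diff(alive))
        mu[k] <- (alive[g] + alive[g + 1]) / 2
      }
      dead <- setdiff(dead, k)
    }
    pi_k <- pmax(cnt / length(li), 1e-4)
    # a reseated component gets a fresh uniform share so the -log pi term
    # cannot strangle it before it can claim voxels
    pi_k[reseated] <- 1 / K
    pi_k <- pi_k / sum(pi_k)
    sigma <- sqrt(mean((iv - mu[li])^2))
    if (!is.finite(sigma) || sigma < sigma_floor) {
      # noiseless emissions give a perfect fit with sigma -> 0: clamp to the
      # floor; a truly degenerate (constant-intensity) input is an error
      if (diff(range(iv)) == 0)
        stop("sigma collapse: in-mask intensities are constant")
      sigma <- sigma_floor
    }
    list(mu = mu, sigma = sigma, pi = pi_k)
  }

  th <- m_step(labels)
  trace <- list()
  phase <- 0L
  for (it in seq_len(params$max_iter)) {
    phase <- phase + 1L
    # annealed coupling: ramp beta up over the first outer iterations so the
    # emission fit settles before the spatial prior locks labels in; beta is
    # constant within each phase, so the per-phase energy stays monotone
    beta_it <- params$beta * min(1, it / 5)
    res <- cpp_icm_sweeps(labels, d, maskv, intens, th$mu, th$sigma,
                          log(th$pi), beta_it, params$icm_sweeps)
    new_labels <- res$labels
    trace[[phase]] <- data.frame(phase = phase,
                                 sweep = seq_along(res$energy),
                                 energy = res$energy)
    changed <- sum(new_labels != labels & maskv)
    labels <- new_labels
    th_new <- m_step(labels)
    param_moved <- max(abs(th_new$mu - th$mu)) > 1e-9 * diff(range(th$mu))
    th <- th_new
    if (changed / n_in < params$tol && !param_moved) break
  }
  # final stabilization at the fitted parameters so labels are exactly the
  # ICM fixed point (for beta = 0: the per-voxel posterior argmax)
  res <- cpp_icm_sweeps(labels, d, maskv, intens, th$mu, th$sigma,
                        log(th$pi), params$beta, max(params$icm_sweeps, 20L))
  labels <- res$labels
  trace[[phase + 1L]] <- data.frame(phase = phase + 1L,
                                    sweep = seq_along(res$energy),
                                    energy = res$energy)

  # relabel ascending by fitted mean
  ord <- order(th$mu)
  remap <- integer(K)
  remap[ord] <- seq_len(K)
  labels[maskv] <- remap[labels[maskv]]
  th$mu <- th$mu[ord]
  th$pi <- th$pi[ord]

  lab_arr <- array(labels, d)
  dim(lab_arr) <- dim(dapi$data)
  structure(list(labels = lab_arr,
                 params = list(K = K, mu = th$mu, sigma = th$sigma, pi = th$pi,
                               beta = params$beta),
                 energy_trace = do.call(rbind, trace),
                 mask = mask$mask,
                 voxel_size = dapi$voxel_size),
            class = "class_field")
}

#' @export
print.class_field <- function(x, ...) {
  cat(sprintf("<class_field> K=%d, %d in-mask voxels, sigma=%.4g, beta=%.3g\n",
              x$params$K, sum(x$mask), x$params$sigma, x$params$beta))
  invisible(x)
}

#' Per-class voxel fractions of a class field
#'
#' @param field a `class_field` from [fit_hmrf()].
#' @return numeric vector of K fractions summing to 1.
#' @export
class_profile <- function(field) {
  inmask <- field$labels[field$mask]
  if (length(inmask) == 0) stop("empty class field")
  fr <- tabulate(inmask, field$params$K) / length(inmask)
  names(fr) <- paste0("class", seq_len(field$params$K))
  fr
}

#' Mean and SEM of class profiles across nuclei
#'
#' @param profiles list of K-fraction vectors (one per nucleus).
#' @return data.frame `class`, `mean`, `sem`, `n`; with a single nucleus the
#'   SEM is reported as 0 and flagged via attribute `single_nucleus`.
#' @export
profile_summary <- function(profiles) {
  if (length(profiles) == 0) stop("need at least one profile")
  K <- length(profiles[[1]])
  if (any(vapply(profiles, length, 1L) != K)) stop("profiles have mixed K")
  mat <- do.call(rbind, profiles)
  n <- nrow(mat)
  out <- data.frame(class = seq_len(K),
                    mean = colMeans(mat),
                    sem = if (n > 1) apply(mat, 2, stats::sd) / sqrt(n) else rep(0, K),
                    n = n)
  attr(out, "single_nucleus") <- n == 1
  out
}

# Fig-style 7-class lookup table: IC blue through compacted white
class_lut <- function(K = 7L) {
  cols <- c("#0000CC", "#7F00FF", "#E00000", "#FF8C00", "#C49A6C", "#FFE800",
            "#FFFFFF")
  if (K != 7L) cols <- grDevices::hcl.colors(K, "Spectral", rev = TRUE)
  rbind(c(0, 0, 0), t(grDevices::col2rgb(cols)) / 255)  # row 1 = class 0
}

#' Export a class field as labeled TIFF
#'
#' Writes the label field as a multi-page TIFF. With `color = FALSE` an 8-bit
#' label image is written (class k stored as gray value k, class 0 as 0),
#' which round-trips exactly. With `color = TRUE` an RGB rendering using a
#' fixed 7-color lookup table (blue, purple, red, orange, light brown,
#' yellow, white; class 0 black) is written instead.
#'
#' @param field a `class_field`.
#' @param path output TIFF path.
#' @param color render with the class lookup table?
#' @export
export_class_tiff <- function(field, path, color = FALSE) {
  lab <- as_3d(field$labels)
  d <- dim(lab)
  if (color) {
    lut <- class_lut(field$params$K)
    pages <- lapply(seq_len(d[3]), function(z) {
      sl <- lab[, , z] + 1L
      array(lut[sl, ], c(d[1], d[2], 3))
    })
  } else {
    pages <- lapply(seq_len(d[3]), function(z) lab[, , z] / 255)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a label TIFF written by [export_class_tiff()] back to labels
#' @param path TIFF path.
#' @export
read_class_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(pages)
  as.integer(round(arr * 255))
  array(as.integer(round(arr * 255)), dim(arr))
}
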